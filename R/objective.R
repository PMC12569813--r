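#' Multiplicative-divisive stand-structure objective
#'
#' The stand score `L` is the mean over core reference trees of
#' `(1 + Mc/d_Mc)(1 + S/d_S) / [(1 + U/d_U)(1 + CI/d_CI)(1 + |W - 0.496|/d_W')]`
#' where the `d` terms are the population standard deviations of the
#' respective per-tree indexes over the same stand state (`d_W'` over the
#' deviations `|W - 0.496|`). Indexes rewarded for increasing (mingling,
#' stratification) sit in the numerator; those to be suppressed (size
#' dominance, crown competition, departure from the random angle pattern)
#' in the denominator. `L > 0` always, and larger is structurally better.
#'
#' @param x A [stand()], or an `index_table` from [structure_indexes()].
#' @param config An [index_config()].
#' @param deltas Optional fixed standard deviations (named like
#'   [index_deltas()] output) to evaluate candidate moves under a frozen
#'   reference state.
#' @return An object of class `stand_objective`: list with `L`,
#'   `contributions` (per-tree tibble), `deltas`, `means`, `n`.
#' @export
stand_objective <- function(x, config = index_config(), deltas = NULL) {
  tab <- if (inherits(x, "index_table")) x else structure_indexes(x, config)
  cfg <- attr(tab, "config") %||% config
  if (is.null(deltas)) deltas <- index_deltas(tab)
  wdev <- abs(tab$W - cfg$w_reference)
  wdev[is.na(wdev)] <- 0
  contrib <- (1 + tab$Mc / deltas[["Mc"]]) * (1 + tab$S / deltas[["S"]]) /
    ((1 + tab$U / deltas[["U"]]) * (1 + tab$CI / deltas[["CI"]]) *
       (1 + wdev / deltas[["w_dev"]]))
  structure(list(
    L = mean(contrib),
    contributions = tibble::tibble(reference_id = tab$reference_id,
                                   contribution = contrib),
    deltas = deltas,
    means = index_means(tab),
    n = nrow(tab)
  ), class = "stand_objective")
}

#' @export
print.stand_objective <- function(x, ...) {
  cat(sprintf("stand objective L = %.4f over %d reference trees\n", x$L, x$n))
  invisible(x)
}

#' @export
tidy.stand_objective <- function(x, ...) x$contributions

#' @export
glance.stand_objective <- function(x, ...) {
  m <- x$means
  tibble::tibble(L = x$L, n = x$n, W_mean = m[["W"]], U_mean = m[["U"]],
                 Mc_mean = m[["Mc"]], S_mean = m[["S"]], CI_mean = m[["CI"]])
}

clause <- function(name, value, pass) {
  tibble::tibble(clause = name, value = value, pass = pass)
}

#' Constraint report for a harvest/replant pair of interventions
#'
#' Evaluates the silvicultural constraint system over three stand states
#' sharing the plot geometry: the initial stand, the stand after selective
#' harvesting, and the stand after replanting. Harvest must not worsen any
#' of the five index means (non-strict comparisons), must preserve the
#' numbers of diameter classes and species, keep canopy density at or
#' above 0.7, and remove at most 35% of the initial stems. Replanting must
#' further improve mingling and the angle pattern relative to the
#' harvested state and land the final density in [1667, 3333] stems/ha.
#' Violations are reported, never thrown.
#'
#' @param initial,after_harvest Stand states.
#' @param after_replant Stand state, or `NULL` to evaluate only the
#'   harvest clauses (used for per-move feasibility inside the optimizer).
#' @param config An [index_config()].
#' @param indexes Optional pre-computed `index_table`s, named `initial`,
#'   `harvest`, `replant`, to avoid recomputation.
#' @return A `constraint_report`: tibble of clauses with an `overall`
#'   attribute (`TRUE` iff every clause holds).
#' @export
constraint_report <- function(initial, after_harvest, after_replant = NULL,
                              config = index_config(), indexes = list()) {
  t0 <- indexes$initial %||% structure_indexes(initial, config)
  t1 <- indexes$harvest %||% structure_indexes(after_harvest, config)
  m0 <- index_means(t0); m1 <- index_means(t1)
  s0 <- stand_summary(initial); s1 <- stand_summary(after_harvest)
  wref <- config$w_reference
  cd1 <- canopy_density(after_harvest)
  tol <- 1e-9
  rep_rows <- list(
    clause("Mc1_ge_Mc0", m1[["Mc"]] - m0[["Mc"]], m1[["Mc"]] >= m0[["Mc"]] - tol),
    clause("S1_ge_S0", m1[["S"]] - m0[["S"]], m1[["S"]] >= m0[["S"]] - tol),
    clause("U1_le_U0", m1[["U"]] - m0[["U"]], m1[["U"]] <= m0[["U"]] + tol),
    clause("CI1_le_CI0", m1[["CI"]] - m0[["CI"]], m1[["CI"]] <= m0[["CI"]] + tol),
    clause("Wdev1_le_Wdev0", abs(m1[["W"]] - wref) - abs(m0[["W"]] - wref),
           abs(m1[["W"]] - wref) <= abs(m0[["W"]] - wref) + tol),
    clause("D1_eq_D0", s1$n_diameter_classes - s0$n_diameter_classes,
           s1$n_diameter_classes == s0$n_diameter_classes),
    clause("T1_eq_T0", s1$n_species - s0$n_species, s1$n_species == s0$n_species),
    clause("Cd_harvest_ge_0.7", cd1, cd1 >= 0.7 - tol),
    clause("N1_ge_0.65_N0", s1$n_trees / s0$n_trees,
           s1$n_trees >= 0.65 * s0$n_trees - tol)
  )
  if (!is.null(after_replant)) {
    t2 <- indexes$replant %||% structure_indexes(after_replant, config)
    m2 <- index_means(t2)
    s2 <- stand_summary(after_replant)
    cd2 <- canopy_density(after_replant)
    rep_rows <- c(rep_rows, list(
      clause("Wdev2_le_Wdev1", abs(m2[["W"]] - wref) - abs(m1[["W"]] - wref),
             abs(m2[["W"]] - wref) <= abs(m1[["W"]] - wref) + tol),
      clause("Mc2_ge_Mc1", m2[["Mc"]] - m1[["Mc"]], m2[["Mc"]] >= m1[["Mc"]] - tol),
      clause("Cd_replant_ge_0.7", cd2, cd2 >= 0.7 - tol),
      clause("PD_in_1667_3333", s2$density_per_ha,
             s2$density_per_ha >= 1667 - tol & s2$density_per_ha <= 3333 + tol)
    ))
  }
  out <- dplyr::bind_rows(rep_rows)
  structure(out, class = c("constraint_report", class(out)),
            overall = all(out$pass))
}

#' @rdname constraint_report
#' @param report A `constraint_report`.
#' @export
constraints_pass <- function(report) isTRUE(attr(report, "overall"))

#' Ideal-structure test
#'
#' A stand has reached the ideal structural state when the core-tree means
#' satisfy `U <= 0.5`, `Mc >= 0.75` and `0.475 <= W <= 0.517`. This is the
#' stopping rule of the dynamic optimization loop.
#'
#' @param x A [stand()] or `index_table`.
#' @param config An [index_config()].
#' @return Logical flag.
#' @export
is_ideal_structure <- function(x, config = index_config()) {
  tab <- if (inherits(x, "index_table")) x else structure_indexes(x, config)
  m <- index_means(tab)
  m[["U"]] <= 0.5 && m[["Mc"]] >= 0.75 && m[["W"]] >= 0.475 && m[["W"]] <= 0.517
}
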