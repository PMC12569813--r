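#' Dynamic predict-optimize loop
#'
#' Alternates structural optimization and five-year growth prediction
#' until the stand reaches the ideal structural state (core means
#' `U <= 0.5`, `Mc >= 0.75`, `0.475 <= W <= 0.517`) or a cycle cap is
#' hit: optimize the current stand, stop if ideal, otherwise advance the
#' optimized stand five years with the predictor bank and repeat. Each
#' cycle's optimization starts a fresh episode budget seeded from
#' `config$seed` plus the cycle number.
#'
#' @param x A [stand()].
#' @param bank A fitted [fit_predictor_bank()].
#' @param config An [optimizer_config()].
#' @param max_cycles Maximum number of five-year advances (default 8,
#'   i.e. a 40-year horizon). `max_cycles = 0` optimizes the current
#'   state only.
#' @param optimizer `"madqn"` (default) or `"maql"`.
#' @param config_idx An [index_config()].
#' @return A `stand_trajectory`: tibble of per-cycle records (years, the
#'   five index means, Cd, density, L before/after optimization, stems
#'   harvested/replanted) with attributes `stop_reason`, `final_stand`,
#'   `snapshots` (list of per-cycle optimized stands), and `config`.
#' @export
dynamic_optimize <- function(x, bank, config = optimizer_config(),
                             max_cycles = 8, optimizer = c("madqn", "maql"),
                             config_idx = index_config()) {
  stopifnot(is_stand(x))
  optimizer <- match.arg(optimizer)
  opt_fun <- if (optimizer == "madqn") optimize_madqn else optimize_maql
  current <- x
  rows <- list()
  snapshots <- list()
  advances <- 0L
  stop_reason <- NULL
  any_feasible <- FALSE
  repeat {
    cfg <- config
    cfg$seed <- config$seed + advances
    res <- opt_fun(current, cfg, config_idx = config_idx)
    any_feasible <- any_feasible || res$feasible
    optimized <- res$best_stand
    tab <- structure_indexes(optimized, config_idx)
    m <- index_means(tab)
    rows[[length(rows) + 1]] <- tibble::tibble(
      cycle = length(rows) + 1L, years = 5L * advances,
      L_initial = res$initial_L, L = res$best_L,
      W = m[["W"]], Mc = m[["Mc"]], CI = m[["CI"]], S = m[["S"]],
      U = m[["U"]], Cd = canopy_density(optimized),
      density = sum(optimized$alive) / stand_area_ha(optimized),
      n_trees = sum(optimized$alive),
      feasible = res$feasible, ideal = is_ideal_structure(tab))
    snapshots[[length(snapshots) + 1]] <- optimized
    current <- optimized
    if (is_ideal_structure(tab)) { stop_reason <- "ideal"; break }
    if (advances >= max_cycles) {
      stop_reason <- if (any_feasible) "max_cycles" else "no_feasible_action"
      break
    }
    current <- advance_stand(current, bank)
    advances <- advances + 1L
  }
  out <- dplyr::bind_rows(rows)
  tibble::new_tibble(out, class = "stand_trajectory",
                     stop_reason = stop_reason, final_stand = current,
                     snapshots = snapshots, config = config)
}

#' @rdname dynamic_optimize
#' @param trajectory A `stand_trajectory`.
#' @export
stop_reason <- function(trajectory) attr(trajectory, "stop_reason")

#' Write a trajectory report
#'
#' Writes the per-cycle record CSV (columns `W`, `Mc`, `CI`, `S`, `U`,
#' `L`, `Years`, ...) and a JSON provenance sidecar (stop reason, seeds
#' and solver settings, package version). Regenerating the report from
#' the same trajectory is byte-identical.
#'
#' @param trajectory A `stand_trajectory` from [dynamic_optimize()].
#' @param dir Output directory (created if needed).
#' @param stem File stem for the report files.
#' @return Invisible character vector of the files written.
#' @export
trajectory_report <- function(trajectory, dir, stem = "trajectory") {
  if (nrow(trajectory) == 0) {
    abort("empty trajectory", class = "standopt_validation_error")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(stem, ".csv"))
  json <- file.path(dir, paste0(stem, ".json"))
  tab <- tibble::as_tibble(trajectory)[, c("W", "Mc", "CI", "S", "U", "L",
                                           "years", "cycle", "density",
                                           "Cd", "feasible", "ideal")]
  names(tab)[names(tab) == "years"] <- "Years"
  readr::write_csv(tab, csv)
  cfg <- attr(trajectory, "config")
  jsonlite::write_json(list(
    stop_reason = stop_reason(trajectory),
    cycles = nrow(trajectory),
    seed = cfg$seed, episodes = cfg$episodes, max_move = cfg$max_move,
    package_version = as.character(utils::packageVersion("standopt"))
  ), json, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(csv, json))
}
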