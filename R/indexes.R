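#' Index configuration
#'
#' Tunables for the structure-index engine. `no_overlap_value` is the
#' crown-overlap sentinel for disjoint crowns (the published convention is
#' 1 m^2; 0 disables it). `terrain_adjusted_layers` switches the vertical
#' layer rule from plain height to height + relative elevation.
#' `mingling_include_reference` includes the reference tree in the
#' species counts of the Simpson correction (default counts neighbours
#' only). `w_reference` is the uniform-angle value regarded as the
#' random-pattern optimum. `w_neighbors` selects the neighbour set of the
#' uniform angle index: `"nearest"` (default) uses the `w_k` nearest
#' living trees — the classic estimator whose random-pattern expectation
#' (about 0.496) and ideal band [0.475, 0.517] the optimization targets —
#' while `"unit"` evaluates W over the Voronoi-unit neighbours with the
#' adaptive threshold `360/(n+1)`, which centres noticeably lower under
#' complete spatial randomness because Voronoi adjacency regularises the
#' angular spacing of neighbours.
#'
#' @param no_overlap_value Sentinel overlap area for disjoint crowns.
#' @param terrain_adjusted_layers Use height + rel_elev for layer rule.
#' @param mingling_include_reference Include reference tree in Simpson counts.
#' @param w_reference Target uniform angle index (default 0.496).
#' @param w_neighbors `"nearest"` or `"unit"` (see Details).
#' @param w_k Neighbour count for `w_neighbors = "nearest"`.
#' @return A list of class `standopt_config`.
#' @export
index_config <- function(no_overlap_value = 1, terrain_adjusted_layers = FALSE,
                         mingling_include_reference = FALSE, w_reference = 0.496,
                         w_neighbors = c("nearest", "unit"), w_k = 4) {
  structure(list(no_overlap_value = no_overlap_value,
                 terrain_adjusted_layers = terrain_adjusted_layers,
                 mingling_include_reference = mingling_include_reference,
                 w_reference = w_reference,
                 w_neighbors = match.arg(w_neighbors),
                 w_k = w_k),
            class = "standopt_config")
}

#' Dominant height of a stand
#'
#' Terrain-adjusted dominant height: with `k = floor(100 * area_ha)` (the
#' 100-per-hectare convention), take the `k` tallest living trees by height
#' and average `height + rel_elev` over them. If fewer than `k` living
#' trees exist, all are used.
#'
#' @param x A [stand()].
#' @param config An [index_config()].
#' @return Dominant height (m).
#' @export
dominant_height <- function(x, config = index_config()) {
  stopifnot(is_stand(x))
  live <- tibble::as_tibble(x)[x$alive, ]
  k <- floor(100 * stand_area_ha(x))
  if (k < 1) abort("plot too small: floor(100 * area_ha) = 0",
                   class = "standopt_validation_error")
  k <- min(k, nrow(live))
  key <- if (isTRUE(config$terrain_adjusted_layers)) live$height + live$rel_elev else live$height
  top <- order(key, decreasing = TRUE)[seq_len(k)]
  mean(live$height[top] + live$rel_elev[top])
}

# Vertical layer flag by thirds of dominant height; exact boundaries go to
# the middle layer.
layer_flag <- function(height, rel_elev, H_d, config) {
  h <- if (isTRUE(config$terrain_adjusted_layers)) height + rel_elev else height
  fl <- integer(length(h))
  fl[h < H_d / 3] <- -1L
  fl[h > 2 * H_d / 3] <- 1L
  fl
}

# --- per-unit index kernels (vectors indexed into the living-tree table) ---

w_index_kernel <- function(ref, nb, live, config) {
  n <- length(nb)
  if (n < 2) return(NA_real_)
  az <- sort(azimuth_deg(live$x[nb] - live$x[ref], live$y[nb] - live$y[ref]))
  gaps <- c(diff(az), 360 - (az[n] - az[1]))
  alpha <- pmin(gaps, 360 - gaps)
  mean(alpha < 360 / (n + 1))
}

u_index_kernel <- function(ref, nb, live) {
  mean(live$dbh[nb] > live$dbh[ref])
}

mc_index_kernel <- function(ref, nb, live, config) {
  n <- length(nb)
  M <- mean(live$species[nb] != live$species[ref])
  counted <- if (isTRUE(config$mingling_include_reference)) c(ref, nb) else nb
  nj <- table(live$species[counted])
  simpson_part <- 1 - sum(as.numeric(nj)^2) / (n + 1)^2
  nprime <- length(unique(live$species[nb]))
  min(1, max(0, M / 2 * (simpson_part + nprime / n)))
}

s_index_kernel <- function(ref, nb, fl) {
  z <- length(unique(fl[c(ref, nb)]))
  z / 3 * mean(fl[nb] == fl[ref])
}

ci_index_kernel <- function(ref, nb, live, config) {
  L <- live$height * live$crown_width * live$crown_length
  if (L[ref] <= 0) abort("reference tree has zero crown volume proxy",
                         class = "standopt_validation_error")
  Z <- pi * (live$crown_width[ref] / 2)^2
  ao <- circle_overlap_area(live$x[ref], live$y[ref], live$crown_width[ref],
                            live$x[nb], live$y[nb], live$crown_width[nb],
                            no_overlap_value = config$no_overlap_value)
  sum(ao * L[nb] / L[ref]) / Z
}

# --- single-unit public wrappers -------------------------------------------

resolve_unit <- function(unit, live) {
  ref <- match(unit$reference_id, live$id)
  nb <- match(unlist(unit$neighbour_ids), live$id)
  if (is.na(ref) || anyNA(nb)) abort("unit refers to unknown or dead trees",
                                     class = "standopt_validation_error")
  list(ref = ref, nb = nb)
}

#' Per-unit spatial structure indexes
#'
#' Single-unit forms of the five index kernels, mostly useful for checking
#' hand computations; [structure_indexes()] computes all units at once.
#' `unit` is a one-row slice of [voronoi_units()] output (or any list with
#' `reference_id` and `neighbour_ids`).
#'
#' @param unit A spatial structure unit.
#' @param x The [stand()] it belongs to.
#' @param config An [index_config()].
#' @param H_d Dominant height, for the stratification index.
#' @return The index value.
#' @name unit_indexes
NULL

#' @rdname unit_indexes
#' @export
uniform_angle_index <- function(unit, x, config = index_config()) {
  live <- living_points(x)
  u <- resolve_unit(unit, live)
  if (length(u$nb) < 2) abort("uniform angle index undefined for n < 2",
                              class = "standopt_validation_error")
  w_index_kernel(u$ref, u$nb, live, config)
}

#' @rdname unit_indexes
#' @export
neighborhood_comparison <- function(unit, x) {
  live <- living_points(x)
  u <- resolve_unit(unit, live)
  u_index_kernel(u$ref, u$nb, live)
}

#' @rdname unit_indexes
#' @export
complete_mingling <- function(unit, x, config = index_config()) {
  live <- living_points(x)
  u <- resolve_unit(unit, live)
  mc_index_kernel(u$ref, u$nb, live, config)
}

#' @rdname unit_indexes
#' @export
stratification_index <- function(unit, x, H_d = dominant_height(x, config),
                                 config = index_config()) {
  if (H_d <= 0) abort("dominant height must be positive",
                      class = "standopt_validation_error")
  live <- living_points(x)
  u <- resolve_unit(unit, live)
  fl <- layer_flag(live$height, live$rel_elev, H_d, config)
  s_index_kernel(u$ref, u$nb, fl)
}

#' @rdname unit_indexes
#' @export
crown_competition_index <- function(unit, x, config = index_config()) {
  live <- living_points(x)
  u <- resolve_unit(unit, live)
  ci_index_kernel(u$ref, u$nb, live, config)
}

row_sort <- function(m) {
  if (ncol(m) == 4) {
    # 4-element sorting network, vectorised over rows
    cex <- function(m, i, j) {
      lo <- pmin(m[, i], m[, j]); hi <- pmax(m[, i], m[, j])
      m[, i] <- lo; m[, j] <- hi; m
    }
    m <- cex(m, 1, 2); m <- cex(m, 3, 4); m <- cex(m, 1, 3)
    m <- cex(m, 2, 4); cex(m, 2, 3)
  } else {
    t(apply(m, 1, sort))
  }
}

# Uniform angle index for all reference trees at once.
w_index_all <- function(refs, adj, xs, ys, config) {
  nref <- length(refs)
  if (config$w_neighbors == "nearest") {
    k <- min(config$w_k, length(xs) - 1)
    if (k < 2) return(rep(NA_real_, nref))
    D2 <- outer(xs[refs], xs, "-")^2 + outer(ys[refs], ys, "-")^2
    D2[cbind(seq_len(nref), refs)] <- Inf
    az <- matrix(0, nref, k)
    for (j in seq_len(k)) {
      nb <- max.col(-D2, ties.method = "first")
      az[, j] <- azimuth_deg(xs[nb] - xs[refs], ys[nb] - ys[refs])
      D2[cbind(seq_len(nref), nb)] <- Inf
    }
    az <- row_sort(az)
    gaps <- cbind(az[, -1, drop = FALSE] - az[, -k, drop = FALSE],
                  360 - (az[, k] - az[, 1]))
    alpha <- pmin(gaps, 360 - gaps)
    rowMeans(alpha < 360 / (k + 1))
  } else {
    vapply(seq_len(nref), function(kk) {
      i <- refs[kk]; nb <- adj[[i]]
      if (length(nb) < 2) return(NA_real_)
      azv <- sort(azimuth_deg(xs[nb] - xs[i], ys[nb] - ys[i]))
      g <- c(diff(azv), 360 - (azv[length(azv)] - azv[1]))
      mean(pmin(g, 360 - g) < 360 / (length(nb) + 1))
    }, numeric(1))
  }
}

# --- whole-stand index table -----------------------------------------------

#' Per-tree structure indexes for all core reference trees
#'
#' Computes the uniform angle index (W), neighborhood comparison (U),
#' complete mingling (Mc), stratification index (S) and crown competition
#' index (CI) for every living core tree over its Voronoi spatial
#' structure unit. The result carries the stand means and the population
#' standard deviations used by the objective (for W the deviation is taken
#' over `|W - 0.496|`; any zero standard deviation is replaced by 1 so the
#' corresponding objective factor degenerates gracefully).
#'
#' @param x A [stand()].
#' @param config An [index_config()].
#' @return A tibble (class `index_table`) with columns `reference_id`,
#'   `n`, `W`, `U`, `Mc`, `S`, `CI`, and attributes `means`, `deltas`,
#'   `H_d`, `config`.
#' @export
structure_indexes <- function(x, config = index_config()) {
  stopifnot(is_stand(x))
  live <- living_points(x)
  adj <- voronoi_adjacency(live, stand_radius(x))
  core_ids <- partition_core_buffer(x)$core
  refs <- which(live$id %in% core_ids)
  if (!length(refs)) abort("stand has no living core trees",
                           class = "standopt_validation_error")
  H_d <- dominant_height(x, config)
  fl <- layer_flag(live$height, live$rel_elev, H_d, config)
  # hot path: the kernels are evaluated fully vectorised over all units at
  # once (the arithmetic is pinned against an independently derived fixture)
  xs <- live$x; ys <- live$y; dbhv <- live$dbh; cwv <- live$crown_width
  spint <- match(live$species, unique(live$species))
  nsp <- max(spint)
  L3 <- live$height * live$crown_width * live$crown_length
  nunit <- length(refs)
  nb_len <- lengths(adj[refs])
  ref_rep <- rep(refs, nb_len)
  unit_rep <- rep(seq_len(nunit), nb_len)
  nbv <- unlist(adj[refs], use.names = FALSE)
  by_unit <- function(v) {
    out <- numeric(nunit)
    out[sort(unique(unit_rep))] <- rowsum(v, unit_rep)[, 1]
    out
  }
  U <- by_unit((dbhv[nbv] > dbhv[ref_rep]) + 0) / nb_len
  # complete mingling: per-unit species counts via a (species x unit) table
  M <- by_unit((spint[nbv] != spint[ref_rep]) + 0) / nb_len
  gid <- (unit_rep - 1L) * nsp + spint[nbv]
  if (isTRUE(config$mingling_include_reference)) {
    gid <- c(gid, (seq_len(nunit) - 1L) * nsp + spint[refs])
  }
  cm <- matrix(tabulate(gid, nbins = nunit * nsp), nrow = nsp)
  Mc <- pmin(1, pmax(0, M / 2 * ((1 - colSums(cm^2) / (nb_len + 1)^2) +
                                   colSums(matrix(tabulate(
                                     (unit_rep - 1L) * nsp + spint[nbv],
                                     nbins = nunit * nsp), nrow = nsp) > 0) /
                                   nb_len)))
  # stratification: layer presence flags per unit, reference included in z
  frac_same <- by_unit((fl[nbv] == fl[ref_rep]) + 0) / nb_len
  z <- Reduce(`+`, lapply(c(-1L, 0L, 1L), function(l) {
    (by_unit((fl[nbv] == l) + 0) > 0 | fl[refs] == l) + 0
  }))
  S <- z / 3 * frac_same
  ao <- circle_overlap_area(xs[ref_rep], ys[ref_rep], cwv[ref_rep],
                            xs[nbv], ys[nbv], cwv[nbv],
                            no_overlap_value = config$no_overlap_value)
  CI <- by_unit(ao * L3[nbv] / L3[ref_rep]) / (pi * (cwv[refs] / 2)^2)
  W <- w_index_all(refs, adj, xs, ys, config)
  tab <- tibble::tibble(reference_id = live$id[refs], n = lengths(adj[refs]),
                        W = W, U = U, Mc = Mc, S = S, CI = CI)
  means <- c(W = mean(W, na.rm = TRUE), U = mean(U), Mc = mean(Mc),
             S = mean(S), CI = mean(CI))
  wdev <- abs(W - config$w_reference)
  pop_sd <- function(v) {
    v <- v[!is.na(v)]
    s <- sqrt(mean((v - mean(v))^2))
    if (!is.finite(s) || s == 0) 1 else s
  }
  deltas <- c(w_dev = pop_sd(wdev), U = pop_sd(U), Mc = pop_sd(Mc),
              S = pop_sd(S), CI = pop_sd(CI))
  tibble::new_tibble(tab, class = "index_table", means = means,
                     deltas = deltas, H_d = H_d, config = config)
}

#' @rdname structure_indexes
#' @export
index_means <- function(tab) attr(tab, "means")

#' @rdname structure_indexes
#' @export
index_deltas <- function(tab) attr(tab, "deltas")

#' Canopy density
#'
#' Fraction of the plot disk covered by the union of living crown disks,
#' evaluated on a fixed 0.25 m grid restricted to the disk. Deterministic
#' by construction, so the canopy-cover constraint (Cd >= 0.7) is a
#' reproducible check.
#'
#' @param x A [stand()].
#' @param grid_step Grid spacing (m).
#' @return Canopy density in `[0, 1]`.
#' @export
canopy_density <- function(x, grid_step = 0.25) {
  stopifnot(is_stand(x))
  R <- stand_radius(x)
  g <- seq(-R + grid_step / 2, R, by = grid_step)
  live <- tibble::as_tibble(x)[x$alive, ]
  nx <- length(g)
  inside <- outer(g^2, g^2, "+") <= R^2   # [ix, iy]
  if (nrow(live) == 0) return(0)
  covered <- matrix(FALSE, nx, nx)
  for (i in seq_len(nrow(live))) {
    r <- live$crown_width[i] / 2
    ix <- which(abs(g - live$x[i]) <= r)
    iy <- which(abs(g - live$y[i]) <= r)
    if (!length(ix) || !length(iy)) next
    d2 <- outer((g[ix] - live$x[i])^2, (g[iy] - live$y[i])^2, "+")
    covered[ix, iy] <- covered[ix, iy] | (d2 <= r^2)
  }
  sum(covered & inside) / sum(inside)
}

#' Competition covariates for prediction
#'
#' Standard forestry competition measures used as model features: the
#' Hegyi competition index (HCI, size-ratio over distance summed over
#' Voronoi neighbours), basal area in larger trees (BAL, m^2/ha, strict
#' inequality, zero for the largest stem), height-diameter ratio
#' (HDR, m/cm), plus the stand-level Reineke stand density index
#' (SDI, reference diameter 25 cm, slope 1.605) and stem density NT.
#'
#' @param x A [stand()].
#' @return A list with `per_tree` (tibble: `id`, `HCI`, `BAL`, `HDR`) and
#'   scalars `SDI`, `NT`.
#' @export
competition_covariates <- function(x) {
  stopifnot(is_stand(x))
  live <- living_points(x)
  adj <- voronoi_adjacency(live, stand_radius(x))
  n <- nrow(live)
  hci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    if (!length(nb)) next
    dist <- sqrt((live$x[nb] - live$x[i])^2 + (live$y[nb] - live$y[i])^2)
    if (any(dist == 0)) abort("coincident stems in Hegyi index",
                              class = "standopt_geometry_error")
    hci[i] <- sum(live$dbh[nb] / (live$dbh[i] * dist))
  }
  area <- stand_area_ha(x)
  ba <- pi * (live$dbh / 200)^2
  ord <- order(live$dbh, decreasing = TRUE)
  bal <- numeric(n)
  acc <- 0; k <- 1
  while (k <= n) {
    same <- which(live$dbh[ord] == live$dbh[ord[k]])
    idx <- ord[same]
    bal[idx] <- acc / area
    acc <- acc + sum(ba[idx])
    k <- max(same) + 1
  }
  NT <- n / area
  Dq <- sqrt(mean(live$dbh^2))
  list(per_tree = tibble::tibble(id = live$id, HCI = hci, BAL = bal,
                                 HDR = live$height / live$dbh),
       SDI = NT * (Dq / 25)^1.605, NT = NT)
}

#' Five-interval classification of a structure index
#'
#' The classic reporting bins for W, U and Mc: class 0 for an exact zero,
#' then `(0, 0.25]`, `(0.25, 0.5]`, `(0.5, 0.75]`, `(0.75, 1]` as classes
#' 1--4. For U the classes read dominant, sub-dominant, intermediate,
#' disadvantaged, absolutely disadvantaged; for Mc zero to complete
#' mixing; for W absolutely uniform to completely non-uniform.
#'
#' @param value Index value(s) in `[0, 1]`.
#' @return Integer class(es) 0--4.
#' @export
five_interval_class <- function(value) {
  stopifnot(all(value >= 0 & value <= 1))
  ifelse(value == 0, 0L, pmin(4L, as.integer(ceiling(value * 4 - 1e-12))))
}
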