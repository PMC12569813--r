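# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic circular-plot stand
#'
#' Emulates the measured plots this package targets: circular plots of
#' 12--35 m radius on sloped terrain, stem densities of roughly 1400--3900
#' trees/ha, a dominant conifer with low initial species mingling, DBH from
#' a Weibull law, and heights/crowns from species growth curves with
#' lognormal noise. Relative elevation is a planar ramp implied by slope
#' and aspect. Defaults follow a mid-sized plot (radius 20 m, 2109
#' trees/ha, mean DBH 14.5 cm, slope 17.7 degrees, NE aspect).
#'
#' @param radius Plot radius (m).
#' @param density Target stem density (trees/ha), within `[500, 5000]`.
#'   The realised tree count is exactly `round(density * area_ha)`.
#' @param species_mix Named vector of species proportions summing to 1.
#' @param clustering Spatial pattern control in `[-1, 1]`: 0 gives complete
#'   spatial randomness, positive values give a Thomas-type cluster process
#'   (1 = very tight clumps), negative values give a jittered triangular
#'   lattice (-1 = near-strict planting lattice).
#' @param slope,aspect Plot slope (degrees) and aspect (compass sector or
#'   azimuth degrees, the downslope direction).
#' @param mean_dbh Target mean DBH (cm) of the Weibull diameter law.
#' @param seed Integer seed; the same arguments and seed always reproduce
#'   the identical stand.
#' @param buffer_width Buffer width passed to [stand()].
#'
#' @return A [stand()].
#' @export
generate_stand <- function(radius = 20, density = 2109,
                           species_mix = c(pinus_yunnanensis = 0.9,
                                           quercus_acutissima = 0.06,
                                           betula_alnoides = 0.04),
                           clustering = 0, slope = 17.7, aspect = "NE",
                           mean_dbh = 14.5, seed, buffer_width = 2) {
  if (missing(seed)) abort("`seed` is required", class = "standopt_validation_error")
  if (density < 500 || density > 5000) {
    abort("`density` must lie in [500, 5000] trees/ha", class = "standopt_validation_error")
  }
  if (abs(sum(species_mix) - 1) > 1e-6) {
    abort("`species_mix` proportions must sum to 1", class = "standopt_validation_error")
  }
  if (abs(clustering) > 1) abort("`clustering` must lie in [-1, 1]",
                                 class = "standopt_validation_error")
  area_ha <- pi * radius^2 / 1e4
  n <- round(density * area_ha)
  if (n < 3) abort("density infeasible for this radius (< 3 trees)",
                   class = "standopt_validation_error")
  with_seed(seed, {
    pos <- generate_positions(n, radius, clustering)
    species <- sample(names(species_mix), n, replace = TRUE, prob = species_mix)
    dbh <- rweibull_truncated(n, mean_dbh)
    # dominant-conifer allometry for every stem: the broad-leaved curves in
    # the growth bank are calibrated at the replant diameter only
    height <- pmax(1.5, evaluate_growth_model("pinus_yunnanensis", "H", dbh) *
                     exp(rnorm(n, 0, 0.08)))
    crown_width <- pmax(0.3, evaluate_growth_model("pinus_yunnanensis", "CW", dbh) *
                          exp(rnorm(n, 0, 0.10)))
    crown_length <- pmin(pmax(0.3, evaluate_growth_model("pinus_yunnanensis", "CL", dbh) *
                                exp(rnorm(n, 0, 0.10))), 0.95 * height)
    age <- pmax(5L, as.integer(round(2.0 * dbh * runif(n, 0.85, 1.15))))
    az <- aspect_azimuth(aspect) * pi / 180
    downslope <- pos$x * sin(az) + pos$y * cos(az)
    rel_elev <- -downslope * tan(slope * pi / 180)
    rel_elev <- rel_elev - min(rel_elev)
    trees <- tibble::tibble(
      id = sprintf("t%04d", seq_len(n)), species = species,
      x = pos$x, y = pos$y, dbh = dbh, height = height,
      crown_width = crown_width, crown_length = crown_length,
      age = age, rel_elev = rel_elev, alive = TRUE, origin = "original")
    stand(trees, radius = radius, slope = slope, aspect = aspect,
          buffer_width = buffer_width)
  })
}

generate_positions <- function(n, radius, clustering) {
  if (clustering == 0) return(runif_disk(n, radius))
  if (clustering > 0) {
    # Thomas-type cluster process: small clumps (~8 stems) whose spread
    # shrinks quadratically toward 1.5% of the radius at clustering = 1
    nparents <- max(3L, round(n / 8))
    parents <- runif_disk(nparents, radius * 0.9)
    sd <- radius * (0.4 * (1 - clustering)^2 + 0.015)
    assign_parent <- sample.int(nparents, n, replace = TRUE)
    x <- numeric(n); y <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        xi <- parents$x[assign_parent[i]] + rnorm(1, 0, sd)
        yi <- parents$y[assign_parent[i]] + rnorm(1, 0, sd)
        if (xi^2 + yi^2 <= radius^2) break
      }
      x[i] <- xi; y[i] <- yi
    }
    return(list(x = x, y = y))
  }
  # jittered square planting lattice, filled from the plot centre outwards
  a <- sqrt(pi * radius^2 / n)
  kmax <- ceiling(radius / a) + 2
  grid <- expand.grid(i = -kmax:kmax, j = -kmax:kmax)
  gx <- grid$i * a
  gy <- grid$j * a
  ord <- order(gx^2 + gy^2)
  keep <- ord[seq_len(n)]
  jitter_sd <- a * (0.35 * (1 + clustering) + 0.02)
  x <- numeric(n); y <- numeric(n)
  for (k in seq_len(n)) {
    repeat {
      xi <- gx[keep[k]] + rnorm(1, 0, jitter_sd)
      yi <- gy[keep[k]] + rnorm(1, 0, jitter_sd)
      if (xi^2 + yi^2 <= radius^2) break
    }
    x[k] <- xi; y[k] <- yi
  }
  list(x = x, y = y)
}

runif_disk <- function(n, radius) {
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  list(x = r * sin(th), y = r * cos(th))
}

# Weibull DBH law (shape 2.6), left-truncated at the 5 cm measurement floor.
rweibull_truncated <- function(n, mean_dbh, shape = 2.6, floor_cm = 5) {
  scale <- mean_dbh / gamma(1 + 1 / shape)
  out <- stats::rweibull(n, shape, scale)
  while (any(bad <- out < floor_cm)) {
    out[bad] <- stats::rweibull(sum(bad), shape, scale)
  }
  out
}
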