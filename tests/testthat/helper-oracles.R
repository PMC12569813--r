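# Independent oracles and fixture builders shared across the test files.

# Brute-force Voronoi adjacency: trees i and j are neighbours iff some
# point of their perpendicular bisector lies inside the plot disk and is
# at least as close to i and j as to every other tree. Solved exactly as
# a 1-D interval intersection along the bisector line (a completely
# different route from the tessellation the package uses).
oracle_adjacency <- function(x, y, radius, eps = 1e-9) {
  n <- length(x)
  adj <- vector("list", n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      mx <- (x[i] + x[j]) / 2; my <- (y[i] + y[j]) / 2
      dx <- x[j] - x[i]; dy <- y[j] - y[i]
      len <- sqrt(dx^2 + dy^2)
      ux <- -dy / len; uy <- dx / len        # unit vector along the bisector
      # disk constraint: |M + t u|^2 <= R^2
      b <- mx * ux + my * uy
      cc <- mx^2 + my^2 - radius^2
      disc <- b^2 - cc
      if (disc <= 0) next
      lo <- -b - sqrt(disc); hi <- -b + sqrt(disc)
      # closer to i than to k: 2 p . (pk - pi) <= |pk|^2 - |pi|^2,
      # linear in the bisector parameter t (vectorised over k)
      k <- setdiff(seq_len(n), c(i, j))
      ddx <- x[k] - x[i]; ddy <- y[k] - y[i]
      rhs <- (x[k]^2 + y[k]^2 - x[i]^2 - y[i]^2) / 2 - (mx * ddx + my * ddy)
      slope <- ux * ddx + uy * ddy
      flat <- abs(slope) < 1e-14
      ok <- !any(flat & rhs < 0)
      if (ok && any(slope > 0)) hi <- min(hi, rhs[slope > 0] / slope[slope > 0])
      if (ok && any(slope < 0)) lo <- max(lo, rhs[slope < 0] / slope[slope < 0])
      if (ok && hi - lo > eps) {
        adj[[i]] <- c(adj[[i]], j)
        adj[[j]] <- c(adj[[j]], i)
      }
    }
  }
  lapply(adj, function(v) sort(unique(v)))
}

# Monte-Carlo two-disk overlap: sample uniformly in the tight bounding box
# of the intersection region and count the fraction inside both disks, so
# the estimator's own relative error stays far below the comparison band
# even for thin lenses. Assumes the circles genuinely intersect (the only
# case the analytic lens formula is exercised on).
oracle_lens_mc <- function(x1, y1, r1, x2, y2, r2, n = 1e6, seed = 1) {
  d <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  stopifnot(d < r1 + r2)
  if (d <= abs(r1 - r2)) {
    return(pi * min(r1, r2)^2)          # containment: exact
  }
  # work along the centre axis: circle 1 at 0, circle 2 at d
  xc <- (d^2 + r1^2 - r2^2) / (2 * d)   # radical line
  half_chord <- sqrt(max(0, r1^2 - xc^2))
  x_lo <- max(-r1, d - r2); x_hi <- min(r1, d + r2)
  # vertical extent: the chord endpoints, unless a circle's apex lies
  # inside the other circle (near-containment lenses)
  y_max <- half_chord + 1e-12
  if (d^2 + r1^2 <= r2^2) y_max <- max(y_max, r1)
  if (d^2 + r2^2 <= r1^2) y_max <- max(y_max, r2)
  set.seed(seed)
  px <- runif(n, x_lo, x_hi); py <- runif(n, -y_max, y_max)
  inside <- (px^2 + py^2 <= r1^2) & ((px - d)^2 + py^2 <= r2^2)
  mean(inside) * (x_hi - x_lo) * 2 * y_max
}

# A hand-positioned stand from explicit columns, defaulting the fields
# the test does not care about.
mini_stand <- function(x, y, radius = 20, dbh = 15, height = 10,
                       crown_width = 3, crown_length = 3,
                       species = "pinus_yunnanensis", age = 30,
                       rel_elev = 0, buffer_width = 2, slope = 0,
                       aspect = "N") {
  n <- length(x)
  trees <- tibble::tibble(
    id = sprintf("t%02d", seq_len(n)), species = rep_len(species, n),
    x = x, y = y, dbh = rep_len(dbh, n), height = rep_len(height, n),
    crown_width = rep_len(crown_width, n),
    crown_length = pmin(rep_len(crown_length, n), 0.9 * rep_len(height, n)),
    age = rep_len(age, n),
    rel_elev = rep_len(rel_elev, n), alive = TRUE, origin = "original")
  stand(trees, radius = radius, slope = slope, aspect = aspect,
        buffer_width = buffer_width)
}

# One spatial structure unit as a list, for the single-unit index ops.
unit_of <- function(reference_id, neighbour_ids) {
  list(reference_id = reference_id, neighbour_ids = list(neighbour_ids))
}

# Place trees at given azimuths (deg, clockwise from north) and ranges
# around a reference at the origin.
ring_stand <- function(azimuth, range = 5, radius = 20, ...) {
  a <- azimuth * pi / 180
  r <- rep_len(range, length(azimuth))
  mini_stand(x = c(0, r * sin(a)), y = c(0, r * cos(a)), radius = radius, ...)
}

# A stand engineered to sit in the ideal structural state: random pattern
# (W in the ideal band), evenly represented species placed by a local
# search that minimises same-species and concentrated neighbourhoods
# (high complete mingling), and diameters snapped to a 4 cm grid so size
# ties keep the neighborhood comparison at or below 0.5.
ideal_stand <- function(seed = 3) {
  s <- generate_stand(radius = 12, density = 2300, seed = seed,
                      species_mix = stats::setNames(rep(1 / 7, 7),
                                                    replant_species()))
  live <- tibble::as_tibble(s)
  live$dbh <- pmax(6, round(live$dbh / 4) * 4)
  adj <- standopt:::voronoi_adjacency(standopt:::living_points(s),
                                      stand_radius(s))
  pool <- replant_species()
  set.seed(seed)
  sp <- sample(pool, nrow(live), replace = TRUE)
  for (pass in 1:6) {
    for (i in sample(nrow(live))) {
      nb <- adj[[i]]
      sc <- sapply(pool, function(p) {
        v <- replace(sp, i, p)[nb]
        sum(table(v)^2) + 3 * sum(v == p)
      })
      best <- names(sc)[sc == min(sc)]
      sp[i] <- if (length(best) == 1) best else sample(best, 1)
    }
  }
  live$species <- sp
  stand(live, radius = stand_radius(s), slope = attr(s, "slope"),
        aspect = attr(s, "aspect"), buffer_width = stand_buffer(s))
}
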