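#' Harvest budget for a stand
#'
#' Selective harvesting is capped at 35% of the initial stem count.
#'
#' @param n_initial Stem count before any harvesting.
#' @return Maximum number of removable stems.
#' @export
harvest_budget <- function(n_initial) floor(0.35 * n_initial)

#' Randomly select harvest candidates
#'
#' Draws `k` distinct living core trees uniformly without replacement
#' (random selection is the felling rule that couples best with the
#' learning optimizer). A tree that is the last living individual of its
#' species is never selected, so harvesting cannot erase a species.
#'
#' @param x A [stand()].
#' @param k Number of candidates.
#' @param n_initial Initial stem count of the optimization (for the 35%
#'   budget).
#' @param n_harvested Stems already harvested in this optimization.
#' @param seed Optional seed; with the same seed the same candidate
#'   sequence is produced.
#' @return Character vector of `k` tree ids.
#' @export
select_harvest_candidates <- function(x, k, n_initial = nrow(x),
                                      n_harvested = 0, seed = NULL) {
  stopifnot(is_stand(x))
  if (k == 0) return(character(0))
  if (k > harvest_budget(n_initial) - n_harvested) {
    abort("harvest budget exhausted: request exceeds 35% of the initial stems",
          class = "standopt_budget_error")
  }
  draw <- function() {
    live <- tibble::as_tibble(x)[x$alive, ]
    core <- partition_core_buffer(x)$core
    pool <- live[live$id %in% core, ]
    counts <- table(live$species)
    chosen <- character(0)
    for (j in seq_len(k)) {
      eligible <- pool$id[!pool$id %in% chosen &
                            counts[pool$species] > 1]
      if (!length(eligible)) {
        abort("no eligible harvest candidates remain", class = "standopt_budget_error")
      }
      pick <- if (length(eligible) == 1) eligible else sample(eligible, 1)
      chosen <- c(chosen, pick)
      sp <- pool$species[match(pick, pool$id)]
      counts[sp] <- counts[sp] - 1
    }
    chosen
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Apply a harvest
#'
#' Removes the given living trees from the stand; all cached spatial
#' structure derives from the tree table, so downstream indexes are
#' recomputed lazily from the new state.
#'
#' @param x A [stand()].
#' @param ids Tree ids to fell.
#' @return The harvested [stand()].
#' @export
apply_harvest <- function(x, ids) {
  stopifnot(is_stand(x))
  if (!length(ids)) return(x)
  unknown <- setdiff(ids, x$id[x$alive])
  if (length(unknown)) {
    abort(sprintf("cannot harvest unknown or dead tree id '%s'", unknown[1]),
          class = "standopt_validation_error")
  }
  restand(tibble::as_tibble(x)[!x$id %in% ids, ], x)
}

#' Maximum number of replants for a stand
#'
#' The post-replanting density may not exceed 3333 stems/ha; the per-plot
#' cap is `floor(3333 * area_ha)` minus the current living stem count.
#'
#' @param x A [stand()].
#' @return Number of additional stems allowed.
#' @export
replant_cap <- function(x) {
  max(0L, floor(3333 * stand_area_ha(x)) - sum(x$alive))
}

# Relative elevation at an arbitrary location, assuming the planar
# slope/aspect ramp the generator uses. Robust to stands whose rel_elev was
# measured rather than generated (median-shift fit).
rel_elev_at <- function(x, px, py) {
  slope <- attr(x, "slope")
  if (is.null(slope) || slope == 0) return(rep(0, length(px)))
  az <- aspect_azimuth(attr(x, "aspect")) * pi / 180
  tanb <- tan(slope * pi / 180)
  shift <- stats::median(x$rel_elev + (x$x * sin(az) + x$y * cos(az)) * tanb)
  pmax(0, shift - (px * sin(az) + py * cos(az)) * tanb)
}

point_in_triangle <- function(px, py, x1, y1, x2, y2, x3, y3) {
  d1 <- (px - x2) * (y1 - y2) - (x1 - x2) * (py - y2)
  d2 <- (px - x3) * (y2 - y3) - (x2 - x3) * (py - y3)
  d3 <- (px - x1) * (y3 - y1) - (x3 - x1) * (py - y1)
  neg <- (d1 < 0) | (d2 < 0) | (d3 < 0)
  pos <- (d1 > 0) | (d2 > 0) | (d3 > 0)
  !(neg & pos)
}

containing_triangle_area <- function(triangles, live, px, py) {
  for (i in seq_len(nrow(triangles))) {
    v <- match(c(triangles$id1[i], triangles$id2[i], triangles$id3[i]), live$id)
    if (point_in_triangle(px, py, live$x[v[1]], live$y[v[1]],
                          live$x[v[2]], live$y[v[2]],
                          live$x[v[3]], live$y[v[3]]))
      return(triangles$area[i])
  }
  0
}

#' Replanting foreground index of a candidate location
#'
#' Scores a candidate planting site for a given species by inserting a
#' virtual 5 cm replant at the location and evaluating
#' `RFI = (1 + DAA/d_DAA)(1 + Mc/d_Mc)(1 + U/d_U) / (1 + CI/d_CI)` where
#' `DAA` is the area of the Delaunay triangle containing the location and
#' `Mc`, `U`, `CI` come from the virtual tree's would-be Voronoi unit; the
#' `d` terms are the standard deviations of the corresponding quantities
#' in the current stand. The virtual tree is discarded afterwards. A large
#' canopy gap, high prospective mingling and a suppressed size position
#' all raise the score; crown competition lowers it (set
#' `u_in_denominator = TRUE` to penalise rather than reward a suppressed
#' position).
#'
#' @param x A [stand()].
#' @param px,py Candidate location (m), inside the core region.
#' @param species Species of the virtual replant.
#' @param config An [index_config()].
#' @param context Optional precomputed list from [rfi_context()].
#' @param u_in_denominator Move the U factor to the denominator.
#' @return The RFI value.
#' @export
replanting_foreground_index <- function(x, px, py, species,
                                        config = index_config(),
                                        context = NULL,
                                        u_in_denominator = FALSE) {
  if (sqrt(px^2 + py^2) > stand_radius(x) - stand_buffer(x)) {
    abort("candidate planting location lies outside the core region",
          class = "standopt_validation_error")
  }
  ctx <- context %||% rfi_context(x, config)
  daa <- containing_triangle_area(ctx$triangles, ctx$live, px, py)
  virt <- initialize_replant(species, px, py, id = ".virtual",
                             rel_elev = rel_elev_at(x, px, py))
  live2 <- dplyr::bind_rows(ctx$live, virt)
  adj2 <- voronoi_adjacency(live2, stand_radius(x))
  vi <- nrow(live2)
  nb <- adj2[[vi]]
  if (!length(nb)) return(0)
  mc <- mc_index_kernel(vi, nb, live2, config)
  u <- u_index_kernel(vi, nb, live2)
  ci <- ci_index_kernel(vi, nb, live2, config)
  d <- ctx$deltas
  u_factor <- 1 + u / d[["U"]]
  num <- (1 + daa / d[["DAA"]]) * (1 + mc / d[["Mc"]])
  den <- 1 + ci / d[["CI"]]
  if (u_in_denominator) den <- den * u_factor else num <- num * u_factor
  num / den
}

#' @rdname replanting_foreground_index
#' @export
rfi_context <- function(x, config = index_config()) {
  live <- living_points(x)
  triangles <- delaunay_triangles(x)
  tab <- structure_indexes(x, config)
  d <- index_deltas(tab)
  pop_sd <- function(v) {
    s <- sqrt(mean((v - mean(v))^2)); if (!is.finite(s) || s == 0) 1 else s
  }
  list(live = live, triangles = triangles,
       deltas = c(DAA = pop_sd(triangles$area), Mc = d[["Mc"]],
                  U = d[["U"]], CI = d[["CI"]]))
}

#' Propose planting locations in canopy gaps
#'
#' Iteratively places `m` replants: at each step the incenters of the `K`
#' largest Delaunay triangles are candidate sites (kept at least
#' `edge_margin` inside the core boundary and `stem_margin` from any
#' stem), each is scored with the replanting foreground index for the next
#' species in the round-robin over the seven replantable species, the best
#' site is planted, and the stand is retriangulated. With `K = 1` the rule
#' degenerates to pure max-area-incenter planting.
#'
#' @param x A [stand()].
#' @param m Number of plants to place.
#' @param K Number of candidate triangles per step.
#' @param species_offset 0-based offset into the species round-robin
#'   (continues an earlier plan).
#' @param config An [index_config()].
#' @param edge_margin,stem_margin Placement margins (m).
#' @return A tibble plan: `x`, `y`, `species`, `rfi`, one row per plant,
#'   in planting order.
#' @export
propose_planting_locations <- function(x, m, K = 10, species_offset = 0,
                                       config = index_config(),
                                       edge_margin = 1, stem_margin = 0.5) {
  stopifnot(is_stand(x))
  if (m == 0) {
    return(tibble::tibble(x = numeric(0), y = numeric(0),
                          species = character(0), rfi = numeric(0)))
  }
  if (sum(x$alive) < 3) abort("need at least 3 living trees to triangulate",
                              class = "standopt_geometry_error")
  species_pool <- replant_species()
  work <- x
  out <- vector("list", m)
  core_r <- stand_radius(x) - stand_buffer(x) - edge_margin
  # index standard deviations are computed once against the base stand and
  # reused across the plan: they change negligibly per planted stem, and
  # recomputing them per step would dominate the cost of planning
  base_deltas <- rfi_context(x, config)$deltas
  for (step in seq_len(m)) {
    sp <- species_pool[(species_offset + step - 1) %% length(species_pool) + 1]
    live_w <- living_points(work)
    tri <- delaunay_triangles(work)
    ctx <- list(live = live_w, triangles = tri, deltas = base_deltas)
    ok <- sqrt(tri$inc_x^2 + tri$inc_y^2) <= core_r
    if (any(ok)) {
      mind <- vapply(which(ok), function(i) {
        min(sqrt((ctx$live$x - tri$inc_x[i])^2 + (ctx$live$y - tri$inc_y[i])^2))
      }, numeric(1))
      ok[which(ok)[mind < stem_margin]] <- FALSE
    }
    cand <- head(which(ok), K)
    if (!length(cand)) {
      abort("no admissible planting location found", class = "standopt_geometry_error")
    }
    scores <- vapply(cand, function(i) {
      replanting_foreground_index(work, tri$inc_x[i], tri$inc_y[i], sp,
                                  config = config, context = ctx)
    }, numeric(1))
    best <- cand[which.max(scores)]
    out[[step]] <- tibble::tibble(x = tri$inc_x[best], y = tri$inc_y[best],
                                  species = sp, rfi = max(scores))
    newtree <- initialize_replant(sp, tri$inc_x[best], tri$inc_y[best],
                                  id = sprintf(".plan%03d", step),
                                  rel_elev = rel_elev_at(work, tri$inc_x[best],
                                                         tri$inc_y[best]))
    work <- restand(dplyr::bind_rows(tibble::as_tibble(work), newtree), work)
  }
  dplyr::bind_rows(out)
}

#' Apply a replanting plan
#'
#' Appends initialized replants (fresh ids, `origin = "replanted"`) at the
#' planned locations.
#'
#' @param x A [stand()].
#' @param plan A plan tibble from [propose_planting_locations()], or its
#'   first `count` rows.
#' @param id_prefix Prefix for the new tree ids.
#' @return The replanted [stand()].
#' @export
apply_replant <- function(x, plan, id_prefix = "r") {
  stopifnot(is_stand(x))
  if (nrow(plan) == 0) return(x)
  if (nrow(plan) > replant_cap(x)) {
    abort("replanting plan exceeds the 3333 stems/ha density cap",
          class = "standopt_budget_error")
  }
  existing <- sum(grepl(paste0("^", id_prefix, "[0-9]+$"), x$id))
  trees <- purrr::map_dfr(seq_len(nrow(plan)), function(i) {
    initialize_replant(plan$species[i], plan$x[i], plan$y[i],
                       id = sprintf("%s%04d", id_prefix, existing + i),
                       rel_elev = rel_elev_at(x, plan$x[i], plan$y[i]))
  })
  restand(dplyr::bind_rows(tibble::as_tibble(x), trees), x)
}

#' Curve-trend search for the best replant count
#'
#' Windowed three-point search over replant counts: evaluate the objective
#' at `{c - s, c, c + s}`; slide the window by `s` in the ascending
#' direction while the trend is monotone, shrink the spacing around an
#' interior maximum, and stop when the spacing has contracted to 1 and the
#' window cannot move. On unimodal profiles this finds the exact argmax;
#' on multimodal ones it returns a local argmax at least as good as its
#' start.
#'
#' @param evaluate Function mapping an integer count in `[0, cap]` to an
#'   objective value.
#' @param cap Maximum count (budget).
#' @param spacing Initial window spacing.
#' @param start Starting count (default `spacing`).
#' @return List with `count` (best count) and `evaluations` (tibble of
#'   all counts tried and their values).
#' @export
curve_trend_count_search <- function(evaluate, cap, spacing = 1,
                                     start = spacing) {
  if (cap <= 0) {
    return(list(count = 0L, evaluations = tibble::tibble(count = integer(0),
                                                         value = numeric(0))))
  }
  memo <- new.env(parent = emptyenv())
  f <- function(c) {
    key <- as.character(c)
    if (is.null(memo[[key]])) memo[[key]] <- evaluate(c)
    memo[[key]]
  }
  clamp <- function(c) min(cap, max(0L, as.integer(c)))
  s <- max(1L, as.integer(spacing))
  c0 <- clamp(start)
  for (iter in seq_len(500)) {
    lo <- clamp(c0 - s); hi <- clamp(c0 + s)
    flo <- f(lo); fc <- f(c0); fhi <- f(hi)
    if (hi > c0 && fhi > fc) {
      c0 <- hi
    } else if (lo < c0 && flo > fc) {
      c0 <- lo
    } else if (s > 1L) {
      s <- max(1L, s %/% 2L)
    } else {
      break
    }
  }
  counts <- as.integer(ls(memo))
  values <- vapply(as.character(counts), function(k) memo[[k]], numeric(1))
  list(count = counts[which.max(values)],
       evaluations = tibble::tibble(count = counts, value = values))
}
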