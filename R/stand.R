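#' @importFrom rlang .data abort
#' @importFrom stats runif rnorm sd setNames predict quantile
#' @importFrom utils head tail
NULL

#' Replantable species pool
#'
#' Species codes for the seven native species used in replanting. Replants
#' are drawn from this pool in equal proportions.
#'
#' @return Character vector of species codes.
#' @export
replant_species <- function() {
  c("pinus_yunnanensis", "pinus_armandii", "quercus_acutissima",
    "vaccinium_bracteatum", "camellia_sinensis", "betula_alnoides",
    "ternstroemia_gymnanthera")
}

tree_columns <- function() {
  c("id", "species", "x", "y", "dbh", "height", "crown_width",
    "crown_length", "age", "rel_elev", "alive", "origin")
}

#' Construct a circular-plot stand
#'
#' A stand is a tibble of trees (one row per stem) carrying plot metadata as
#' attributes. Coordinates are Cartesian metres with the plot centre at the
#' origin and y pointing north; azimuths are measured clockwise from north.
#'
#' @param trees Data frame with columns `id`, `species`, `x`, `y`, `dbh`
#'   (cm), `height` (m), `crown_width` (m, crown projection diameter),
#'   `crown_length` (m), `age` (years), `rel_elev` (m above the plot
#'   minimum), `alive` (logical), `origin` (`"original"` or `"replanted"`).
#' @param radius Plot radius in metres.
#' @param slope Slope in degrees.
#' @param aspect Aspect as one of `"N"`, `"NE"`, `"E"`, `"SE"`, `"S"`,
#'   `"SW"`, `"W"`, `"NW"`, or an azimuth in degrees.
#' @param buffer_width Width of the edge-correction buffer in metres
#'   (default 2): trees within `buffer_width` of the plot boundary act only
#'   as neighbours, never as reference trees.
#' @param survey_year Optional survey year, kept as provenance.
#' @param validate Check invariants (default `TRUE`).
#'
#' @return A `stand` object (tibble subclass).
#' @export
stand <- function(trees, radius, slope = 0, aspect = "N", buffer_width = 2,
                  survey_year = NA_integer_, validate = TRUE) {
  trees <- tibble::as_tibble(trees)
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0) {
    abort("`radius` must be a single positive number.", class = "standopt_validation_error")
  }
  if (buffer_width < 0 || buffer_width >= radius) {
    abort("`buffer_width` must lie in [0, radius).", class = "standopt_validation_error")
  }
  missing <- setdiff(tree_columns(), names(trees))
  if (length(missing)) {
    abort(paste0("tree table is missing column(s): ", paste(missing, collapse = ", ")),
          class = "standopt_schema_error")
  }
  trees <- trees[tree_columns()]
  trees$id <- as.character(trees$id)
  trees$species <- as.character(trees$species)
  trees$alive <- as.logical(trees$alive)
  out <- tibble::new_tibble(trees, class = "stand",
                            radius = as.numeric(radius),
                            slope = as.numeric(slope),
                            aspect = aspect,
                            buffer_width = as.numeric(buffer_width),
                            survey_year = survey_year)
  if (validate) validate_stand(out)
  out
}

#' @export
print.stand <- function(x, ...) {
  cat(sprintf("<stand> radius %.1f m (%.4f ha), buffer %.1f m, slope %.1f deg, aspect %s\n",
              stand_radius(x), stand_area_ha(x), stand_buffer(x),
              attr(x, "slope"), format(attr(x, "aspect"))))
  cat(sprintf("  %d trees (%d living), %d species\n",
              nrow(x), sum(x$alive), length(unique(x$species[x$alive]))))
  NextMethod()
}

#' @rdname stand
#' @param x A `stand` object.
#' @export
stand_radius <- function(x) attr(x, "radius")

#' @rdname stand
#' @export
stand_buffer <- function(x) attr(x, "buffer_width")

#' @rdname stand
#' @export
stand_area_ha <- function(x) pi * attr(x, "radius")^2 / 1e4

#' @rdname stand
#' @export
is_stand <- function(x) inherits(x, "stand")

#' Validate stand invariants
#'
#' Checks the per-tree invariants (positive sizes, crown length not above
#' height, coordinates inside the plot radius, DBH at least 5 cm) and
#' signals a validation error naming the first offending row.
#'
#' @param x A `stand`.
#' @return `x`, invisibly.
#' @export
validate_stand <- function(x) {
  stopifnot(is_stand(x))
  r <- sqrt(x$x^2 + x$y^2)
  checks <- list(
    "duplicated tree id"            = duplicated(x$id),
    "non-finite coordinate"         = !is.finite(x$x) | !is.finite(x$y),
    "coordinate outside plot radius" = r > stand_radius(x) + 1e-9,
    "dbh below 5 cm"                = !is.finite(x$dbh) | x$dbh < 5,
    "non-positive height"           = !is.finite(x$height) | x$height <= 0,
    "non-positive crown_width"      = !is.finite(x$crown_width) | x$crown_width <= 0,
    "crown_length above height"     = !is.finite(x$crown_length) | x$crown_length <= 0 |
                                       x$crown_length > x$height + 1e-9,
    "negative rel_elev"             = !is.finite(x$rel_elev) | x$rel_elev < -1e-9,
    "bad origin"                    = !x$origin %in% c("original", "replanted")
  )
  for (msg in names(checks)) {
    bad <- which(checks[[msg]])
    if (length(bad)) {
      abort(sprintf("%s in row %d (id %s)", msg, bad[1], x$id[bad[1]]),
            class = "standopt_validation_error")
    }
  }
  invisible(x)
}

#' Diameter class of a tree
#'
#' Classification starts from a DBH of 6 cm with 2 cm half-open intervals
#' `[6,8), [8,10), ...` giving classes 1, 2, .... Trees with
#' `5 <= dbh < 6` (freshly replanted stock) fall into a pre-class 0 that is
#' excluded from the diameter-class count, so planting cannot change the
#' class diversity.
#'
#' @param dbh Numeric vector of diameters (cm).
#' @return Integer vector of class indexes (0 = pre-class).
#' @export
diameter_class <- function(dbh) {
  ifelse(dbh < 6, 0L, 1L + as.integer(floor((dbh - 6) / 2)))
}

#' Summarise a stand
#'
#' Non-spatial summary: stem density, number of diameter classes `D`
#' (classes at or above 6 cm actually present), number of species `T` among
#' living trees, quadratic mean DBH, and per-class / per-species counts.
#' Dead trees are excluded throughout.
#'
#' @param x A `stand`.
#' @return A list of class `stand_summary`.
#' @export
stand_summary <- function(x) {
  stopifnot(is_stand(x))
  keep <- x$alive
  if (!any(keep)) abort("stand has no living trees", class = "standopt_validation_error")
  dbh <- x$dbh[keep]
  cls <- diameter_class(dbh)
  cls_tab <- table(cls)
  sp_tab <- table(x$species[keep])
  structure(list(
    n_trees = sum(keep),
    density_per_ha = sum(keep) / stand_area_ha(x),
    n_diameter_classes = length(unique(cls[cls >= 1L])),
    n_species = length(sp_tab),
    quadratic_mean_dbh = sqrt(mean(dbh^2)),
    class_counts = tibble::tibble(class = as.integer(names(cls_tab)),
                                  n = as.integer(cls_tab)),
    species_counts = tibble::tibble(species = names(sp_tab),
                                    n = as.integer(sp_tab)),
    area_ha = stand_area_ha(x)
  ), class = "stand_summary")
}

#' @export
print.stand_summary <- function(x, ...) {
  cat(sprintf("stand summary: %d living trees, %.1f trees/ha, D = %d classes, T = %d species, Dq = %.1f cm\n",
              x$n_trees, x$density_per_ha, x$n_diameter_classes,
              x$n_species, x$quadratic_mean_dbh))
  invisible(x)
}

#' @export
tidy.stand_summary <- function(x, ...) {
  tibble::tibble(
    n_trees = x$n_trees, density_per_ha = x$density_per_ha,
    n_diameter_classes = x$n_diameter_classes, n_species = x$n_species,
    quadratic_mean_dbh = x$quadratic_mean_dbh
  )
}

# Rebuild a stand from a (possibly modified) tree tibble, keeping metadata.
restand <- function(trees, template, validate = FALSE) {
  stand(trees, radius = stand_radius(template), slope = attr(template, "slope"),
        aspect = attr(template, "aspect"), buffer_width = stand_buffer(template),
        survey_year = attr(template, "survey_year"), validate = validate)
}

# Azimuth in degrees, clockwise from north (y axis).
azimuth_deg <- function(dx, dy) {
  (atan2(dx, dy) * 180 / pi) %% 360
}

aspect_azimuth <- function(aspect) {
  if (is.numeric(aspect)) return(aspect %% 360)
  lut <- c(N = 0, NE = 45, E = 90, SE = 135, S = 180, SW = 225, W = 270, NW = 315)
  if (!aspect %in% names(lut)) {
    abort(sprintf("unknown aspect '%s'", aspect), class = "standopt_validation_error")
  }
  unname(lut[[aspect]])
}
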