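#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_path
#'   facet_wrap labs theme_minimal coord_fixed annotate scale_size_area
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Plot a stand map
#'
#' Stems at their plot coordinates, point size proportional to DBH,
#' coloured by species, with the plot and core boundaries drawn.
#'
#' @param object A [stand()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stand <- function(object, ...) {
  R <- stand_radius(object)
  circle <- function(r) {
    th <- seq(0, 2 * pi, length.out = 181)
    tibble::tibble(x = r * cos(th), y = r * sin(th))
  }
  live <- tibble::as_tibble(object)[object$alive, ]
  ggplot(live, aes(x = .data$x, y = .data$y)) +
    geom_path(data = circle(R), linetype = 1, colour = "grey30") +
    geom_path(data = circle(R - stand_buffer(object)),
              linetype = 2, colour = "grey60") +
    geom_point(aes(size = .data$dbh, colour = .data$species,
                   shape = .data$origin), alpha = 0.8) +
    scale_size_area(max_size = 4) +
    coord_fixed() +
    labs(x = "x (m)", y = "y (m)", size = "DBH (cm)") +
    theme_minimal()
}

#' Plot per-tree index distributions
#'
#' @param object An `index_table` from [structure_indexes()].
#' @param ... Unused.
#' @return A ggplot of the five index distributions.
#' @export
autoplot.index_table <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("W", "U", "Mc", "S", "CI"),
                              names_to = "index", values_to = "value")
  ggplot(long, aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue", colour = "white") +
    facet_wrap(~index, scales = "free") +
    labs(x = NULL, y = "reference trees") +
    theme_minimal()
}

#' Plot the optimization progress
#'
#' @param object A `stand_optimization` from [optimize_madqn()] or
#'   [optimize_maql()].
#' @param ... Unused.
#' @return A ggplot of best objective vs episode.
#' @export
autoplot.stand_optimization <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$episode, y = .data$best_L)) +
    geom_line() +
    ggplot2::geom_hline(yintercept = object$initial_L, linetype = 2) +
    labs(x = "episode", y = "best feasible L",
         title = sprintf("%s: L %.3f -> %.3f", object$algorithm,
                         object$initial_L, object$best_L)) +
    theme_minimal()
}

#' Plot a dynamic-optimization trajectory
#'
#' @param object A `stand_trajectory` from [dynamic_optimize()].
#' @param ... Unused.
#' @return A ggplot of L and the five index means against years.
#' @export
autoplot.stand_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("L", "W", "U", "Mc", "S", "CI"),
                              names_to = "quantity", values_to = "value")
  ggplot(long, aes(x = .data$years, y = .data$value)) +
    geom_line() + geom_point() +
    facet_wrap(~quantity, scales = "free_y") +
    labs(x = "years", y = NULL) +
    theme_minimal()
}
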