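#' Read a tree-list CSV as a stand
#'
#' The file format is a plain CSV with the twelve tree columns, preceded by
#' a metadata block of `#`-prefixed `key: value` lines carrying the plot
#' metadata (`radius_m`, `slope_deg`, `aspect`, `buffer_width_m`,
#' `survey_year`). [write_stand()] produces this format and
#' `read_stand(write_stand(s))` reproduces `s` field for field.
#'
#' @param path Path to a tree-list CSV.
#' @return A [stand()].
#' @export
read_stand <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_0-9]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  for (key in c("radius_m", "buffer_width_m")) {
    if (is.null(meta[[key]])) {
      abort(sprintf("metadata key '%s' missing from %s", key, path),
            class = "standopt_schema_error")
    }
  }
  trees <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                           col_types = readr::cols(
                             id = readr::col_character(),
                             species = readr::col_character(),
                             alive = readr::col_logical(),
                             origin = readr::col_character(),
                             .default = readr::col_double()
                           ))
  missing <- setdiff(tree_columns(), names(trees))
  if (length(missing)) {
    abort(paste0("tree-list file is missing column(s): ", paste(missing, collapse = ", ")),
          class = "standopt_schema_error")
  }
  num_cols <- setdiff(tree_columns(), c("id", "species", "alive", "origin"))
  for (cc in num_cols) {
    bad <- which(!is.finite(trees[[cc]]))
    if (length(bad)) {
      abort(sprintf("non-numeric value in column '%s', row %d", cc, bad[1]),
            class = "standopt_validation_error")
    }
  }
  aspect <- meta[["aspect"]] %||% "N"
  if (grepl("^[-0-9.]+$", aspect)) aspect <- as.numeric(aspect)
  stand(trees,
        radius = as.numeric(meta[["radius_m"]]),
        slope = as.numeric(meta[["slope_deg"]] %||% 0),
        aspect = aspect,
        buffer_width = as.numeric(meta[["buffer_width_m"]]),
        survey_year = suppressWarnings(as.integer(meta[["survey_year"]] %||% NA)))
}

#' Write a stand to a tree-list CSV
#'
#' @param x A [stand()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stand <- function(x, path) {
  stopifnot(is_stand(x))
  meta <- c(
    sprintf("# radius_m: %.10g", stand_radius(x)),
    sprintf("# slope_deg: %.10g", attr(x, "slope")),
    sprintf("# aspect: %s", format(attr(x, "aspect"))),
    sprintf("# buffer_width_m: %.10g", stand_buffer(x)),
    sprintf("# survey_year: %s", format(attr(x, "survey_year")))
  )
  writeLines(meta, path)
  body <- readr::format_csv(tibble::as_tibble(x))
  cat(body, file = path, append = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
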