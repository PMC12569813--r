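# Species growth-curve bank used to size replanted stock (and, with noise,
# the synthetic generator's allometry). Each row is one fitted curve for
# height (H), crown width (CW) or crown length (CL) against DBH (cm).
# `factor_5cm` is the published value of the curve at the 5 cm
# replant-initialization diameter. Rows whose printed parameters do not
# reproduce that value carry an additive calibration offset so that the
# bank returns the published stand factor exactly at 5 cm.
growth_model_rows <- function() {
  tibble::tribble(
    ~species,                   ~variable, ~form,                 ~a,       ~b,      ~c,      ~d,     ~factor_5cm,
    "pinus_yunnanensis",        "H",  "chapman_richards",     16.7289,  0.0871,  1.1212,  NA,      5.20,
    "pinus_yunnanensis",        "CW", "power",                 0.5652,  0.7023,  NA,      NA,      1.74,
    "pinus_yunnanensis",        "CL", "power",                 0.3646,  0.7984,  NA,      NA,      1.32,
    "pinus_armandii",           "H",  "chapman_richards",     17.0986,  0.0816,  0.9258,  NA,      5.19,
    "pinus_armandii",           "CW", "logistic",              4.2420,  2.2677,  0.0523,  NA,      1.54,
    "pinus_armandii",           "CL", "chapman_richards",     41.0291,  0.0289,  0.4971,  NA,      2.56,
    "quercus_acutissima",       "H",  "shifted_exponential",   1.0822,  3.2453, 17.2914,  3.5632,  5.12,
    "quercus_acutissima",       "CW", "cubic",                 0.2574,  0.2442, -0.0022,  NA,      1.82,
    "quercus_acutissima",       "CL", "power",                 0.4833,  0.6892,  NA,      NA,      1.47,
    "betula_alnoides",          "H",  "reciprocal_dbh",        0.0211,  0.6850,  NA,      NA,      6.33,
    "betula_alnoides",          "CW", "logistic",              3.0360,  0.8446,  0.1345,  NA,      2.12,
    "betula_alnoides",          "CL", "power",                 2.0317,  0.2375,  NA,      NA,      2.98,
    "vaccinium_bracteatum",     "H",  "exp_decay",             2.2004,  0.5011,  4.9997,  NA,      2.20,
    "vaccinium_bracteatum",     "CW", "logistic",              2.9716,  1.0269, -0.0314,  NA,      1.35,
    "vaccinium_bracteatum",     "CL", "logistic",              1.0123,  0.7829,  4.0326,  NA,      1.01,
    "camellia_sinensis",        "H",  "chapman_richards",     10.0002,  0.2114,  1.9997,  NA,      4.26,
    "camellia_sinensis",        "CW", "logistic",              1.9389,  0.5366,  0.1097,  NA,      1.48,
    "camellia_sinensis",        "CL", "power",                 0.9009,  0.3250,  NA,      NA,      1.55,
    "ternstroemia_gymnanthera", "H",  "quadratic",             2.9963,  0.9818, -0.1110,  NA,      5.13,
    "ternstroemia_gymnanthera", "CW", "log_linear",           -0.1710,  0.2247,  NA,      NA,      1.21,
    "ternstroemia_gymnanthera", "CL", "chapman_richards",      1.9964,  0.1762,  1.0005,  NA,      1.17
  )
}

growth_form_eval <- function(form, dbh, a, b, c, d) {
  switch(form,
    chapman_richards    = a * (1 - exp(-b * dbh))^c,
    power               = a * dbh^b,
    logistic            = a / (1 + b * exp(-c * dbh)),
    reciprocal_dbh      = 1 / (a + b / dbh),
    exp_decay           = a * exp(-b / dbh^c),
    quadratic           = a + b * dbh + c * dbh^2,
    cubic               = a + b * dbh^2 + c * dbh^3,
    log_linear          = exp(a + b * log(dbh)),
    shifted_exponential = a * exp(b + c / (dbh + 1)) + d,
    abort(sprintf("unknown growth-model form '%s'", form))
  )
}

#' Species growth-model bank
#'
#' Returns the shipped bank of height / crown-width / crown-length curves
#' for the seven replantable species, one row per (species, variable), with
#' the fitted parameters, the published curve value at the 5 cm replant
#' diameter, and the additive calibration offset applied where the
#' parameters do not reproduce that value to two decimals. The calibrated
#' curves are trusted at and near the initialization diameter; projection
#' of established trees is the prediction module's job, not this bank's.
#'
#' @return A tibble with columns `species`, `variable`, `form`, `a`--`d`,
#'   `factor_5cm`, `raw_5cm`, `offset`.
#' @export
growth_model_bank <- function() {
  bank <- growth_model_rows()
  bank$raw_5cm <- vapply(seq_len(nrow(bank)), function(i) {
    growth_form_eval(bank$form[i], 5, bank$a[i], bank$b[i], bank$c[i], bank$d[i])
  }, numeric(1))
  bank$offset <- ifelse(round(bank$raw_5cm, 2) == bank$factor_5cm,
                        0, bank$factor_5cm - bank$raw_5cm)
  bank
}

the_bank <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- growth_model_bank()
    cache
  }
})

#' Evaluate a species growth model
#'
#' @param species Species code (see [replant_species()]).
#' @param variable One of `"H"`, `"CW"`, `"CL"`.
#' @param dbh DBH in cm (vectorised), positive.
#' @return Predicted height / crown width / crown length (m).
#' @export
evaluate_growth_model <- function(species, variable, dbh) {
  stopifnot(all(dbh > 0))
  bank <- the_bank()
  row <- bank[bank$species == species & bank$variable == variable, ]
  if (nrow(row) != 1) {
    abort(sprintf("no growth model for species '%s', variable '%s'", species, variable),
          class = "standopt_validation_error")
  }
  growth_form_eval(row$form, dbh, row$a, row$b, row$c, row$d) + row$offset
}

#' Initialize a replanted tree
#'
#' Replants enter the stand with a DBH of 5 cm and an age of 5 years;
#' height, crown width and crown length come from the species growth bank
#' evaluated at that diameter. The tree is alive, tagged
#' `origin = "replanted"`, and falls in diameter pre-class 0 so the
#' stand's diameter-class count is unchanged by planting.
#'
#' @param species Species code.
#' @param x,y Planting location (m, plot-centred).
#' @param id Tree id to assign.
#' @param rel_elev Relative elevation at the location (m).
#' @return A one-row tibble with the tree columns.
#' @export
initialize_replant <- function(species, x, y, id, rel_elev = 0) {
  h <- evaluate_growth_model(species, "H", 5)
  cw <- evaluate_growth_model(species, "CW", 5)
  cl <- min(evaluate_growth_model(species, "CL", 5), 0.95 * h)
  tibble::tibble(id = id, species = species, x = x, y = y, dbh = 5,
                 height = h, crown_width = cw, crown_length = cl,
                 age = 5L, rel_elev = rel_elev, alive = TRUE,
                 origin = "replanted")
}
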