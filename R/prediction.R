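# Individual-tree prediction: feature assembly, VIF screening, pluggable
# learners with seeded defaults, a PSO hyperparameter tuner, the 5-year
# sequential update, and the mortality rule.

#' Assemble the per-tree feature matrix
#'
#' One row per living tree with the candidate predictors: AGE, DBH, 1/DBH,
#' DBH^2, H, CW, CL, stem density NT, stand density index SDI, slope SLO,
#' aspect ASP (8-sector ordinal, 1 = N ... 8 = NW), height-diameter ratio
#' HDR, basal area in larger trees BAL, and the Hegyi competition index
#' HCI. Dead trees are excluded.
#'
#' @param x A [stand()].
#' @return A tibble with an `id` column plus the feature columns.
#' @export
compute_features <- function(x) {
  stopifnot(is_stand(x))
  live <- living_points(x)
  cov <- competition_covariates(x)
  az <- aspect_azimuth(attr(x, "aspect"))
  tibble::tibble(
    id = live$id,
    AGE = as.numeric(live$age),
    DBH = live$dbh,
    inv_DBH = 1 / live$dbh,
    DBH2 = live$dbh^2,
    H = live$height,
    CW = live$crown_width,
    CL = live$crown_length,
    NT = cov$NT,
    SDI = cov$SDI,
    SLO = attr(x, "slope"),
    ASP = floor(((az + 22.5) %% 360) / 45) + 1,
    HDR = cov$per_tree$HDR,
    BAL = cov$per_tree$BAL,
    HCI = cov$per_tree$HCI
  )
}

#' Feature subsets per prediction task
#'
#' @return Named list of character vectors (tasks `age`, `dbh`, `height`,
#'   `cw`, `cl`, `mortality`).
#' @export
feature_sets <- function() {
  list(
    age       = c("inv_DBH", "H", "ASP", "SLO", "NT", "SDI"),
    dbh       = c("AGE", "ASP", "NT", "SLO", "SDI", "BAL", "DBH2"),
    height    = c("AGE", "ASP", "DBH", "SLO"),
    cw        = c("AGE", "inv_DBH", "CL", "ASP", "SDI", "HDR", "NT"),
    cl        = c("AGE", "inv_DBH", "ASP", "SDI", "HDR", "NT"),
    mortality = c("inv_DBH", "H", "BAL", "HCI")
  )
}

#' Variance-inflation-factor screening
#'
#' Iteratively drops the column with the highest VIF while any VIF exceeds
#' the threshold. `VIF_k = 1 / (1 - R^2_k)` where `R^2_k` comes from
#' regressing column `k` on the remaining columns; an exactly collinear
#' column has infinite VIF. Ties and singular designs resolve
#' deterministically by column order.
#'
#' @param df Data frame of numeric candidate predictors (2+ columns, more
#'   rows than columns).
#' @param threshold VIF threshold (default 10).
#' @return List with `kept` and `dropped` column names and `vif` (final
#'   VIF values of the kept columns).
#' @export
vif_filter <- function(df, threshold = 10) {
  df <- as.data.frame(df)
  if (ncol(df) < 2 || nrow(df) <= ncol(df)) {
    abort("need at least 2 columns and more rows than columns",
          class = "standopt_validation_error")
  }
  vif_of <- function(d) {
    vapply(seq_along(d), function(k) {
      y <- d[[k]]
      if (stats::var(y) == 0) return(Inf)
      fit <- stats::lm(y ~ ., data = d[-k])
      r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  dropped <- character(0)
  repeat {
    v <- vif_of(df)
    if (ncol(df) <= 1 || all(v <= threshold)) break
    worst <- which.max(v)   # which.max takes the first on ties
    dropped <- c(dropped, names(df)[worst])
    df <- df[-worst]
  }
  list(kept = names(df), dropped = dropped,
       vif = stats::setNames(vif_of(df), names(df)))
}

# --- learner contract ------------------------------------------------------

#' Learner constructors
#'
#' A learner is a list with `fit(X, y)` returning a model and
#' `predict(model, X)` returning numeric predictions (probabilities for
#' classifiers). Any object honouring this contract can be dropped into
#' the predictor bank. The defaults are random forests ([ranger::ranger])
#' for the tree-height and crown-width tasks and gradient boosting
#' ([xgboost::xgboost]) for the diameter-growth, crown-length, age and
#' mortality tasks; both are deterministic given their seed.
#'
#' @param num.trees,nrounds,max_depth,eta Model hyperparameters.
#' @param seed Integer seed.
#' @param objective xgboost objective.
#' @return A learner list.
#' @name learners
NULL

#' @rdname learners
#' @export
learner_ranger <- function(num.trees = 300, seed = 1) {
  list(
    fit = function(X, y) {
      ranger::ranger(y = y, x = as.data.frame(X), num.trees = num.trees,
                     seed = seed, num.threads = 1)
    },
    predict = function(model, X) {
      predict(model, data = as.data.frame(X), num.threads = 1)$predictions
    },
    label = sprintf("ranger(%d trees)", num.trees)
  )
}

#' @rdname learners
#' @export
learner_xgboost <- function(nrounds = 300, max_depth = 4, eta = 0.1,
                            objective = "reg:squarederror", seed = 1) {
  list(
    fit = function(X, y) {
      dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
      xgboost::xgb.train(
        params = list(objective = objective, max_depth = max_depth,
                      eta = eta, nthread = 1, seed = seed),
        data = dtrain, nrounds = nrounds, verbose = 0)
    },
    predict = function(model, X) {
      predict(model, xgboost::xgb.DMatrix(as.matrix(X)))
    },
    label = sprintf("xgboost(%d rounds, depth %d, eta %.3g%s)",
                    nrounds, max_depth, eta,
                    if (objective == "reg:squarederror") "" else paste0(", ", objective))
  )
}

#' @rdname learners
#' @export
default_learners <- function(seed = 1) {
  list(
    age       = learner_xgboost(seed = seed),
    dbh       = learner_xgboost(seed = seed),
    height    = learner_ranger(seed = seed),
    cw        = learner_ranger(seed = seed),
    cl        = learner_xgboost(seed = seed),
    mortality = learner_xgboost(objective = "binary:logistic", seed = seed)
  )
}

# --- reference growth law --------------------------------------------------

#' Reference growth law for synthetic stands
#'
#' A known individual-tree growth law used to label synthetic training
#' stands and to serve as the simulation truth when checking that the
#' prediction pipeline recovers dynamics it was trained on. Five-year
#' diameter increment declines exponentially in DBH and linearly in
#' basal-area competition; height, crown width and crown length follow the
#' dominant conifer's allometric curves; death strikes trees under extreme
#' crowding, with a size-aware threshold: the Hegyi index scales with the
#' neighbour/subject diameter ratio, so small recruits carry structurally
#' larger values while tolerating shade, and self-thinning in these stands
#' removes established suppressed stems rather than regeneration.
#'
#' @return List of vectorised functions `dgi(dbh, bal)`, `height(dbh)`,
#'   `cw(dbh)`, `cl(dbh)`, `dead(hci, dbh)`.
#' @export
reference_growth_law <- function() {
  list(
    dgi = function(dbh, bal) 3.0 * exp(-dbh / 20) * pmax(0, 1 - bal / 60),
    height = function(dbh) evaluate_growth_model("pinus_yunnanensis", "H", dbh),
    cw = function(dbh) evaluate_growth_model("pinus_yunnanensis", "CW", dbh),
    cl = function(dbh) pmin(evaluate_growth_model("pinus_yunnanensis", "CL", dbh),
                            0.95 * evaluate_growth_model("pinus_yunnanensis", "H", dbh)),
    # mortality is a rare event: only severe crowding kills (Hegyi values
    # for established stems in these densities run 2-6, so 8 marks the
    # extreme tail; the 60/DBH term keeps the size-ratio inflation of the
    # index for small recruits from reading as lethal suppression)
    dead = function(hci, dbh) hci > 8 + 60 / dbh
  )
}

#' Training rows for the prediction tasks
#'
#' Applies a growth law to each stand to produce (features at t, target at
#' t+5) rows for every task, with the feature refreshes the sequential
#' update implies (the height model, for example, sees the already-updated
#' age and DBH).
#'
#' @param stands List of [stand()] objects.
#' @param law A growth law, as from [reference_growth_law()].
#' @return Named list of data frames, one per task, each with the task's
#'   feature columns plus a `target` column.
#' @export
growth_training_data <- function(stands, law = reference_growth_law()) {
  fs <- feature_sets()
  rows <- lapply(stands, function(s) {
    f0 <- compute_features(s)
    dgi <- law$dgi(f0$DBH, f0$BAL)
    dbh1 <- f0$DBH + dgi
    f_dbh <- f0; f_dbh$AGE <- f0$AGE + 5   # DBH model sees the advanced age
    f_h <- f_dbh
    f_h$DBH <- dbh1; f_h$inv_DBH <- 1 / dbh1; f_h$DBH2 <- dbh1^2
    list(
      age       = cbind(f0[fs$age], target = f0$AGE + 5),
      dbh       = cbind(f_dbh[fs$dbh], target = log(dgi + 1)),
      height    = cbind(f_h[fs$height], target = law$height(dbh1)),
      cw        = cbind(f_h[fs$cw], target = law$cw(dbh1)),
      cl        = cbind(f_h[fs$cl], target = law$cl(dbh1)),
      mortality = cbind(f0[fs$mortality], target = as.numeric(law$dead(f0$HCI, f0$DBH)))
    )
  })
  stats::setNames(lapply(names(fs), function(task) {
    do.call(rbind, lapply(rows, `[[`, task))
  }), names(fs))
}

#' Fit the default predictor bank
#'
#' Fits one learner per prediction task (age, diameter growth, height,
#' mortality, crown width, crown length) on pooled per-tree rows from the
#' training stands, holding out a fraction for validation metrics. The
#' diameter-growth target is `ln(DGI + 1)`; the mortality learner outputs
#' a probability. Deterministic given `seed`.
#'
#' @param stands List of training [stand()]s.
#' @param seed Integer seed (controls the validation split and learners).
#' @param learners Named list of learners (see [default_learners()]).
#' @param law Growth law used to label the rows.
#' @param holdout Validation fraction.
#' @param predict_age Advance age with the fitted learner instead of the
#'   deterministic +5 (ages are known exactly in simulation, so the
#'   default is the deterministic rule).
#' @return A `predictor_bank`: per-task fitted models, features, and
#'   validation metrics.
#' @export
fit_predictor_bank <- function(stands, seed = 1,
                               learners = default_learners(seed),
                               law = reference_growth_law(),
                               holdout = 0.2, predict_age = FALSE) {
  if (!length(stands)) abort("no training stands supplied",
                             class = "standopt_validation_error")
  data <- growth_training_data(stands, law)
  if (nrow(data$dbh) < 50) abort("need at least 50 training rows",
                                 class = "standopt_validation_error")
  fs <- feature_sets()
  bank <- with_seed(seed, {
    lapply(names(fs), function(task) {
      d <- data[[task]]
      n <- nrow(d)
      val <- sample.int(n, max(1, round(holdout * n)))
      X <- d[setdiff(names(d), "target")]
      lr <- learners[[task]]
      model <- lr$fit(X[-val, , drop = FALSE], d$target[-val])
      pred <- lr$predict(model, X[val, , drop = FALSE])
      metrics <- if (task == "mortality") {
        c(accuracy = mean((pred > 0.5) == (d$target[val] > 0.5)))
      } else {
        sse <- sum((pred - d$target[val])^2)
        sst <- sum((d$target[val] - mean(d$target[val]))^2)
        c(r_squared = if (sst > 0) 1 - sse / sst else NA_real_,
          rmse = sqrt(mean((pred - d$target[val])^2)))
      }
      list(model = model, learner = lr, features = fs[[task]],
           metrics = metrics, n_train = n - length(val), n_val = length(val))
    })
  })
  structure(stats::setNames(bank, names(fs)),
            class = "predictor_bank", seed = seed, predict_age = predict_age)
}

#' @export
print.predictor_bank <- function(x, ...) {
  cat("predictor bank:\n")
  for (task in names(x)) {
    m <- x[[task]]$metrics
    cat(sprintf("  %-9s %s  %s\n", task, x[[task]]$learner$label %||% "",
                paste(sprintf("%s=%.4f", names(m), m), collapse = " ")))
  }
  invisible(x)
}

#' @export
glance.predictor_bank <- function(x, ...) {
  purrr::map_dfr(names(x), function(task) {
    m <- x[[task]]$metrics
    tibble::tibble(task = task, metric = names(m), value = unname(m),
                   n_train = x[[task]]$n_train, n_val = x[[task]]$n_val)
  })
}

bank_predict <- function(bank, task, features) {
  b <- bank[[task]]
  b$learner$predict(b$model, features[b$features])
}

#' Mortality decision rule
#'
#' A tree is classified as dead only when the predicted mortality
#' probability exceeds 0.5 *and* it is under high competition pressure
#' (Hegyi index above 0.75); mortality is a rare event, so the probability
#' threshold alone would over-kill in unbalanced stands.
#'
#' @param prob Mortality probability in `[0, 1]`.
#' @param hci Hegyi competition index.
#' @return Logical: `TRUE` = dead.
#' @export
mortality_decision <- function(prob, hci) {
  stopifnot(all(prob >= 0 & prob <= 1))
  prob > 0.5 & hci > 0.75
}

#' Advance a stand by one five-year cycle
#'
#' Sequentially updates every living tree in the fixed order age, DBH,
#' height, mortality, crown width, crown length, refreshing the feature
#' matrix between steps so each model sees the already-updated state (the
#' height model sees the new age and DBH; crown predictions are only made
#' for survivors). Diameter growth is recovered from the predicted
#' `ln(DGI + 1)` as `exp(pred) - 1`, clamped at zero, so DBH never
#' shrinks. Trees killed at the mortality step keep their last crown
#' measurements and are excluded from all later structure computations.
#'
#' @param x A [stand()].
#' @param bank A fitted [fit_predictor_bank()].
#' @return The advanced [stand()].
#' @export
advance_stand <- function(x, bank) {
  stopifnot(is_stand(x), inherits(bank, "predictor_bank"))
  trees <- tibble::as_tibble(x)
  live_idx <- which(trees$alive)
  if (!length(live_idx)) return(x)
  # 1. age
  if (isTRUE(attr(bank, "predict_age"))) {
    f <- compute_features(x)
    trees$age[live_idx] <- round(bank_predict(bank, "age", f))
  } else {
    trees$age[live_idx] <- trees$age[live_idx] + 5L
  }
  x <- restand(trees, x)
  # 2. DBH growth on the updated age
  f <- compute_features(x)
  dgi <- pmax(0, exp(bank_predict(bank, "dbh", f)) - 1)
  trees$dbh[live_idx] <- trees$dbh[live_idx] + dgi
  x <- restand(trees, x)
  # 3. height sees the new DBH
  f <- compute_features(x)
  trees$height[live_idx] <- pmax(1.5, bank_predict(bank, "height", f))
  x <- restand(trees, x)
  # 4. mortality on the updated state
  f <- compute_features(x)
  prob <- pmin(1, pmax(0, bank_predict(bank, "mortality", f)))
  dead <- mortality_decision(prob, f$HCI)
  trees$alive[live_idx[dead]] <- FALSE
  x <- restand(trees, x)
  # 5-6. crowns, survivors only
  surv_idx <- which(trees$alive)
  if (length(surv_idx)) {
    f <- compute_features(x)
    trees$crown_width[surv_idx] <- pmax(0.3, bank_predict(bank, "cw", f))
    x <- restand(trees, x)
    f <- compute_features(x)
    cl <- pmax(0.3, bank_predict(bank, "cl", f))
    trees$crown_length[surv_idx] <- pmin(cl, 0.95 * trees$height[surv_idx])
  }
  restand(trees, x)
}

# --- PSO hyperparameter tuner ---------------------------------------------

#' Particle swarm optimization over a box
#'
#' Canonical PSO (inertia 0.72, cognitive and social coefficients 1.49)
#' minimising an objective over box bounds; used to tune learner
#' hyperparameters against validation loss, but applicable to any bounded
#' search. Particles are clamped to the box; integer dimensions are
#' rounded at evaluation. Deterministic given `seed`.
#'
#' @param objective Function of a numeric vector, returning the loss.
#' @param lower,upper Numeric bounds (equal length, lower < upper).
#' @param integer Logical vector marking integer-valued dimensions.
#' @param swarm Number of particles.
#' @param iterations Number of velocity updates.
#' @param seed Integer seed.
#' @param inertia,cognitive,social PSO coefficients.
#' @return List with `par` (best position), `value` (best loss), and
#'   `history` (best loss per iteration).
#' @export
pso_tune <- function(objective, lower, upper, integer = NULL, swarm = 15,
                     iterations = 50, seed = 1, inertia = 0.72,
                     cognitive = 1.49, social = 1.49) {
  d <- length(lower)
  if (d == 0 || length(upper) != d || any(upper < lower)) {
    abort("bounds must be non-empty with lower <= upper",
          class = "standopt_validation_error")
  }
  if (is.null(integer)) integer <- rep(FALSE, d)
  integer <- rep_len(integer, d)
  snap <- function(P) {
    lo <- matrix(lower, nrow(P), d, byrow = TRUE)
    hi <- matrix(upper, nrow(P), d, byrow = TRUE)
    P <- pmin(hi, pmax(lo, P))
    P[, integer] <- round(P[, integer])
    P
  }
  with_seed(seed, {
    pos <- snap(matrix(runif(swarm * d, rep(lower, each = swarm),
                             rep(upper, each = swarm)), swarm, d))
    vel <- matrix(0, swarm, d)
    fit <- apply(pos, 1, objective)
    pbest <- pos; pbest_fit <- fit
    g <- which.min(fit)
    gbest <- pos[g, ]; gbest_fit <- fit[g]
    history <- numeric(iterations)
    for (it in seq_len(iterations)) {
      r1 <- matrix(runif(swarm * d), swarm, d)
      r2 <- matrix(runif(swarm * d), swarm, d)
      vel <- inertia * vel +
        cognitive * r1 * (pbest - pos) +
        social * r2 * (matrix(gbest, swarm, d, byrow = TRUE) - pos)
      pos <- snap(pos + vel)
      fit <- apply(pos, 1, objective)
      better <- fit < pbest_fit
      pbest[better, ] <- pos[better, , drop = FALSE]
      pbest_fit[better] <- fit[better]
      if (min(fit) < gbest_fit) {
        g <- which.min(fit)
        gbest <- pos[g, ]; gbest_fit <- fit[g]
      }
      history[it] <- gbest_fit
    }
    list(par = drop(snap(matrix(gbest, 1))), value = gbest_fit,
         history = history)
  })
}
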