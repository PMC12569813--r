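test_that("feature matrix derives the documented columns", {
  s <- generate_stand(radius = 12, density = 2000, seed = 8)
  f <- compute_features(s)
  i <- which.min(abs(f$DBH - 20))
  expect_equal(f$inv_DBH, 1 / f$DBH)
  expect_equal(f$DBH2, f$DBH^2)
  expect_equal(f$HDR, f$H / f$DBH)
  expect_equal(f$BAL[which.max(f$DBH)], 0)
  expect_true(all(f$ASP %in% 1:8))
  expect_equal(unique(f$SLO), attr(s, "slope"))
  expect_equal(feature_sets()$cw,
               c("AGE", "inv_DBH", "CL", "ASP", "SDI", "HDR", "NT"))
  expect_equal(feature_sets()$mortality, c("inv_DBH", "H", "BAL", "HCI"))
  # dead trees are excluded
  trees <- tibble::as_tibble(s); trees$alive[1:5] <- FALSE
  s2 <- stand(trees, radius = stand_radius(s), buffer_width = 2)
  expect_equal(nrow(compute_features(s2)), nrow(s) - 5)
})

test_that("VIF filter matches the closed-form oracle and drops duplicates", {
  set.seed(1)
  a <- rnorm(200); b <- rnorm(200)
  d <- data.frame(a = a, b = b)
  res <- vif_filter(d)
  expect_setequal(res$kept, c("a", "b"))
  expect_true(all(res$vif < 1.2))

  dup <- data.frame(a = a, b = b, a2 = a)
  res2 <- vif_filter(dup)
  expect_length(res2$dropped, 1)
  expect_true(res2$dropped %in% c("a", "a2"))

  # equicorrelated design: VIF = 1/(1 - R^2) with known R^2
  rho <- 0.9
  S <- matrix(rho, 3, 3); diag(S) <- 1
  Z <- matrix(rnorm(3000 * 3), ncol = 3) %*% chol(S)
  d3 <- as.data.frame(Z)
  v <- vif_filter(d3, threshold = Inf)$vif
  # for equicorrelated columns R^2_k = 2 rho^2 / (1 + rho)
  expect_equal(unname(v), rep(1 / (1 - 2 * rho^2 / (1 + rho)), 3),
               tolerance = 0.15)
  expect_error(vif_filter(d[1]), class = "standopt_validation_error")
})

test_that("mortality decision needs both probability and competition", {
  expect_true(mortality_decision(0.6, 0.8))
  expect_false(mortality_decision(0.6, 0.5))
  expect_false(mortality_decision(0.4, 0.9))
  expect_false(mortality_decision(0.5, 0.9))   # strictly greater than 0.5
  expect_error(mortality_decision(1.4, 0.9))
})

test_that("PSO finds the sphere optimum and respects the box", {
  res <- pso_tune(function(p) sum(p^2), lower = c(-5, -5), upper = c(5, 5),
                  swarm = 20, iterations = 100, seed = 2)
  expect_lt(sqrt(sum(res$par^2)), 1e-2)
  expect_true(all(diff(res$history) <= 0))  # best loss non-increasing

  # swarm of one with zero velocity stays at its start
  res1 <- pso_tune(function(p) sum(p^2), lower = 1, upper = 2, swarm = 1,
                   iterations = 5, seed = 3, inertia = 0, cognitive = 0,
                   social = 0)
  expect_gte(res1$par, 1); expect_lte(res1$par, 2)
  expect_equal(res1$value, res1$par^2)

  # integer dimensions are rounded, all positions clamped to the box
  resi <- pso_tune(function(p) (p[1] - 3.4)^2, lower = 0, upper = 10,
                   integer = TRUE, swarm = 10, iterations = 30, seed = 4)
  expect_equal(resi$par, 3)
  expect_error(pso_tune(function(p) 0, lower = numeric(0), upper = numeric(0)),
               class = "standopt_validation_error")
})

test_that("default bank recovers a known growth law", {
  stands <- lapply(1:6, function(i)
    generate_stand(radius = 12, density = 2300, seed = 100 + i,
                   species_mix = c(pinus_yunnanensis = 0.7,
                                   betula_alnoides = 0.3)))
  bank <- fit_predictor_bank(stands, seed = 1)
  expect_gte(bank$dbh$metrics[["r_squared"]], 0.95)
  expect_gte(bank$mortality$metrics[["accuracy"]], 0.9)
  # determinism
  bank2 <- fit_predictor_bank(stands, seed = 1)
  s <- stands[[1]]
  expect_equal(tibble::as_tibble(advance_stand(s, bank)),
               tibble::as_tibble(advance_stand(s, bank2)))
  expect_error(fit_predictor_bank(stands[1][0], seed = 1),
               class = "standopt_validation_error")
})

test_that("advance_stand follows the sequential update semantics", {
  stands <- lapply(1:4, function(i)
    generate_stand(radius = 12, density = 2300, seed = 200 + i))
  bank <- fit_predictor_bank(stands, seed = 2)
  s <- stands[[1]]
  s1 <- advance_stand(s, bank)
  # ages advance deterministically by the 5-year cycle
  expect_equal(s1$age[s1$alive | !s1$alive], s$age + 5L)
  # DBH never shrinks (log-transform target clamped at zero)
  expect_true(all(s1$dbh >= s$dbh - 1e-12))
  # dead trees keep their last crown measurements and stay dead
  died <- which(!s1$alive)
  if (length(died)) {
    expect_equal(s1$crown_width[died], s$crown_width[died])
    s2 <- advance_stand(s1, bank)
    expect_true(all(!s2$alive[died]))
  }
  # tree count is non-increasing under growth
  expect_lte(sum(s1$alive), sum(s$alive))
})

test_that("five projected cycles track the reference law", {
  stands <- lapply(1:6, function(i)
    generate_stand(radius = 12, density = 2100, seed = 300 + i))
  bank <- fit_predictor_bank(stands, seed = 3)
  law <- reference_growth_law()
  s <- generate_stand(radius = 12, density = 2100, seed = 999)
  # simulation oracle: iterate the true law on the tree list directly
  truth <- s
  pred <- s
  for (cycle in 1:3) {
    f <- compute_features(truth)
    trees <- tibble::as_tibble(truth)
    li <- which(trees$alive)
    trees$age[li] <- trees$age[li] + 5
    trees$dbh[li] <- trees$dbh[li] + law$dgi(f$DBH, f$BAL)
    trees$height[li] <- law$height(trees$dbh[li])
    dead <- law$dead(f$HCI, f$DBH)
    trees$alive[li[dead]] <- FALSE
    truth <- stand(trees, radius = stand_radius(s), slope = attr(s, "slope"),
                   aspect = attr(s, "aspect"), buffer_width = 2,
                   validate = FALSE)
    pred <- advance_stand(pred, bank)
  }
  mean_truth <- mean(truth$dbh[truth$alive])
  mean_pred <- mean(pred$dbh[pred$alive])
  expect_lt(abs(mean_pred - mean_truth) / mean_truth, 0.05)
})
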