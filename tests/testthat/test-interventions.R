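test_that("growth bank reproduces every published stand factor at 5 cm", {
  bank <- growth_model_bank()
  expect_equal(nrow(bank), 21)
  for (i in seq_len(nrow(bank))) {
    expect_equal(
      round(evaluate_growth_model(bank$species[i], bank$variable[i], 5), 2),
      bank$factor_5cm[i],
      info = paste(bank$species[i], bank$variable[i]))
  }
  # spot values
  expect_equal(round(evaluate_growth_model("pinus_yunnanensis", "H", 5), 2), 5.20)
  expect_equal(round(evaluate_growth_model("betula_alnoides", "H", 5), 2), 6.33)
  expect_equal(round(evaluate_growth_model("ternstroemia_gymnanthera", "H", 5), 2), 5.13)
  expect_equal(round(evaluate_growth_model("vaccinium_bracteatum", "H", 5), 2), 2.20)
  expect_error(evaluate_growth_model("unknown_species", "H", 5),
               class = "standopt_validation_error")
})

test_that("uncalibrated rows evaluate from the raw printed parameters", {
  # Betula height under the reciprocal-of-DBH reading, no offset
  expect_equal(evaluate_growth_model("betula_alnoides", "H", 5),
               1 / (0.0211 + 0.6850 / 5), tolerance = 1e-12)
  bank <- growth_model_bank()
  expect_equal(bank$offset[bank$species == "betula_alnoides" &
                             bank$variable == "H"], 0)
  # rows that need the calibration offset carry a nonzero one
  expect_true(all(bank$offset[bank$species == "quercus_acutissima" &
                                bank$variable %in% c("H", "CW")] != 0))
})

test_that("replants initialize at 5 cm / 5 years with bank dimensions", {
  tr <- initialize_replant("pinus_yunnanensis", 1, 2, id = "r1")
  expect_equal(tr$dbh, 5)
  expect_equal(tr$age, 5L)
  expect_equal(tr$origin, "replanted")
  expect_true(tr$alive)
  expect_equal(round(tr$height, 2), 5.20)
  expect_equal(round(tr$crown_length, 2), 1.32)
  expect_equal(diameter_class(tr$dbh), 0L)
  expect_equal(round(initialize_replant("vaccinium_bracteatum", 0, 0, "r2")$height, 2),
               2.20)
})

test_that("harvest selection respects budget, species survival, determinism", {
  s <- generate_stand(radius = 12, density = 2300, seed = 10,
                      species_mix = c(pinus_yunnanensis = 0.95,
                                      betula_alnoides = 0.05))
  expect_identical(select_harvest_candidates(s, 0), character(0))
  ids1 <- select_harvest_candidates(s, 10, seed = 3)
  ids2 <- select_harvest_candidates(s, 10, seed = 3)
  expect_identical(ids1, ids2)
  expect_length(unique(ids1), 10)
  core <- partition_core_buffer(s)$core
  expect_true(all(ids1 %in% core))

  n0 <- nrow(s)
  expect_error(select_harvest_candidates(s, harvest_budget(n0) + 1),
               class = "standopt_budget_error")
  expect_error(select_harvest_candidates(s, 1, n_initial = 100, n_harvested = 35),
               class = "standopt_budget_error")

  # a single-individual species is never selected, even under many draws
  live <- tibble::as_tibble(s)
  counts <- table(live$species)
  if (any(counts == 1)) {
    lone <- live$id[live$species %in% names(counts)[counts == 1]]
    for (seed in 1:20) {
      expect_false(any(lone %in% select_harvest_candidates(s, 20, seed = seed)))
    }
  }
})

test_that("applying a harvest removes exactly the requested trees", {
  s <- generate_stand(radius = 12, density = 2000, seed = 1)
  expect_identical(tibble::as_tibble(apply_harvest(s, character(0))),
                   tibble::as_tibble(s))
  s1 <- apply_harvest(s, s$id[1:3])
  expect_equal(nrow(s1), nrow(s) - 3)
  expect_false(any(s$id[1:3] %in% s1$id))
  expect_error(apply_harvest(s, "nope"), class = "standopt_validation_error")
})

test_that("harvest can never exceed 35% under adversarial request sequences", {
  s <- generate_stand(radius = 12, density = 2000, seed = 6)
  n0 <- nrow(s)
  harvested <- 0
  cur <- s
  withr::with_seed(9, {
    for (round in 1:60) {
      k <- sample(1:12, 1)
      ids <- tryCatch(
        select_harvest_candidates(cur, k, n_initial = n0,
                                  n_harvested = harvested),
        standopt_budget_error = function(e) NULL)
      if (is.null(ids)) next
      cur <- apply_harvest(cur, ids)
      harvested <- harvested + length(ids)
    }
  })
  expect_lte(harvested, harvest_budget(n0))
  expect_gte(nrow(cur), ceiling(0.65 * n0))
})

test_that("RFI factors combine as specified", {
  s <- generate_stand(radius = 12, density = 1800, seed = 12)
  ctx <- rfi_context(s)
  # manufactured context: unit deltas make factor arithmetic transparent
  ctx1 <- ctx
  ctx1$deltas <- c(DAA = 1, Mc = 1, U = 1, CI = 1)
  rfi <- replanting_foreground_index(s, 1, 1, "betula_alnoides",
                                     context = ctx1)
  expect_gt(rfi, 0)
  # two candidates identical except CI 0 vs 2 with unit deltas -> ratio 3
  daa <- 2; mc <- 0.5; u <- 1
  f <- function(ci) (1 + daa) * (1 + mc) * (1 + u) / (1 + ci)
  expect_equal(f(0) / f(2), 3)
  # outside the core region errors
  expect_error(replanting_foreground_index(s, 11.5, 0, "betula_alnoides"),
               class = "standopt_validation_error")
})

test_that("RFI increases with gap size, all else equal", {
  # interior canopy gap: a candidate in the hole scores higher than one
  # squeezed between stems, same species
  set.seed(33)
  ang <- runif(50, 0, 2 * pi); rr <- sqrt(runif(50, 0.25, 1)) * 11
  s <- mini_stand(x = rr * cos(ang), y = rr * sin(ang), radius = 14,
                  dbh = runif(50, 8, 25))
  ctx <- rfi_context(s)
  rfi_gap <- replanting_foreground_index(s, 0, 0, "betula_alnoides", context = ctx)
  dense_i <- which.max(tibble::as_tibble(s)$x)
  px <- s$x[dense_i] - 0.8; py <- s$y[dense_i]
  rfi_dense <- replanting_foreground_index(s, px, py, "betula_alnoides",
                                           context = ctx)
  expect_gt(rfi_gap, rfi_dense)
})

test_that("planting locations fill the largest canopy gap first", {
  set.seed(7)
  ang <- runif(70, 0, 2 * pi); rr <- sqrt(runif(70, 0.2, 1)) * 11
  s <- mini_stand(x = rr * cos(ang), y = rr * sin(ang), radius = 14,
                  dbh = runif(70, 8, 25))
  # all stems at least 4.9 m out: the centre is the dominant gap
  plan <- propose_planting_locations(s, 3, K = 5)
  expect_equal(nrow(plan), 3)
  expect_lt(sqrt(plan$x[1]^2 + plan$y[1]^2), 5)
  expect_equal(plan$species, replant_species()[1:3])  # round-robin order

  expect_equal(nrow(propose_planting_locations(s, 0)), 0)
})

test_that("replant caps enforce the 3333/ha density ceiling", {
  s <- generate_stand(radius = 12, density = 3200, seed = 14)
  cap <- replant_cap(s)
  expect_equal(cap, floor(3333 * stand_area_ha(s)) - nrow(s))
  plan <- propose_planting_locations(s, min(3, cap), K = 3)
  s2 <- apply_replant(s, plan)
  expect_lte(nrow(s2) / stand_area_ha(s2), 3333)
  big_plan <- plan[rep(1, cap + 1), ]
  expect_error(apply_replant(s, big_plan), class = "standopt_budget_error")
})

test_that("replanted species shares stay within ceil arithmetic of 1/7", {
  s <- generate_stand(radius = 14, density = 1700, seed = 3)
  m <- 18
  plan <- propose_planting_locations(s, m, K = 3)
  shares <- table(factor(plan$species, levels = replant_species()))
  expect_true(all(shares >= floor(m / 7)))
  expect_true(all(shares <= ceiling(m / 7)))
  s2 <- apply_replant(s, plan)
  expect_equal(nrow(s2), nrow(s) + m)
  expect_true(all(s2$dbh[s2$origin == "replanted"] == 5))
})

test_that("curve-trend search equals exhaustive argmax on unimodal profiles", {
  f <- function(c) -(c - 600)^2
  res <- curve_trend_count_search(f, cap = 1000, spacing = 50)
  expect_equal(res$count, 600L)

  expect_equal(curve_trend_count_search(function(c) c, cap = 120,
                                        spacing = 16)$count, 120L)
  expect_equal(curve_trend_count_search(function(c) -c, cap = 120,
                                        spacing = 16)$count, 0L)
  expect_equal(curve_trend_count_search(function(c) c, cap = 0)$count, 0L)

  withr::with_seed(5, {
    for (case in 1:50) {
      peak <- sample(0:300, 1)
      sc <- runif(1, 0.5, 4)
      g <- function(c) -sc * (c - peak)^2 + 0.3 * c   # still strictly unimodal
      true_peak <- which.max(vapply(0:300, g, numeric(1))) - 1L
      res <- curve_trend_count_search(g, cap = 300, spacing = sample(5:60, 1))
      expect_equal(res$count, true_peak)
    }
  })
})

test_that("curve-trend search on multimodal profiles returns a local argmax", {
  g <- function(c) sin(c / 10) + 0.002 * c
  res <- curve_trend_count_search(g, cap = 300, spacing = 20, start = 100)
  expect_gte(g(res$count), g(100))
  vals <- vapply(pmax(0, pmin(300, res$count + (-1:1))), g, numeric(1))
  expect_equal(which.max(vals), 2L)   # local maximum
})
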