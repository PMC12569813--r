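# Small shared benchmark stand for the episode mechanics tests.
opt_test_stand <- function(seed = 1, radius = 12) {
  generate_stand(radius = radius, density = 2300, seed = seed,
                 clustering = 0.3,
                 species_mix = c(pinus_yunnanensis = 0.9,
                                 quercus_acutissima = 0.06,
                                 betula_alnoides = 0.04))
}

test_that("reward schedule maps every event to its published value", {
  sch <- reward_schedule()
  expect_equal(reward_for_event("terminal_success", sch), 150)
  expect_equal(reward_for_event("constraint_violation", sch), -50)
  expect_equal(reward_for_event("improve_ge_5pct", sch), 100)
  expect_equal(reward_for_event("improve_ge_1pct", sch), 50)
  expect_equal(reward_for_event("improve_ge_0.1pct", sch), 10)
  expect_equal(reward_for_event("improve_positive", sch), 1)
  expect_equal(reward_for_event("no_improvement", sch), -1)
  expect_equal(reward_for_event("illegal_move", sch), -50)
  expect_error(reward_for_event("nonsense", sch),
               class = "standopt_validation_error")
  # band edges relative to L0
  expect_equal(standopt:::delta_event(0.05, 1), "improve_ge_5pct")
  expect_equal(standopt:::delta_event(0.005 * 1, 1), "improve_ge_0.1pct")
  expect_equal(standopt:::delta_event(1e-6, 1), "improve_positive")
  expect_equal(standopt:::delta_event(-0.1, 1), "no_improvement")
})

test_that("always-forward policies meet exactly at the midpoint", {
  s <- opt_test_stand()
  cfg <- optimizer_config(episodes = 1, max_move = 6, seed = 2, replant_K = 2)
  ep <- run_episode(s, function(o) 1L, function(o) 1L, config = cfg)
  last <- tail(ep$trajectory, 1)
  expect_equal(last$pos1, 6L)
  expect_equal(last$pos2, 6L)
  expect_equal(max(ep$trajectory$step), 6L)
  expect_gte(ep$L_final, 0)
})

test_that("episodes are reproducible under a fixed seed", {
  s <- opt_test_stand()
  cfg <- optimizer_config(episodes = 1, max_move = 5, seed = 3, replant_K = 2)
  pol <- function(o) if (stats::runif(1) < 0.7) 1L else 2L
  ep1 <- run_episode(s, pol, pol, config = cfg)
  ep2 <- run_episode(s, pol, pol, config = cfg)
  expect_identical(ep1$trajectory, ep2$trajectory)
  expect_equal(ep1$L_final, ep2$L_final)
})

test_that("illegal moves are punished and do not change positions", {
  s <- opt_test_stand()
  cfg <- optimizer_config(episodes = 1, max_move = 4, seed = 4, replant_K = 2)
  # both agents try to walk backwards out of range forever
  ep <- run_episode(s, function(o) 2L, function(o) 2L, config = cfg)
  tr <- ep$trajectory
  expect_true(all(tr$event[tr$agent == 1] == "illegal_move"))
  expect_true(all(tr$pos1 == 0L))
  # guard terminates the non-meeting episode
  expect_lte(max(tr$step), 2 * 2 * cfg$max_move)
})

test_that("empty or degenerate stands are rejected up front", {
  s <- mini_stand(x = c(0, 1, 2), y = c(0, 0, 0), radius = 10)
  expect_error(run_episode(s, function(o) 1L, function(o) 1L,
                           config = optimizer_config(episodes = 1, seed = 1)),
               class = "standopt_geometry_error")
})

test_that("tabular Q-learning improves the stand within a few episodes", {
  s <- opt_test_stand(seed = 5)
  cfg <- optimizer_config(episodes = 4, max_move = 8, seed = 1, replant_K = 2)
  res <- optimize_maql(s, cfg)
  expect_s3_class(res, "stand_optimization")
  expect_gte(res$best_L, res$initial_L)
  expect_true(all(diff(res$episode_L) >= 0))   # running best is monotone
  # the returned stand is feasible: legal final density, no lost diameter
  # class or species, harvest within budget
  expect_true(res$feasible)
  dens <- sum(res$best_stand$alive) / stand_area_ha(res$best_stand)
  expect_gte(dens, 1667); expect_lte(dens, 3333)
  sm0 <- stand_summary(s)
  sm1 <- stand_summary(res$best_stand)
  expect_gte(sm1$n_diameter_classes, sm0$n_diameter_classes)
  expect_gte(sm1$n_species, sm0$n_species)
  n_kept <- sum(res$best_stand$origin == "original")
  expect_lte(sum(s$alive) - n_kept, harvest_budget(sum(s$alive)))
})

test_that("MAQL with zero discount learns immediate reward estimates", {
  s <- opt_test_stand()
  cfg <- optimizer_config(episodes = 2, max_move = 4, seed = 6, gamma = 0,
                          replant_K = 2)
  res <- optimize_maql(s, cfg)
  Q <- res$diagnostics$Q
  # all visited updates pull Q toward bounded immediate rewards
  expect_true(all(is.finite(unlist(Q))))
  expect_lte(max(unlist(Q)), 150)
  expect_gte(min(unlist(Q)), -50)
})

test_that("deep Q-network run is seed-deterministic and tracks the budget", {
  s <- opt_test_stand(seed = 7)
  cfg <- optimizer_config(episodes = 3, max_move = 6, seed = 2, replant_K = 2,
                          buffer_size = 40, batch_size = 8)
  res1 <- optimize_madqn(s, cfg)
  res2 <- optimize_madqn(s, cfg)
  expect_equal(res1$episode_L, res2$episode_L)
  expect_equal(tibble::as_tibble(res1$best_stand),
               tibble::as_tibble(res2$best_stand))
  # replay buffers never exceed their configured capacity
  expect_true(all(res1$diagnostics$buffer_fill <= 40))
  expect_gte(res1$best_L, res1$initial_L)
  # density guard on the returned stand
  dens <- sum(res1$best_stand$alive) / stand_area_ha(res1$best_stand)
  expect_lte(dens, 3333)
})

test_that("with lr = 0 the value networks stay frozen", {
  s <- opt_test_stand()
  cfg0 <- optimizer_config(episodes = 2, max_move = 4, seed = 9, lr = 0,
                           replant_K = 2, buffer_size = 30, batch_size = 5)
  res <- optimize_madqn(s, cfg0)
  expect_s3_class(res, "stand_optimization")
  # learner steps happened but the outcome equals a re-run (no drift)
  res2 <- optimize_madqn(s, cfg0)
  expect_equal(res$episode_L, res2$episode_L)
})

test_that("optimization results expose tidy/glance/autoplot", {
  s <- opt_test_stand()
  cfg <- optimizer_config(episodes = 2, max_move = 4, seed = 10, replant_K = 2)
  res <- optimize_maql(s, cfg)
  expect_equal(nrow(tidy(res)), 2)
  g <- glance(res)
  expect_equal(g$algorithm, "MAQL")
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(autoplot(s), "ggplot")
  expect_s3_class(autoplot(structure_indexes(s)), "ggplot")
})
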