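# Two-agent episode mechanics and the Q-learning solvers. Agent 1 walks a
# positional counter 0 -> 50 proposing single-tree selective harvests;
# agent 2 walks 100 -> 50 steering the replant count through curve-trend
# window moves; an episode ends when the counters meet. Every accepted
# move is rewarded by how much it improves the stand objective.

#' Reward schedule
#'
#' The published reward/punishment values: `a` for terminal success
#' (agents meet, all constraints hold, the objective improved), `b` for a
#' constraint-violating move, `c1`--`c4` for accepted moves whose
#' objective gain is at least 5%, 1%, 0.1% or simply positive relative to
#' the initial objective, `c5` for an accepted move that did not improve
#' the objective, and `c6` for an illegal move (leaving the positional
#' range or exceeding the harvest budget).
#'
#' @param a,b,c1,c2,c3,c4,c5,c6 Reward values.
#' @return A named list of class `reward_schedule`.
#' @export
reward_schedule <- function(a = 150, b = -50, c1 = 100, c2 = 50, c3 = 10,
                            c4 = 1, c5 = -1, c6 = -50) {
  structure(list(a = a, b = b, c1 = c1, c2 = c2, c3 = c3, c4 = c4,
                 c5 = c5, c6 = c6), class = "reward_schedule")
}

reward_events <- function() {
  c(terminal_success = "a", constraint_violation = "b",
    improve_ge_5pct = "c1", improve_ge_1pct = "c2",
    improve_ge_0.1pct = "c3", improve_positive = "c4",
    no_improvement = "c5", illegal_move = "c6")
}

#' Reward for an event
#'
#' @param event One of `terminal_success`, `constraint_violation`,
#'   `improve_ge_5pct`, `improve_ge_1pct`, `improve_ge_0.1pct`,
#'   `improve_positive`, `no_improvement`, `illegal_move`.
#' @param schedule A [reward_schedule()].
#' @return The reward value.
#' @export
reward_for_event <- function(event, schedule = reward_schedule()) {
  map <- reward_events()
  if (!event %in% names(map)) {
    abort(sprintf("unknown reward event '%s'", event),
          class = "standopt_validation_error")
  }
  schedule[[map[[event]]]]
}

# Objective-gain band of an accepted move, relative to the initial L.
delta_event <- function(dL, L0) {
  if (dL >= 0.05 * L0) "improve_ge_5pct"
  else if (dL >= 0.01 * L0) "improve_ge_1pct"
  else if (dL >= 0.001 * L0) "improve_ge_0.1pct"
  else if (dL > 0) "improve_positive"
  else "no_improvement"
}

#' Optimizer configuration
#'
#' Defaults follow the published solver settings (discount 0.9, learning
#' rate 0.01, greedy rate 0.9, replay buffer 10000, batch 32, three hidden
#' layers of 24 units, positional range 0--100 with a farthest move
#' distance of 50, iteration cap 10000). `episodes` is the number of
#' episodes actually run (capped at `Wmax`); scale it, together with
#' `max_move`, to the compute budget at hand. `replant_spacing` is the
#' initial curve-trend window spacing (default: an eighth of the replant
#' cap); `replant_K` is the number of candidate gap incenters scored per
#' planting while the optimizer explores. `freeze_deltas` evaluates
#' candidate moves under the initial stand's index standard deviations.
#'
#' @param episodes Episodes to run.
#' @param gamma Discount factor.
#' @param lr Learning rate.
#' @param epsilon Greedy rate of the epsilon-greedy policy.
#' @param buffer_size,batch_size Replay buffer capacity and sample size.
#' @param hidden Hidden layer widths of the value network.
#' @param target_period Learner steps between target-network syncs.
#' @param max_move Farthest positional move distance per agent.
#' @param harvest_batch Trees per harvest proposal.
#' @param replant_spacing Initial replant window spacing.
#' @param replant_K Candidate incenters per planting.
#' @param freeze_deltas Evaluate moves under frozen deltas.
#' @param td_clip TD-error clip for the value-network update (Huber-style
#'   stabiliser; `Inf` disables it).
#' @param Wmax Hard cap on episodes.
#' @param seed Integer seed.
#' @param epsilon_decay Optional linear decay of the exploration share
#'   (0 = constant greedy rate, the default).
#' @return A list of class `optimizer_config`.
#' @export
optimizer_config <- function(episodes = 50, gamma = 0.9, lr = 0.01,
                             epsilon = 0.9, buffer_size = 10000,
                             batch_size = 32, hidden = c(24, 24, 24),
                             target_period = 100, max_move = 50,
                             harvest_batch = 1, replant_spacing = NULL,
                             replant_K = 3, freeze_deltas = FALSE,
                             td_clip = 10, Wmax = 10000, seed = 1,
                             epsilon_decay = 0) {
  structure(list(episodes = min(episodes, Wmax), gamma = gamma, lr = lr,
                 epsilon = epsilon, buffer_size = buffer_size,
                 batch_size = batch_size, hidden = hidden,
                 target_period = target_period, max_move = max_move,
                 harvest_batch = harvest_batch,
                 replant_spacing = replant_spacing, replant_K = replant_K,
                 freeze_deltas = freeze_deltas, td_clip = td_clip,
                 Wmax = Wmax, seed = seed,
                 epsilon_decay = epsilon_decay),
            class = "optimizer_config")
}

# --- episode environment ---------------------------------------------------

stand_eval <- function(x, config_idx, deltas = NULL) {
  tab <- structure_indexes(x, config_idx)
  list(stand = x, tab = tab, means = index_means(tab),
       L = stand_objective(tab, deltas = deltas)$L,
       summary = stand_summary(x), cd = canopy_density(x))
}

make_episode_env <- function(x, config, config_idx = index_config(),
                             schedule = reward_schedule()) {
  env <- new.env(parent = emptyenv())
  env$config <- config
  env$config_idx <- config_idx
  env$schedule <- schedule
  env$s0 <- x
  env$e0 <- stand_eval(x, config_idx)
  env$L0 <- env$e0$L
  env$n0 <- sum(x$alive)
  env$budget <- harvest_budget(env$n0)
  env$deltas0 <- if (isTRUE(config$freeze_deltas)) index_deltas(env$e0$tab) else NULL
  env$plan <- propose_planting_locations(x, 0)
  env$plan_max <- Inf
  env$best_L <- -Inf
  env$best_stand <- NULL
  env$best_feasible <- FALSE
  env
}

env_reset <- function(env) {
  cfg <- env$config
  env$pos1 <- 0L
  env$pos2 <- 2L * cfg$max_move
  env$harvested <- 0L
  env$e1 <- env$e0              # state after harvesting so far
  env$version <- (env$version %||% 0L) + 1L
  env$memo <- new.env(parent = emptyenv())
  env$count <- 0L
  # three evenly spaced densities spanning the replant range: the initial
  # window spacing is a quarter of the cap so the first moves scan the
  # whole count range before the spacing contracts for refinement
  env$spacing <- cfg$replant_spacing %||% max(1L, replant_cap(env$s0) %/% 4L)
  env$e2 <- env$e0              # realized (harvest + replant) state
  env$steps <- 0L
  consider_best(env, eval_count(env, 0L))
  invisible(env)
}

# Harvest-stage constraint clauses against the episode-initial stand.
harvest_ok <- function(env, ev) {
  m0 <- env$e0$means; m1 <- ev$means
  s0 <- env$e0$summary; s1 <- ev$summary
  wref <- env$config_idx$w_reference
  tol <- 1e-9
  m1[["Mc"]] >= m0[["Mc"]] - tol &&
    m1[["S"]] >= m0[["S"]] - tol &&
    m1[["U"]] <= m0[["U"]] + tol &&
    m1[["CI"]] <= m0[["CI"]] + tol &&
    abs(m1[["W"]] - wref) <= abs(m0[["W"]] - wref) + tol &&
    s1$n_diameter_classes == s0$n_diameter_classes &&
    s1$n_species == s0$n_species &&
    ev$cd >= 0.7 - tol &&
    s1$n_trees >= 0.65 * s0$n_trees - tol
}

# Replant-stage clauses of the realized state against the harvested state.
replant_ok <- function(env, ev) {
  m1 <- env$e1$means; m2 <- ev$means
  wref <- env$config_idx$w_reference
  tol <- 1e-9
  abs(m2[["W"]] - wref) <= abs(m1[["W"]] - wref) + tol &&
    m2[["Mc"]] >= m1[["Mc"]] - tol &&
    ev$cd >= 0.7 - tol &&
    ev$summary$density_per_ha >= 1667 - tol &&
    ev$summary$density_per_ha <= 3333 + tol
}

fully_feasible <- function(env, ev) {
  harvest_ok(env, env$e1) && replant_ok(env, ev)
}

consider_best <- function(env, ev) {
  if (fully_feasible(env, ev) && ev$L > env$best_L) {
    env$best_L <- ev$L
    env$best_stand <- ev$stand
    env$best_feasible <- TRUE
  }
}

# Realize (and memoize) the stand at a given replant count on the current
# harvested state. The planting-location sequence is an append-only cache
# extended lazily against the harvested stand current at extension time.
eval_count <- function(env, count) {
  count <- min(count, env$plan_max)
  key <- sprintf("v%d_%d", env$version, count)
  if (!is.null(env$memo[[key]])) return(env$memo[[key]])
  ev <- if (count == 0L) {
    env$e1
  } else {
    len <- nrow(env$plan)
    if (len < count) {
      base <- apply_replant(env$e1$stand, env$plan[seq_len(min(len, count)), ])
      more <- tryCatch(
        propose_planting_locations(base, count - len, K = env$config$replant_K,
                                   species_offset = len,
                                   config = env$config_idx),
        standopt_geometry_error = function(e) NULL)
      if (is.null(more) || nrow(more) < count - len) {
        env$plan_max <- len + if (is.null(more)) 0L else nrow(more)
      }
      if (!is.null(more)) env$plan <- dplyr::bind_rows(env$plan, more)
      count <- min(count, nrow(env$plan))
      key <- sprintf("v%d_%d", env$version, count)
    }
    sel <- env$plan[seq_len(count), ]
    # a cached location can collide with a stem that was harvested when
    # the location was chosen but restored at episode reset: drop such rows
    live1 <- env$e1$stand
    clear <- vapply(seq_len(nrow(sel)), function(i) {
      min((live1$x - sel$x[i])^2 + (live1$y - sel$y[i])^2) > 0.0025
    }, logical(1))
    stand_eval(apply_replant(env$e1$stand, sel[clear, ]),
               env$config_idx, deltas = env$deltas0)
  }
  consider_best(env, ev)
  env$memo[[key]] <- ev
  ev
}

obs_vector <- function(env, agent) {
  cfg <- env$config
  pos <- if (agent == 1L) env$pos1 else env$pos2
  ev <- env$e2
  m <- ev$means
  cap <- max(1L, replant_cap(env$e1$stand))
  c(pos / (2 * cfg$max_move),
    m[["W"]], m[["U"]], m[["Mc"]], m[["S"]], m[["CI"]] / (1 + m[["CI"]]),
    ev$cd,
    ev$summary$density_per_ha / 3333,
    env$harvested / max(1L, env$budget),
    env$count / cap,
    min(2, ev$L / env$L0))
}

OBS_DIM <- 11L

step_harvest <- function(env, action) {
  cfg <- env$config
  if (action == 1L) {
    if (env$pos1 + 1L > cfg$max_move ||
        env$harvested + cfg$harvest_batch > env$budget) {
      return("illegal_move")
    }
    env$pos1 <- env$pos1 + 1L
    ids <- tryCatch(
      select_harvest_candidates(env$e1$stand, cfg$harvest_batch,
                                n_initial = env$n0,
                                n_harvested = env$harvested),
      standopt_budget_error = function(e) NULL)
    if (is.null(ids)) return("illegal_move")
    cand <- stand_eval(apply_harvest(env$e1$stand, ids), env$config_idx,
                       deltas = env$deltas0)
    if (!harvest_ok(env, cand)) return("constraint_violation")
    dL <- cand$L - env$e1$L
    env$e1 <- cand
    env$harvested <- env$harvested + length(ids)
    env$version <- env$version + 1L
    env$memo <- new.env(parent = emptyenv())
    env$plan_max <- Inf
    env$e2 <- eval_count(env, env$count)
    delta_event(dL, env$L0)
  } else {
    if (env$pos1 - 1L < 0L) return("illegal_move")
    env$pos1 <- env$pos1 - 1L
    "no_improvement"
  }
}

step_replant <- function(env, action) {
  cfg <- env$config
  if (action == 1L) {
    if (env$pos2 - 1L < cfg$max_move) return("illegal_move")
    env$pos2 <- env$pos2 - 1L
    cap <- min(replant_cap(env$e1$stand), env$plan_max)
    s <- env$spacing
    c0 <- env$count
    lo <- max(0L, c0 - s); hi <- min(cap, c0 + s)
    f <- function(cc) eval_count(env, cc)$L
    fc <- f(c0)
    cnew <- c0
    if (hi > c0 && f(hi) > fc) cnew <- hi
    else if (lo < c0 && f(lo) > fc) cnew <- lo
    else env$spacing <- max(1L, s %/% 2L)
    ev_new <- eval_count(env, cnew)
    dL <- ev_new$L - env$e2$L
    env$count <- cnew
    env$e2 <- ev_new
    delta_event(dL, env$L0)
  } else {
    if (env$pos2 + 1L > 2L * cfg$max_move) return("illegal_move")
    env$pos2 <- env$pos2 + 1L
    env$spacing <- max(1L, env$spacing %/% 2L)
    "no_improvement"
  }
}

terminal_event <- function(env) {
  if (env$pos1 != env$pos2) return(NULL)
  success <- fully_feasible(env, env$e2) && env$e2$L > env$L0
  if (success) "terminal_success" else "terminal_meet"
}

# Shared episode mechanics. `select(agent, obs)` returns an action;
# `on_transition(agent, obs, action, reward, obs_next, done)` is the
# learning hook. Returns the trajectory tibble.
episode_run <- function(env, select, on_transition = NULL) {
  env_reset(env)
  schedule <- env$schedule
  rows <- list()
  done <- FALSE
  guard <- 2L * (2L * env$config$max_move)
  for (step in seq_len(guard)) {
    for (agent in 1:2) {
      obs <- obs_vector(env, agent)
      action <- select(agent, obs)
      event <- if (agent == 1L) step_harvest(env, action) else step_replant(env, action)
      reward <- reward_for_event(event, schedule)
      term <- terminal_event(env)
      if (!is.null(term)) {
        done <- TRUE
        if (term == "terminal_success") {
          reward <- reward + reward_for_event("terminal_success", schedule)
          event <- "terminal_success"
        }
      }
      obs_next <- obs_vector(env, agent)
      rows[[length(rows) + 1]] <- tibble::tibble(
        step = step, agent = agent, action = action, event = event,
        reward = reward, L = env$e2$L, pos1 = env$pos1, pos2 = env$pos2)
      if (!is.null(on_transition)) {
        on_transition(agent, obs, action, reward, obs_next, done)
      }
      if (done) break
    }
    if (done) break
  }
  dplyr::bind_rows(rows)
}

#' Run a single two-agent episode
#'
#' Alternates the harvest and replant agents under fixed policies until
#' their positional counters meet (or a step guard fires). A harvest-agent
#' forward step proposes a single-tree random-selection harvest, accepted
#' only if no constraint clause fails; a replant-agent forward step moves
#' the replant count through one curve-trend window move and re-realizes
#' the planting plan. Rewards follow the [reward_schedule()].
#'
#' @param x A [stand()].
#' @param policy1,policy2 Functions mapping an observation vector to an
#'   action (1 = forward, 2 = backward).
#' @param schedule A [reward_schedule()].
#' @param config An [optimizer_config()].
#' @param config_idx An [index_config()].
#' @return List with `stand` (realized final stand), `trajectory`
#'   (tibble of per-move records), `L0`, and `L_final`.
#' @export
run_episode <- function(x, policy1, policy2, schedule = reward_schedule(),
                        config = optimizer_config(), config_idx = index_config()) {
  stopifnot(is_stand(x))
  env <- make_episode_env(x, config, config_idx, schedule)
  traj <- with_seed(config$seed,
                    episode_run(env, function(agent, obs) {
                      if (agent == 1L) policy1(obs) else policy2(obs)
                    }))
  list(stand = env$e2$stand, trajectory = traj, L0 = env$L0,
       L_final = env$e2$L)
}

# --- tabular multi-agent Q-learning ---------------------------------------

disc_state <- function(obs, max_move) {
  pos <- as.integer(round(obs[1] * 2 * max_move))
  lbin <- min(9L, max(0L, as.integer(floor((obs[11] - 0.8) / 0.05))))
  pos * 10L + lbin + 1L
}

#' Optimize a stand with tabular two-agent Q-learning
#'
#' Baseline solver: each agent keeps a Q table over (position,
#' coarse objective bin) x (forward, backward), updated with the standard
#' one-step rule, epsilon-greedy behaviour. Returns the best
#' constraint-satisfying stand seen across episodes.
#'
#' @param x A [stand()].
#' @param config An [optimizer_config()].
#' @param schedule A [reward_schedule()].
#' @param config_idx An [index_config()].
#' @return A `stand_optimization` object.
#' @export
optimize_maql <- function(x, config = optimizer_config(),
                          schedule = reward_schedule(),
                          config_idx = index_config()) {
  stopifnot(is_stand(x))
  with_seed(config$seed, {
    env <- make_episode_env(x, config, config_idx, schedule)
    nstate <- (2L * config$max_move + 1L) * 10L
    Q <- list(matrix(0, nstate, 2), matrix(0, nstate, 2))
    eps_greedy <- function(q, greedy) {
      if (runif(1) < greedy) which.max(q) else sample(2L, 1L)
    }
    episode_L <- numeric(config$episodes)
    for (ep in seq_len(config$episodes)) {
      greedy <- min(0.99, config$epsilon + config$epsilon_decay * (ep - 1))
      episode_run(env,
        select = function(agent, obs) {
          eps_greedy(Q[[agent]][disc_state(obs, config$max_move), ], greedy)
        },
        on_transition = function(agent, obs, action, reward, obs_next, done) {
          s <- disc_state(obs, config$max_move)
          s2 <- disc_state(obs_next, config$max_move)
          target <- reward + if (done) 0 else config$gamma * max(Q[[agent]][s2, ])
          Q[[agent]][s, action] <<- Q[[agent]][s, action] +
            config$lr * (target - Q[[agent]][s, action])
        })
      episode_L[ep] <- if (env$best_feasible) env$best_L else env$L0
    }
    optimization_result(env, episode_L, "MAQL", list(Q = Q))
  })
}

# --- multi-agent deep Q-network -------------------------------------------

#' Optimize a stand with the two-agent deep Q-network
#'
#' Each agent approximates its action values with a small fully-connected
#' network (three hidden layers of 24 ReLU units) over a stand-summary
#' observation (agent position, the five index means, canopy density,
#' density, budget fractions, objective ratio), trained by experience
#' replay (capacity 10000, batch 32) against a periodically synced target
#' network; behaviour is epsilon-greedy. Episode mechanics are identical
#' to [optimize_maql()]. Returns the best constraint-satisfying stand.
#'
#' @inheritParams optimize_maql
#' @return A `stand_optimization` object.
#' @export
optimize_madqn <- function(x, config = optimizer_config(),
                           schedule = reward_schedule(),
                           config_idx = index_config()) {
  stopifnot(is_stand(x))
  with_seed(config$seed, {
    env <- make_episode_env(x, config, config_idx, schedule)
    nets <- list(mlp_init(OBS_DIM, config$hidden, 2),
                 mlp_init(OBS_DIM, config$hidden, 2))
    targets <- nets
    buffers <- list(list(), list())
    learner_steps <- 0L
    episode_L <- numeric(config$episodes)
    for (ep in seq_len(config$episodes)) {
      greedy <- min(0.99, config$epsilon + config$epsilon_decay * (ep - 1))
      episode_run(env,
        select = function(agent, obs) {
          if (runif(1) < greedy) {
            which.max(mlp_predict(nets[[agent]], matrix(obs, 1)))
          } else sample(2L, 1L)
        },
        on_transition = function(agent, obs, action, reward, obs_next, done) {
          buf <- buffers[[agent]]
          if (length(buf) >= config$buffer_size) buf <- buf[-1]
          buf[[length(buf) + 1]] <- list(obs = obs, action = action,
                                         reward = reward, obs_next = obs_next,
                                         done = done)
          buffers[[agent]] <<- buf
          if (length(buf) < config$batch_size) return(invisible())
          idx <- sample.int(length(buf), config$batch_size)
          X <- do.call(rbind, lapply(buf[idx], `[[`, "obs"))
          X2 <- do.call(rbind, lapply(buf[idx], `[[`, "obs_next"))
          r <- vapply(buf[idx], `[[`, numeric(1), "reward")
          a <- vapply(buf[idx], `[[`, integer(1), "action")
          dn <- vapply(buf[idx], `[[`, logical(1), "done")
          qnext <- apply(mlp_predict(targets[[agent]], X2), 1, max)
          tgt <- r + ifelse(dn, 0, config$gamma * qnext)
          upd <- mlp_td_step(nets[[agent]], X, a, tgt, config$lr,
                             td_clip = config$td_clip)
          if (is.null(upd)) {
            abort("value-network loss diverged (non-finite TD error)",
                  class = "standopt_optimizer_error")
          }
          nets[[agent]] <<- upd
          learner_steps <<- learner_steps + 1L
          if (learner_steps %% config$target_period == 0L) {
            targets <<- nets
          }
        })
      episode_L[ep] <- if (env$best_feasible) env$best_L else env$L0
    }
    optimization_result(env, episode_L, "MADQN",
                        list(learner_steps = learner_steps,
                             buffer_fill = lengths(buffers)))
  })
}

optimization_result <- function(env, episode_L, algorithm, diagnostics) {
  best_stand <- env$best_stand %||% env$s0
  structure(list(
    initial_L = env$L0,
    best_L = if (env$best_feasible) env$best_L else env$L0,
    best_stand = best_stand,
    feasible = env$best_feasible,
    episode_L = episode_L,
    n_episodes = length(episode_L),
    algorithm = algorithm,
    diagnostics = diagnostics
  ), class = "stand_optimization")
}

#' @export
print.stand_optimization <- function(x, ...) {
  cat(sprintf("%s optimization: L %.4f -> %.4f over %d episodes (%s)\n",
              x$algorithm, x$initial_L, x$best_L, x$n_episodes,
              if (x$feasible) "feasible" else "no feasible state found"))
  invisible(x)
}

#' @export
tidy.stand_optimization <- function(x, ...) {
  tibble::tibble(episode = seq_along(x$episode_L), best_L = x$episode_L)
}

#' @export
glance.stand_optimization <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, initial_L = x$initial_L,
                 best_L = x$best_L, improvement = x$best_L / x$initial_L - 1,
                 feasible = x$feasible, n_episodes = x$n_episodes)
}
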