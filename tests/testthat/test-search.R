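test_that("termination reasons fire at the documented boundaries", {
  # stall rule: last improvement at cycle 93, K = 15 -> stop at cycle 108
  fired_at <- NA_integer_
  for (cycle in 94:200) {
    t <- check_termination(list(iteration = cycle, best_quality = 0.94,
                                best_iteration = 93), T = 200, K = 15)
    if (t$stop) { fired_at <- cycle; break }
  }
  expect_identical(fired_at, 108L)
  expect_identical(check_termination(list(iteration = 108, best_quality = 0.94,
                                          best_iteration = 93),
                                     200, 15)$reason, "stalled")

  # iteration budget
  t <- check_termination(list(iteration = 200, best_quality = 0.5,
                              best_iteration = 199), 200, 15)
  expect_identical(t$reason, "max_iterations")

  # strict ceiling semantics
  t <- check_termination(list(iteration = 10, best_quality = 1 - 1e-6,
                              best_iteration = 10), 200, 15, q_max = 1)
  expect_false(t$stop)
  t <- check_termination(list(iteration = 10, best_quality = 1,
                              best_iteration = 10), 200, 15, q_max = 1)
  expect_identical(t$reason, "quality_ceiling")
})

test_that("a constant environment stalls right after the first improvement", {
  env <- list(evaluate = function(actions) 0.5)
  team <- make_automata_team(4L)
  res <- run_search(env, team, T = 200, K = 15, seed = 1)
  # improvement only at iteration 1; K iterations later the stall fires
  expect_identical(res$iteration, 16L)
  expect_identical(res$stop_reason, "stalled")
  expect_identical(res$best_iteration, 1L)
})

test_that("the quality ceiling stops the search immediately", {
  env <- list(evaluate = function(actions) 1.0)
  team <- make_automata_team(4L)
  res <- run_search(env, team, T = 200, K = 15, q_max = 1, seed = 2)
  expect_identical(res$iteration, 1L)
  expect_identical(res$stop_reason, "quality_ceiling")
  expect_equal(res$best_quality, 1.0)
})

test_that("search state invariants hold along a stochastic run", {
  env <- make_oracle_table(3, 4, structure = "additive", seed = 5)
  team <- lapply(1:3, function(i) la_new(4))
  res <- run_search(env, team, T = 100, K = 100, seed = 3,
                    q_max = 0.999999)
  h <- res$history
  expect_lte(nrow(h), 100L)
  expect_true(all(diff(h$best_quality) >= 0))
  expect_equal(res$best_quality, max(h$quality))
  expect_identical(res$stall_count, res$iteration - res$best_iteration)
  # reward iff strict improvement over the running best
  running_best <- cummax(c(-Inf, head(h$quality, -1)))
  expect_identical(h$improved, h$quality > running_best)
  # the returned actions reproduce the best quality deterministically
  expect_equal(env$evaluate(res$best_actions), res$best_quality)
})

test_that("environment failures are scored zero and the search continues", {
  calls <- 0L
  env <- list(evaluate = function(actions) {
    calls <<- calls + 1L
    if (calls == 2L) stop("simulated training crash")
    0.4 + calls / 100
  })
  team <- make_automata_team(3L)
  expect_warning(
    res <- run_search(env, team, T = 5, K = 5, seed = 4),
    "failed"
  )
  expect_identical(res$iteration, 5L)
  expect_equal(res$history$quality[2], 0)
})

test_that("rewarded probability mass on a unique optimum never decreases", {
  # single automaton, deterministic separable oracle, no exploration, b = 0
  env <- list(evaluate = function(actions) c(0.2, 0.9, 0.4, 0.1)[actions[1]])
  la <- la_new(4, reward_coeff = 0.3, penalty_coeff = 0,
               exploration_rate = 0)
  set.seed(6)
  best <- -Inf
  prev_p2 <- la$probabilities[2]
  optimum_rewarded <- FALSE
  for (iter in 1:100) {
    sel <- la_select(la)
    la <- sel$la
    q <- env$evaluate(sel$action)
    if (q > best) {
      best <- q
      la <- la_reward(la, sel$action)
      if (sel$action == 2L) optimum_rewarded <- TRUE
    } else {
      la <- la_penalty(la, sel$action)  # identity with b = 0
    }
    # once the optimum has been rewarded no later update can shrink it:
    # further rewards require beating the best, which only the optimum does
    if (optimum_rewarded) expect_gte(la$probabilities[2] + 1e-12, prev_p2)
    prev_p2 <- la$probabilities[2]
  }
  expect_true(optimum_rewarded)
  expect_gt(la$probabilities[2], 0.25)
})

test_that("search on a tiny oracle matches exhaustive enumeration", {
  for (s in 1:5) {
    env <- make_oracle_table(4, 4, structure = "single_peak", seed = 40 + s)
    tab <- enumerate_oracle(env)
    team <- lapply(1:4, function(i) la_new(4))
    res <- run_search(env, team, T = 400, K = 400, q_max = 1, seed = s)
    expect_equal(res$best_quality, max(tab$quality))
  }
})

test_that("the JSONL log is complete, valid and resumable", {
  env <- make_oracle_table(3, 4, structure = "additive", seed = 9)
  team <- lapply(1:3, function(i) la_new(4))
  log_path <- withr::local_tempfile(fileext = ".jsonl")
  res <- run_search(env, team, T = 30, K = 30, seed = 7, q_max = 0.9999,
                    log_path = log_path)
  recs <- read_search_log(log_path)
  expect_length(recs, res$iteration)
  expect_identical(vapply(recs, function(r) r$iteration, numeric(1)),
                   as.numeric(seq_len(res$iteration)))
  expect_equal(recs[[res$iteration]]$best_quality, res$best_quality)
  expect_length(recs[[1]]$automata_max_p, 3L)
  # truncated trailing line is detected and dropped
  cat("{\"iteration\": 31, \"trunc", file = log_path, append = TRUE)
  expect_warning(recs2 <- read_search_log(log_path), "malformed")
  expect_length(recs2, res$iteration)
})

test_that("the CNN environment is deterministic and bounded", {
  spec <- phantom_spec(shape = c(16L, 16L))
  train <- generate_dataset(3, spec, seed = 21)
  val <- generate_dataset(2, spec, seed = 22)
  sub <- conv_action_subspace(n_filters = 32L, filter_lengths = c(1L, 3L),
                              filter_widths = 1L)
  st <- training_settings(max_epochs = 3, patience_epochs = 3,
                          batch_size = 2, patch_shape = c(8L, 8L), seed = 5)
  env <- make_cnn_environment(train, val, st, action_subset = sub,
                              model_seed = 5)
  acts <- c(rep(2L, 19L), 1L, 2L)
  q1 <- env$evaluate(acts)
  q2 <- env$evaluate(acts)
  expect_identical(q1, q2)
  expect_gte(q1, 0)
  expect_lte(q1, 1)
  cfg <- env$assemble(acts)
  expect_s3_class(cfg, "network_configuration")
  expect_identical(cfg$conv_indices, rep(sub[2], 19L))
})
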