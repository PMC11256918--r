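test_that("policy outputs are proper action distributions and seeded", {
  set.seed(61)
  pol <- build_policy(policy_config(), kappa = 3)
  w <- matrix(sample(0:20, 35, TRUE), nrow = 5)
  p <- policy_probs(pol, w)
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  expect_true(all(p > 0))
  set.seed(61)
  pol2 <- build_policy(policy_config(), kappa = 3)
  expect_identical(pol$params, pol2$params)
})

test_that("unsupported architecture settings are configuration errors", {
  expect_error(policy_config(lstm_layers = 1), "not implemented")
  expect_error(policy_config(conv_layers = list(c(3, 8))), "not implemented")
})

test_that("gradient steps move probability toward rewarded actions", {
  set.seed(62)
  pol <- build_policy(policy_config(learning_rate = 0.05), kappa = 1)
  w <- c(19L, 19L, 19L)
  before <- policy_probs(pol, w)[1, 2]
  # two-armed bandit: reward 1 for action 1 (G), 0 otherwise
  for (i in 1:30) {
    eps <- lapply(0:3, function(a) list(windows = matrix(w, nrow = 1),
                                        actions = a,
                                        reward = as.numeric(a == 1)))
    pol <- rnamotiflib:::policy_update(pol, eps)
  }
  after <- policy_probs(pol, w)[1, 2]
  expect_gt(after, before)
})

test_that("the bandit reduction concentrates on the rewarded action", {
  tk <- task("?", "?")
  obj <- objective("bandit", function(cand, task) as.numeric(cand$sequence == "G"))
  cfg <- env_config(state_radius = 2, engine = nussinov_engine(), objective = obj)
  set.seed(63)
  pol <- build_policy(policy_config(), kappa = 2)
  res <- train(pol, tk, cfg, training_config(episodes = 1000, seed = 63))
  p <- policy_probs(res$policy, observe(encode_task(tk, 2), tk, 0, cfg))[1, ]
  expect_gte(p[2], 0.9)
})

test_that("training improves reward on a trivial open design task", {
  tk <- task("????", "....")
  cfg <- env_config(state_radius = 2, engine = nussinov_engine())
  set.seed(64)
  pol <- build_policy(policy_config(), kappa = 2)
  res <- train(pol, tk, cfg, training_config(episodes = 600, seed = 64))
  expect_equal(nrow(res$log), 600)
  expect_gt(mean(tail(res$log$reward, 100)), mean(head(res$log$reward, 100)) - 1e-9)
})

test_that("restart restores the exact initial parameters", {
  set.seed(65)
  pol <- build_policy(policy_config(), kappa = 2)
  init <- pol$params
  tk <- task("??", "..")
  cfg <- env_config(state_radius = 2, engine = nussinov_engine())
  res <- train(pol, tk, cfg, training_config(episodes = 50, seed = 65))
  expect_false(identical(res$policy$params, init))
  back <- policy_restart(res$policy)
  expect_identical(back$params, init)
})

test_that("the design loop emits exact budgets and reproducible streams", {
  sp <- parse_design_space("????????", "((....))")
  obj <- structure_objective()
  cfg <- env_config(state_radius = 3, engine = nussinov_engine())
  set.seed(66); pol <- build_policy(policy_config(), kappa = 3)
  a <- design(pol, sp, obj, n_candidates = 15, env_cfg = cfg, seed = 66)
  expect_equal(nrow(a), 15)
  set.seed(66); pol2 <- build_policy(policy_config(), kappa = 3)
  b <- design(pol2, sp, obj, n_candidates = 15, env_cfg = cfg, seed = 66)
  expect_identical(a, b)
})

test_that("the solved flag agrees with the two constraint relations", {
  sp <- parse_design_space("????????", "((....))")
  obj <- structure_objective()
  cfg <- env_config(state_radius = 3, engine = nussinov_engine())
  out <- random_agent(sp, obj, n_candidates = 40, env_cfg = cfg, seed = 67)
  for (i in seq_len(nrow(out))) {
    tk <- task(out$task_sequence[i], out$task_structure[i])
    cand <- candidate(out$sequence[i], folded_structure = out$structure[i])
    expect_equal(out$solved[i],
                 satisfies_hard_constraints(tk, cand) &&
                   satisfies_folding_relation(cand, tk, nussinov_engine()))
  }
})

test_that("a single unconstrained position is always solved", {
  sp <- parse_design_space("?", ".")
  obj <- structure_objective()
  cfg <- env_config(state_radius = 2, engine = nussinov_engine())
  out <- random_agent(sp, obj, n_candidates = 400, env_cfg = cfg, seed = 68)
  expect_equal(mean(out$solved), 1.0)
})

test_that("random agent actions are uniform and respect constraints", {
  sp <- parse_design_space("A???A", ".....")
  obj <- structure_objective()
  cfg <- env_config(state_radius = 2, engine = nussinov_engine())
  out <- random_agent(sp, obj, n_candidates = 1200, env_cfg = cfg, seed = 69)
  expect_true(all(substr(out$sequence, 1, 1) == "A"))
  expect_true(all(substr(out$sequence, 5, 5) == "A"))
  nts <- unlist(strsplit(substr(out$sequence, 2, 4), ""))
  freq <- table(factor(nts, levels = c("A", "C", "G", "U"))) / length(nts)
  sigma <- sqrt(0.25 * 0.75 / length(nts))
  expect_true(all(abs(freq - 0.25) < 3 * sigma + 1e-12))
})

test_that("policy checkpoints round-trip through JSON", {
  set.seed(70)
  pol <- build_policy(policy_config(dense_units = c(16, 8)), kappa = 2)
  path <- withr::local_tempfile(fileext = ".json")
  save_policy(pol, path)
  back <- load_policy(path)
  expect_equal(back$params, pol$params, tolerance = 1e-12)
  expect_equal(back$init_params, pol$init_params, tolerance = 1e-12)
  expect_equal(back$cfg, pol$cfg)
  w <- matrix(sample(0:20, 10, TRUE), nrow = 2)
  expect_equal(policy_probs(back, w), policy_probs(pol, w), tolerance = 1e-12)
})
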