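test_that("structure loss counts violated constrained positions only", {
  expect_equal(structure_loss("(((...)))", "(((...)))"), 0)
  expect_equal(structure_loss("((..))", "((()))"), 2)
  expect_equal(structure_loss("((????))?", "((....))."), 0)
  expect_error(structure_loss("((", "((("), "differs")
  # with no wildcard it reduces to the plain Hamming distance
  set.seed(41)
  syms <- c(".", "(", ")")
  for (rep in 1:10) {
    a <- paste(sample(syms, 12, TRUE), collapse = "")
    b <- paste(sample(syms, 12, TRUE), collapse = "")
    expect_equal(structure_loss(a, b),
                 sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]))
  }
})

test_that("structure and combined rewards follow the closed forms", {
  expect_equal(structure_reward(0, 8, 2.7), 1)
  expect_equal(structure_reward(8, 8, 0.5), 0)
  expect_equal(structure_reward(2, 8, 1), 0.75)
  expect_equal(combined_reward(0, 8, 0), 1)
  expect_equal(combined_reward(loss = 0.8 * 10, length = 10, gc_l = 0.3), 0)
  expect_equal(combined_reward(2, 8, 0.1), 0.65)
  # monotone non-increasing in loss, bounded in [0, 1]
  r <- vapply(0:8, function(l) structure_reward(l, 8, 1.7), numeric(1))
  expect_true(all(diff(r) <= 0) && all(r >= 0) && all(r <= 1))
  rc <- vapply(0:8, function(l) combined_reward(l, 8, 0.2), numeric(1))
  expect_true(all(diff(rc) <= 0) && all(rc >= 0) && all(rc <= 1))
})

test_that("gc loss applies the tolerance band and ignores ordering", {
  expect_equal(gc_loss("AUGC", 0.5, 0.01), 0)
  expect_equal(gc_loss("AUGC", 0.54, 0.01), 0.04)
  expect_equal(gc_loss("AUGC", 0.505, 0.01), 0)
  set.seed(42)
  s <- random_rna(30)
  perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(gc_loss(s, 0.7, 0.01), gc_loss(perm, 0.7, 0.01))
})

test_that("WL distance is a bounded metric-like score on structure graphs", {
  for (s in c("((....))", "...", "(((...)))...((...))")) {
    expect_equal(wl_distance(s, s, 2), 0, tolerance = 1e-9)
  }
  expect_equal(wl_distance("...", "(((", 1), 1)
  d1 <- wl_distance("((....))", "((...)).", 2)
  d2 <- wl_distance("((...)).", "((....))", 2)
  expect_equal(d1, d2)
  # frozen value from an independent label-refinement implementation
  expect_equal(d1, 1 / 6, tolerance = 1e-9)
  expect_true(d1 > 0 && d1 < 1)
})

test_that("plug-in transforms implement the bitscore floor and cubic energy map", {
  expect_equal(plugin_reward_transform(NA, "bitscore"), -200)
  expect_equal(plugin_reward_transform(31.5, "bitscore"), 31.5)
  expect_equal(plugin_reward_transform(-10, "rri_energy"), 1000)
  expect_equal(plugin_reward_transform(0, "rri_energy"), 0)
})

test_that("plugin objectives wrap a scorer behind the objective contract", {
  scorer <- function(seq) if (grepl("GG", seq)) nchar(seq) else NA
  obj <- plugin_objective("toy", scorer, "bitscore", solved_threshold = 4)
  expect_equal(obj$reward_fun(candidate("AGGA"), NULL), 4)
  expect_equal(obj$reward_fun(candidate("AUAU"), NULL), -200)
  expect_true(obj$solved_fun(candidate("AGGA"), NULL))
})

test_that("local improvement repairs a near-miss and respects its gate", {
  eng <- nussinov_engine()
  # GGGAAAACCC folds into three pairs; breaking the closing C at a free
  # position lets the 4-way enumeration recover a zero-loss assignment
  tk <- task("GGGAAAACC?", "(((....)))")
  broken <- candidate("GGGAAAACCA")
  expect_gt(structure_loss(tk$structure_constraints, fold(eng, broken$sequence)), 0)
  fixed <- local_improvement(broken, tk, eng)
  expect_equal(structure_loss(tk$structure_constraints, fixed$folded_structure), 0)
  expect_true(satisfies_hard_constraints(tk, fixed))

  # zero-loss input is returned unchanged
  good <- candidate("GGGAAAACCC", folded_structure = fold(eng, "GGGAAAACCC"))
  expect_identical(local_improvement(good, tk, eng)$sequence, good$sequence)

  # above the mismatch gate nothing happens
  far <- candidate("AAAAAAAAAA")
  same <- local_improvement(far, tk, eng, max_mismatches = 1)
  expect_identical(same$sequence, far$sequence)
})

test_that("GC improvement walks free positions toward the target", {
  eng <- nussinov_engine()
  cfg <- reward_config(gc_desired = 1, gc_tolerance = 0.01)
  tk <- task("????", "????")
  out <- gc_improvement(candidate("AAAA"), tk, cfg, eng)
  expect_true(all(strsplit(out$sequence, "")[[1]] %in% c("G", "C")))

  # already inside the tolerance band: unchanged
  cfg2 <- reward_config(gc_desired = 0.5, gc_tolerance = 0.01)
  inband <- gc_improvement(candidate("AUGC"), tk, cfg2, eng)
  expect_equal(inband$sequence, "AUGC")

  # no free positions: unchanged
  tk3 <- task("AAAA", "????")
  expect_equal(gc_improvement(candidate("AAAA"), tk3, cfg, eng)$sequence, "AAAA")
})

test_that("refinement never violates the sequence channel", {
  eng <- nussinov_engine()
  set.seed(43)
  for (rep in 1:10) {
    n <- sample(8:14, 1)
    seq <- random_rna(n)
    phi <- strsplit(seq, "")[[1]]
    phi[sample(n, n %/% 2)] <- "?"
    omega <- strsplit(nussinov_fold(random_rna(n)), "")[[1]]
    tk <- task(paste(phi, collapse = ""), paste(omega, collapse = ""))
    cand <- candidate(seq)
    cfg <- reward_config(gc_desired = 0.5, gc_tolerance = 0.05)
    out <- gc_improvement(local_improvement(cand, tk, eng), tk, cfg, eng)
    keep <- phi != "?"
    expect_equal(strsplit(out$sequence, "")[[1]][keep], phi[keep])
  }
})
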