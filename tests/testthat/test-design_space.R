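test_that("parsing splits motifs at variable-length wildcards", {
  sp <- parse_design_space("????????", "((....))")
  expect_length(sp$motifs, 1)
  expect_equal(sp$motifs[[1]]$fixed_length, 8L)
  expect_equal(length_bounds(sp), c(8L, 8L))

  sp3 <- parse_design_space("?*?GUAA??*", "?*(....)?*", min_len = 6, max_len = 60)
  expect_length(sp3$motifs, 3)
  expect_true(sp3$motifs[[1]]$variable)
  expect_equal(sp3$motifs[[2]]$sequence_part, "?GUAA?")
  expect_equal(sp3$motifs[[2]]$structure_part, "(....)")
  expect_true(sp3$motifs[[3]]$variable)
})

test_that("parse errors name the offending position or region", {
  expect_error(parse_design_space("??", "((("), "2 sequence tokens")
  expect_error(parse_design_space("?X?", "..."), "position 2")
  expect_error(parse_design_space("*??", "..."), "after '\\?'")
  expect_error(parse_design_space("?*??", "?*?)", min_len = 2, max_len = 9), NA)
  expect_error(parse_design_space("?*??", "????"), "variable-length region")
  expect_error(parse_design_space("?*?", "?*?"),
               "min_len and max_len are required")
  expect_error(parse_design_space("??", "??", min_len = 1, max_len = 3),
               "must equal the fixed length")
})

test_that("length bounds clamp the lower end to the fixed token count", {
  sp <- parse_design_space("?*?GUAA??*", "?*(....)?*", min_len = 3, max_len = 60)
  expect_equal(length_bounds(sp), c(6L, 60L))
  sp2 <- parse_design_space("?*?GUAA??*", "?*(....)?*", min_len = 6, max_len = 60)
  expect_equal(length_bounds(sp2), c(6L, 60L))
})

test_that("rendering a parsed space reproduces the input token stream", {
  for (lines in list(c("????????", "((....))"),
                     c("?*?GUAA??*", "?*(....)?*"),
                     c("AC?*GU", "..?*()"))) {
    has_var <- grepl("?*", lines[1], fixed = TRUE)
    sp <- parse_design_space(lines[1], lines[2],
                             min_len = if (has_var) 4, max_len = if (has_var) 30)
    expect_equal(unname(format(sp)), lines)
  }
})

test_that("sampled tasks have the right length and contain fixed tokens in order", {
  sp <- parse_design_space("?*?GUAA??*", "?*(....)?*", min_len = 6, max_len = 20)
  set.seed(11)
  for (i in 1:50) {
    tk <- sample_task(sp)
    expect_equal(nchar(tk$sequence_constraints), tk$length)
    expect_equal(nchar(tk$structure_constraints), tk$length)
    expect_true(tk$length >= 6 && tk$length <= 20)
    expect_match(tk$sequence_constraints, "GUAA", fixed = TRUE)
    expect_match(tk$structure_constraints, "(....)", fixed = TRUE)
  }
})

test_that("task sampling with no variable region has no freedom", {
  sp <- parse_design_space("????????", "((....))")
  set.seed(1)
  tk <- sample_task(sp)
  expect_equal(tk$sequence_constraints, "????????")
  expect_equal(tk$structure_constraints, "((....))")
  expect_error(sample_task(sp, 9), "outside feasible bounds")
})

test_that("fixed-length sampling matches the enumeration oracle", {
  sp <- parse_design_space("?*?GUAA??*", "?*(....)?*", min_len = 6, max_len = 10)
  # the only length-6 instantiation is the bare motif
  set.seed(2)
  tk6 <- sample_task(sp, 6)
  expect_equal(tk6$sequence_constraints, "?GUAA?")
  expect_equal(tk6$structure_constraints, "(....)")
  # every draw lies in the exhaustively enumerated instantiation set and the
  # whole set is covered
  enum <- oracle_enumerate_instantiations("?*?GUAA??*", "?*(....)?*", 6, 10)
  set.seed(3)
  seen <- replicate(2000, {
    tk <- sample_task(sp)
    paste0(tk$sequence_constraints, "/", tk$structure_constraints)
  })
  expect_true(all(seen %in% enum))
  expect_setequal(unique(seen), enum)
})

test_that("hard-constraint relation checks both channels position-wise", {
  tk <- task("??GACU??C", "?????????")
  expect_true(satisfies_hard_constraints(tk, candidate("AAGACUGGC")))
  expect_false(satisfies_hard_constraints(tk, candidate("AAGACUGGA")))

  tk2 <- task("?????????", "((????))?")
  cand <- candidate("GGAAAAUCC", folded_structure = "((....)).")
  expect_true(satisfies_hard_constraints(tk2, cand))
  expect_error(satisfies_hard_constraints(tk2, candidate("GGAAAAUCC")),
               "no folded_structure")
  expect_error(satisfies_hard_constraints(tk2, candidate("GGAAAAUCCA")),
               "differs from task length")
})

test_that("hard constraints are monotone under constraint relaxation", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    seq <- random_rna(n)
    db <- nussinov_fold(seq)
    # random constraints, partially satisfied
    phi <- strsplit(seq, "")[[1]]
    phi[sample(n, n %/% 2)] <- "?"
    omega <- strsplit(db, "")[[1]]
    omega[sample(n, n %/% 2)] <- "?"
    flip <- sample(n, 1)
    omega[flip] <- sample(setdiff(c(".", "(", ")"), omega[flip]), 1)
    tk <- task(paste(phi, collapse = ""), paste(omega, collapse = ""))
    cand <- candidate(seq, folded_structure = db)
    before <- satisfies_hard_constraints(tk, cand)
    # relax one constrained position
    constrained <- which(omega != "?")
    omega[sample(constrained, 1)] <- "?"
    tk2 <- task(tk$sequence_constraints, paste(omega, collapse = ""))
    after <- satisfies_hard_constraints(tk2, cand)
    expect_true(!before || after)
  }
})

test_that("folding relation agrees with a direct fold call", {
  eng <- nussinov_engine()
  tk <- task("??????????", "((????))??")
  cand <- candidate("GGGAAAACCC")
  direct <- fold(eng, "GGGAAAACCC")
  expect_equal(satisfies_folding_relation(cand, tk, eng),
               oracle_matches_constraints(direct, tk$structure_constraints))
  # unconstrained structure is always satisfied
  expect_true(satisfies_folding_relation(candidate("AAAA"), task("????", "????"), eng))
})

test_that("design space files round-trip including bounds and comments", {
  sp <- parse_design_space("?*AC?GU?*", "?*(...)?*", min_len = 7, max_len = 30)
  path <- withr::local_tempfile(fileext = ".txt")
  write_design_space(sp, path)
  sp2 <- read_design_space(path)
  expect_equal(format(sp2), format(sp))
  expect_equal(length_bounds(sp2), length_bounds(sp))
})

test_that("candidate FASTA and sidecar files are written", {
  df <- data.frame(id = c("a", "b"), sequence = c("ACGU", "GGGC"),
                   gc = c(0.5, 1), stringsAsFactors = FALSE)
  fasta <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_candidates(df, fasta, tsv)
  back <- read_fasta(fasta)
  expect_equal(unname(back), df$sequence)
  expect_equal(names(back), df$id)
  side <- read.delim(tsv)
  expect_equal(side$gc, df$gc)
})
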