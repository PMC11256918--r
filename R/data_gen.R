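#' Synthetic training-corpus specification
#'
#' The corpus generator emulates a folded RNA collection: uniform-random
#' sequences with one of three length distributions (mirroring sets of at most
#' 200 nt, at least 200 nt, and mixed lengths), folded by a configurable
#' engine. Desk-scale length ranges are 50-200 nt (`short`), 200-350 nt
#' (`long`) and 50-350 nt (`mixed`).
#'
#' @param n_samples Number of (sequence, structure) pairs (> 0).
#' @param length_distribution One of `"short"`, `"long"`, `"mixed"`.
#' @param seed Integer seed making the corpus reproducible.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_samples, length_distribution = c("short", "long", "mixed"),
                        seed = 1L) {
  stopifnot(n_samples > 0)
  structure(list(n_samples = as.integer(n_samples),
                 length_distribution = match.arg(length_distribution),
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Generate a synthetic folded corpus
#'
#' @param spec A [corpus_spec()].
#' @param engine A [folding_engine()] (default the bundled Nussinov folder).
#' @return Data frame with columns `sequence` and `structure`.
#' @export
generate_corpus <- function(spec, engine = nussinov_engine()) {
  stopifnot(inherits(spec, "corpus_spec"))
  set.seed(spec$seed)
  range <- switch(spec$length_distribution,
                  short = c(50L, 200L), long = c(200L, 350L), mixed = c(50L, 350L))
  lens <- range[1] + sample.int(range[2] - range[1] + 1L, spec$n_samples,
                                replace = TRUE) - 1L
  seqs <- vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
  }, character(1))
  data.frame(sequence = seqs, structure = fold(engine, seqs),
             stringsAsFactors = FALSE)
}

#' Masking specification
#'
#' Controls the masked-task pipeline: up to `max_parts` non-overlapping
#' structure intervals are masked, each covering at most `max_part_fraction`
#' of the length; the sequence is masked on the complement so constraints
#' alternate between the two channels; a `random_mask_fraction` share of
#' samples instead receives independent random sequence masking.
#'
#' @param max_parts Maximum number of masked structure intervals (default 5).
#' @param max_part_fraction Maximum interval length as a fraction of the total
#'   length (default 0.2).
#' @param random_mask_fraction Probability that a sample gets random sequence
#'   masking instead of complementary masking (default 0.2).
#' @return An object of class `masking_spec`.
#' @export
masking_spec <- function(max_parts = 5, max_part_fraction = 0.2,
                         random_mask_fraction = 0.2) {
  stopifnot(max_parts >= 0, max_part_fraction > 0, max_part_fraction <= 1,
            random_mask_fraction >= 0, random_mask_fraction <= 1)
  structure(list(max_parts = as.integer(max_parts),
                 max_part_fraction = max_part_fraction,
                 random_mask_fraction = random_mask_fraction),
            class = "masking_spec")
}

# Draw up to `n_parts` non-overlapping intervals of length <= max_len each,
# uniform positions and lengths, by rejection (a failed draw is skipped).
draw_intervals <- function(L, n_parts, max_len) {
  covered <- rep(FALSE, L)
  intervals <- list()
  for (p in seq_len(n_parts)) {
    for (try in 1:50) {
      len <- sample.int(max_len, 1L)
      start <- sample.int(L - len + 1L, 1L)
      span <- start:(start + len - 1L)
      if (!any(covered[span])) {
        covered[span] <- TRUE
        intervals[[length(intervals) + 1L]] <- span
        break
      }
    }
  }
  intervals
}

#' Mask one corpus sample into a design task
#'
#' Implements the masked training objective: structure intervals are masked
#' with `?`, the sequence is masked on the structure-unmasked complement
#' (alternating constraints), and a random share of samples gets independent
#' Bernoulli(0.5) sequence masking instead. When no structure interval is
#' drawn the result is a plain inverse-folding task (fully masked sequence,
#' fully constrained structure).
#'
#' @param sequence,structure One corpus entry (equal lengths).
#' @param spec A [masking_spec()].
#' @return An [task()] with attribute `category` set to `"inverse"`,
#'   `"alternating"` or `"random"`.
#' @export
mask_sample <- function(sequence, structure, spec = masking_spec()) {
  L <- nchar(sequence)
  stopifnot(L == nchar(structure), L >= 1)
  seq_chars <- strsplit(sequence, "")[[1]]
  struct_chars <- strsplit(structure, "")[[1]]
  n_parts <- sample.int(spec$max_parts + 1L, 1L) - 1L
  max_len <- max(1L, floor(spec$max_part_fraction * L))
  intervals <- if (n_parts > 0) draw_intervals(L, n_parts, max_len) else list()
  struct_masked <- rep(FALSE, L)
  for (span in intervals) struct_masked[span] <- TRUE
  struct_chars[struct_masked] <- "?"
  random_branch <- stats::runif(1) < spec$random_mask_fraction
  if (random_branch) {
    seq_chars[stats::runif(L) < 0.5] <- "?"
    category <- "random"
  } else {
    seq_chars[!struct_masked] <- "?"
    category <- if (length(intervals) == 0) "inverse" else "alternating"
  }
  out <- task(paste(seq_chars, collapse = ""), paste(struct_chars, collapse = ""))
  attr(out, "category") <- category
  out
}

#' Build a masked training set from a corpus
#'
#' Applies [mask_sample()] to every corpus entry.
#'
#' @param corpus Data frame with `sequence` and `structure` columns.
#' @param spec A [masking_spec()].
#' @param seed Optional seed for the masking draws.
#' @return List of [task()] objects; `attr(, "categories")` records each
#'   task's masking category for reporting.
#' @export
build_training_set <- function(corpus, spec = masking_spec(), seed = NULL) {
  stopifnot(is.data.frame(corpus), nrow(corpus) > 0)
  if (!is.null(seed)) set.seed(seed)
  tasks <- vector("list", nrow(corpus))
  categories <- character(nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    tasks[[i]] <- mask_sample(corpus$sequence[i], corpus$structure[i], spec)
    categories[i] <- attr(tasks[[i]], "category")
  }
  attr(tasks, "categories") <- categories
  tasks
}

#' Read or write a two-column corpus file
#'
#' Tab-separated file with columns `sequence` and `structure`; a user-supplied
#' corpus of real folded RNAs can be loaded the same way for fidelity runs.
#'
#' @param corpus Data frame with `sequence` and `structure`.
#' @param path File path.
#' @return `read_corpus` returns the corpus data frame.
#' @export
write_corpus <- function(corpus, path) {
  utils::write.table(corpus[, c("sequence", "structure")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  corpus <- utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  stopifnot(all(c("sequence", "structure") %in% names(corpus)))
  corpus
}
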