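# Theophylline riboswitch protocol: TCT8-4 aptamer + spacer + anti-aptamer
# complement + 8xU terminator tail (transcriptional OFF switch).

RIBOSWITCH_APTAMER <- "AAGUGAUACCAGCAUCGUCUUGAUGCCCUUGGCAGCACUUCA"
RIBOSWITCH_USTRETCH <- "UUUUUUUU"
RIBOSWITCH_SPACER_RANGE <- c(6L, 20L)
RIBOSWITCH_COMPLEMENT_RANGE <- c(10L, 21L)

rna_revcomp <- function(x) {
  chartr("ACGU", "UGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

#' TCT8-4 theophylline aptamer
#'
#' The aptamer sequence used by the riboswitch protocol, with the fixed
#' 10-nt reverse complement of its 3' end that seeds the terminator stem.
#'
#' @return List with `sequence`, `complement10` and the component length
#'   ranges of the construct.
#' @export
theophylline_aptamer <- function() {
  list(sequence = RIBOSWITCH_APTAMER,
       complement10 = rna_revcomp(substr(RIBOSWITCH_APTAMER,
                                         nchar(RIBOSWITCH_APTAMER) - 9L,
                                         nchar(RIBOSWITCH_APTAMER))),
       spacer_range = RIBOSWITCH_SPACER_RANGE,
       complement_range = RIBOSWITCH_COMPLEMENT_RANGE,
       u_stretch = RIBOSWITCH_USTRETCH)
}

#' Riboswitch design space
#'
#' Parses the packaged design-space record (a reconstruction of the published
#' construct layout: aptamer, variable spacer, fixed terminator-seed
#' complement, variable extension, 8-U tail) or a user-supplied definition.
#'
#' @param path Design-space file; defaults to the packaged record.
#' @return An `rna_design_space` with total length bounds 66-91 nt.
#' @export
riboswitch_space <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "riboswitch_design_space_synthetic.txt",
                        package = "rnamotiflib", mustWork = TRUE)
  }
  read_design_space(path)
}

#' Instantiated riboswitch task for given component lengths
#'
#' @param spacer_len Spacer length (6-20 nt).
#' @param complement_len Complement length (10-21 nt); the part beyond the
#'   fixed 10-nt seed becomes unconstrained extension positions.
#' @return An [task()] of length `42 + spacer_len + complement_len + 8`.
#' @export
riboswitch_task <- function(spacer_len, complement_len) {
  stopifnot(spacer_len >= RIBOSWITCH_SPACER_RANGE[1],
            spacer_len <= RIBOSWITCH_SPACER_RANGE[2],
            complement_len >= RIBOSWITCH_COMPLEMENT_RANGE[1],
            complement_len <= RIBOSWITCH_COMPLEMENT_RANGE[2])
  apt <- theophylline_aptamer()
  ext <- complement_len - 10L
  task(
    paste0(apt$sequence, strrep("?", spacer_len), apt$complement10,
           strrep("?", ext), apt$u_stretch),
    paste0(strrep("?", nchar(apt$sequence) - 10L), strrep("(", 10L),
           strrep("?", spacer_len), strrep(")", 10L),
           strrep("?", ext), strrep(".", 8L))
  )
}

#' Random riboswitch baseline sampler
#'
#' Reimplementation of the original library construction: a uniform random
#' spacer of 6-20 nt and a 10-21 nt exact reverse complement of the aptamer
#' 3' end are concatenated with the aptamer and the 8-U tail. Uses the
#' current R random number generator.
#'
#' @param n Number of candidates.
#' @return Data frame with `sequence`, `spacer_len` and `complement_len`.
#' @export
wachsmuth_sample <- function(n = 1) {
  apt <- theophylline_aptamer()
  spacer_len <- sample(RIBOSWITCH_SPACER_RANGE[1]:RIBOSWITCH_SPACER_RANGE[2],
                       n, replace = TRUE)
  complement_len <- sample(
    RIBOSWITCH_COMPLEMENT_RANGE[1]:RIBOSWITCH_COMPLEMENT_RANGE[2],
    n, replace = TRUE)
  La <- nchar(apt$sequence)
  seqs <- vapply(seq_len(n), function(i) {
    spacer <- paste(sample(c("A", "C", "G", "U"), spacer_len[i], replace = TRUE),
                    collapse = "")
    comp <- rna_revcomp(substr(apt$sequence, La - complement_len[i] + 1L, La))
    paste0(apt$sequence, spacer, comp, apt$u_stretch)
  }, character(1))
  data.frame(sequence = seqs, spacer_len = spacer_len,
             complement_len = complement_len, stringsAsFactors = FALSE)
}

#' Evaluate design-criteria validity of candidates
#'
#' Folds every candidate with the engine and applies the criteria to each
#' (candidate, task) pair. The default criteria are the structure constraints
#' of the instantiated design space evaluated position-wise on the MFE fold,
#' together with the sequence channel, i.e. the hard-constraint relation; a
#' custom criteria function `(sequence, folded, task) -> named logical`
#' can replace them.
#'
#' @param sequences Character vector of candidate sequences.
#' @param tasks List of [task()] objects, one per candidate (a single task is
#'   recycled).
#' @param engine A [folding_engine()].
#' @param criteria Optional criteria function.
#' @return Logical vector (all criteria satisfied), with the folded
#'   structures in `attr(, "structures")` and the per-criterion outcomes in
#'   `attr(, "criteria")`.
#' @export
evaluate_validity <- function(sequences, tasks, engine, criteria = NULL) {
  if (inherits(tasks, "rna_task")) tasks <- list(tasks)
  if (length(tasks) == 1L) tasks <- rep(tasks, length(sequences))
  stopifnot(length(tasks) == length(sequences))
  folded <- fold(engine, sequences)
  if (is.null(criteria)) criteria <- design_space_criteria
  outcomes <- lapply(seq_along(sequences), function(i) {
    criteria(sequences[i], folded[i], tasks[[i]])
  })
  per <- do.call(rbind, lapply(outcomes, function(x) as.data.frame(as.list(x))))
  valid <- vapply(outcomes, all, logical(1))
  attr(valid, "structures") <- folded
  attr(valid, "criteria") <- per
  valid
}

# Default criteria: the hard-constraint relation of the instantiated task,
# split into its two channels.
design_space_criteria <- function(sequence, folded, task) {
  phi <- strsplit(task$sequence_constraints, "")[[1]]
  omega <- strsplit(task$structure_constraints, "")[[1]]
  s <- strsplit(sequence, "")[[1]]
  f <- strsplit(folded, "")[[1]]
  c(sequence_constraints = all(s[phi != "?"] == phi[phi != "?"]),
    structure_constraints = all(f[omega != "?"] == omega[omega != "?"]))
}

#' Achievable GC-content bounds of a design space
#'
#' Minimum and maximum GC fraction over all admissible lengths and
#' assignments: fixed nucleotides contribute their own GC count, free
#' positions are filled with A/U for the minimum and G/C for the maximum.
#'
#' @param space An `rna_design_space`.
#' @return Numeric vector `c(min, max)`.
#' @export
gc_bounds <- function(space) {
  stopifnot(inherits(space, "rna_design_space"))
  seq_line <- format(space)[["sequence"]]
  tokens <- tokenize_constraints(seq_line, SEQ_TOKENS, "sequence")$tokens
  fixed <- tokens[!tokens %in% c("?", "?*")]
  g <- sum(fixed %in% c("G", "C"))
  f <- length(tokens[tokens != "?*"])  # fixed-position count incl. single '?'
  n_known <- length(fixed)
  b <- length_bounds(space)
  lo <- 1; hi <- 0
  for (L in b[1]:b[2]) {
    free <- L - n_known
    lo <- min(lo, g / L)
    hi <- max(hi, (g + free) / L)
  }
  c(lo, hi)
}

#' Library report
#'
#' Summarises a designed candidate library: number of candidates, the
#' percentage passing the validity criteria, the number of distinct folded
#' structures (over all candidates, with the valid-only count reported
#' alongside), and histograms over length and GC content.
#'
#' @param sequences Candidate sequences (character vector or a [design()]
#'   result data frame with a `sequence` column).
#' @param tasks Per-candidate [task()] list (or one task recycled). For
#'   baseline riboswitch candidates from [wachsmuth_sample()] the tasks are
#'   derived from `spacer_len`/`complement_len` automatically.
#' @param engine A [folding_engine()].
#' @param criteria Optional criteria function, see [evaluate_validity()].
#' @param gc_binwidth Width of the GC histogram bins (default 0.05).
#' @return An object of class `library_report`.
#' @export
library_report <- function(sequences, tasks = NULL, engine, criteria = NULL,
                           gc_binwidth = 0.05) {
  if (is.data.frame(sequences)) {
    df <- sequences
    if (is.null(tasks) && all(c("spacer_len", "complement_len") %in% names(df))) {
      tasks <- lapply(seq_len(nrow(df)), function(i) {
        riboswitch_task(df$spacer_len[i], df$complement_len[i])
      })
    }
    if (is.null(tasks) && all(c("task_sequence", "task_structure") %in% names(df))) {
      tasks <- lapply(seq_len(nrow(df)), function(i) {
        task(df$task_sequence[i], df$task_structure[i])
      })
    }
    sequences <- df$sequence
  }
  stopifnot(length(sequences) > 0, !is.null(tasks))
  valid <- evaluate_validity(sequences, tasks, engine, criteria)
  structs <- attr(valid, "structures")
  gc <- vapply(sequences, gc_content, numeric(1), USE.NAMES = FALSE)
  lens <- nchar(sequences)
  gc_bins <- cut(gc, breaks = seq(0, 1, by = gc_binwidth), include.lowest = TRUE)
  rep <- list(n_candidates = length(sequences),
              valid_fraction = 100 * mean(valid),
              unique_structures = length(unique(structs)),
              unique_structures_valid = length(unique(structs[valid])),
              length_histogram = table(lens),
              gc_histogram = table(gc_bins),
              engine = engine$name,
              criteria_outcomes = attr(valid, "criteria"),
              valid = valid)
  class(rep) <- "library_report"
  rep
}

#' @export
print.library_report <- function(x, ...) {
  cat("Candidate library report (engine: ", x$engine, ")\n", sep = "")
  cat("  candidates:            ", x$n_candidates, "\n")
  cat("  valid candidates (%):  ", round(x$valid_fraction, 1), "\n")
  cat("  unique structures:     ", x$unique_structures,
      " (valid only: ", x$unique_structures_valid, ")\n", sep = "")
  cat("  length range:          ",
      paste(range(as.integer(names(x$length_histogram))), collapse = "-"), "nt\n")
  invisible(x)
}
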