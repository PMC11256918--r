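#' Pair table of a dot-bracket string
#'
#' Matches brackets with a stack and returns, for every position, the 1-based
#' index of its pairing partner or `NA`. Unmatched brackets, dots and `?`
#' wildcards all map to `NA`; unbalanced input is legal (constraint strings may
#' contain any composition of brackets).
#'
#' @param structure A dot-bracket string over `.`, `(`, `)` and `?`.
#' @return An integer vector of partner indices (`NA` where unpaired), with the
#'   same length as `structure`.
#' @examples
#' pair_table("((....))")
#' pair_table("?)(?")
#' @export
pair_table <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c(".", "(", ")", "?"))
  if (length(bad) > 0) {
    stop("illegal structure character '", chars[bad[1]], "' at position ",
         bad[1], " (1-based)")
  }
  partner <- rep(NA_integer_, length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")" && length(stack) > 0) {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  partner
}

#' Construct a folding engine
#'
#' A folding engine wraps a secondary-structure predictor behind a uniform
#' contract: `fold_fun` maps a character vector of RNA sequences to a character
#' vector of balanced dot-bracket strings of identical lengths.
#'
#' @param name Engine identifier recorded in result metadata.
#' @param mode One of `"MFE"`, `"MEA"` or `"custom"`.
#' @param fold_fun Vectorised function `character -> character`.
#' @return An object of class `folding_engine`.
#' @seealso [nussinov_engine()], [viennarna_engine()], [fold()]
#' @export
folding_engine <- function(name, mode = c("MFE", "MEA", "custom"), fold_fun) {
  mode <- match.arg(mode)
  stopifnot(is.function(fold_fun))
  structure(list(name = name, mode = mode, fold_fun = fold_fun),
            class = "folding_engine")
}

#' @export
print.folding_engine <- function(x, ...) {
  cat("<folding_engine ", x$name, " (", x$mode, ")>\n", sep = "")
  invisible(x)
}

#' Fold sequences with an engine
#'
#' @param engine A [folding_engine()].
#' @param sequences Character vector of RNA sequences over A, C, G, U.
#' @return Character vector of dot-bracket structures.
#' @export
fold <- function(engine, sequences) {
  stopifnot(inherits(engine, "folding_engine"))
  if (length(sequences) == 0) return(character(0))
  check_rna_alphabet(sequences)
  out <- engine$fold_fun(sequences)
  if (any(nchar(out) != nchar(sequences))) {
    stop("engine '", engine$name, "' returned structures of wrong length")
  }
  out
}

check_rna_alphabet <- function(sequences) {
  bad <- grepl("[^ACGU]", sequences)
  if (any(bad)) {
    chars <- strsplit(sequences[which(bad)[1]], "", fixed = TRUE)[[1]]
    pos <- which(!chars %in% c("A", "C", "G", "U"))[1]
    stop("illegal nucleotide '", chars[pos], "' at position ", pos,
         " (1-based); sequences must be over A, C, G, U")
  }
  invisible(TRUE)
}

#' Nussinov maximum base-pairing fold
#'
#' Deterministic dynamic-programming folder maximising the number of
#' Watson-Crick and GU wobble pairs subject to a minimum hairpin loop size.
#' Ties are broken by preferring an unpaired 3' position, then the earliest
#' pairing partner, so the output is a pure function of the input. Bundled so
#' the whole toolkit runs without an external folding package.
#'
#' @param sequence RNA sequence over A, C, G, U.
#' @param min_hairpin Minimum number of unpaired positions enclosed by a pair
#'   (steric minimum, default 3).
#' @return A dot-bracket string of the same length.
#' @examples
#' nussinov_fold("GGGAAAACCC")
#' @export
nussinov_fold <- function(sequence, min_hairpin = 3) {
  stopifnot(length(sequence) == 1, nchar(sequence) >= 1, min_hairpin >= 0)
  check_rna_alphabet(sequence)
  .nussinov_fold_cpp(sequence, as.integer(min_hairpin))
}

#' Bundled Nussinov folding engine
#'
#' @param min_hairpin Minimum hairpin loop size (default 3).
#' @return A [folding_engine()] of mode `"custom"`.
#' @export
nussinov_engine <- function(min_hairpin = 3) {
  force(min_hairpin)
  folding_engine(
    name = sprintf("nussinov(min_hairpin=%d)", as.integer(min_hairpin)),
    mode = "custom",
    fold_fun = function(sequences) {
      vapply(sequences, function(s) .nussinov_fold_cpp(s, as.integer(min_hairpin)),
             character(1), USE.NAMES = FALSE)
    }
  )
}

#' ViennaRNA RNAfold engine (MFE or MEA)
#'
#' Delegates folding to the `RNAfold` executable of the ViennaRNA package,
#' batching all sequences through a single process call. `kind = "MFE"` returns
#' minimum free energy structures, `kind = "MEA"` maximum expected accuracy
#' structures (`RNAfold --MEA`).
#'
#' @param kind `"MFE"` or `"MEA"`.
#' @param rnafold Path to the RNAfold binary; discovered on `PATH` by default.
#' @return A [folding_engine()].
#' @export
viennarna_engine <- function(kind = c("MFE", "MEA"), rnafold = Sys.which("RNAfold")) {
  kind <- match.arg(kind)
  if (!nzchar(rnafold)) {
    stop("RNAfold executable not found on PATH; install the ViennaRNA package ",
         "or use the bundled nussinov_engine()")
  }
  force(rnafold)
  fold_fun <- function(sequences) rnafold_batch(rnafold, sequences, kind)
  folding_engine(name = sprintf("RNAfold-%s", kind), mode = kind,
                 fold_fun = fold_fun)
}

rnafold_batch <- function(rnafold, sequences, kind) {
  infile <- tempfile("rnafold_in_")
  on.exit(unlink(infile), add = TRUE)
  writeLines(sequences, infile)
  # run inside a scratch directory: with -p RNAfold drops dot-plot files
  workdir <- tempfile("rnafold_wd_")
  dir.create(workdir)
  oldwd <- setwd(workdir)
  on.exit({ setwd(oldwd); unlink(workdir, recursive = TRUE) }, add = TRUE)
  args <- c("--noPS", if (kind == "MEA") c("--MEA", "-p"))
  out <- suppressWarnings(
    system2(rnafold, args = args, stdin = infile, stdout = TRUE, stderr = FALSE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("RNAfold exited with status ", status)
  }
  # ps/dp file names are only emitted when PS output is on; with --noPS the
  # records are plain text blocks, one per input sequence.
  if (kind == "MFE") {
    struct_lines <- out[seq(2, length(out), by = 2)]
    structs <- sub("^([.()]+).*$", "\\1", struct_lines)
  } else {
    mea_lines <- grep(" MEA=", out, value = TRUE, fixed = TRUE)
    if (length(mea_lines) != length(sequences)) {
      stop("unexpected RNAfold --MEA output (", length(mea_lines),
           " MEA records for ", length(sequences), " sequences)")
    }
    structs <- sub("^([.()]+).*$", "\\1", mea_lines)
  }
  if (length(structs) != length(sequences) || any(!grepl("^[.()]+$", structs))) {
    stop("failed to parse RNAfold output")
  }
  structs
}

#' Convenience constructor for external engines
#'
#' @param kind `"MFE"` or `"MEA"`.
#' @return A [folding_engine()] backed by ViennaRNA's RNAfold.
#' @export
external_engine <- function(kind = c("MFE", "MEA")) {
  viennarna_engine(match.arg(kind))
}
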