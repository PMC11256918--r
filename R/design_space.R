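SEQ_TOKENS <- c("A", "C", "G", "U", "?", "?*")
STRUCT_TOKENS <- c(".", "(", ")", "?", "?*")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tokenise a constraint line: every character is a token except that "?*" is a
# single two-character token. `*` anywhere else is an error. Returns tokens
# plus the 1-based character offset of each token (for error messages).
tokenize_constraints <- function(line, alphabet, channel) {
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  tokens <- character(0)
  offsets <- integer(0)
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "?" && i < length(chars) && chars[i + 1L] == "*") {
      tokens <- c(tokens, "?*")
      offsets <- c(offsets, i)
      i <- i + 2L
    } else {
      if (chars[i] == "*") {
        stop(channel, " constraints: '*' at position ", i,
             " (1-based) is only legal immediately after '?'")
      }
      if (!chars[i] %in% alphabet) {
        stop(channel, " constraints: illegal character '", chars[i],
             "' at position ", i, " (1-based)")
      }
      tokens <- c(tokens, chars[i])
      offsets <- c(offsets, i)
      i <- i + 1L
    }
  }
  list(tokens = tokens, offsets = offsets)
}

#' Create a motif
#'
#' A motif pairs a sequence-constraint fragment with a structure-constraint
#' fragment. `?` marks a single unconstrained position, `?*` an unconstrained
#' region of arbitrary length; a `?*` region must be unconstrained in both
#' channels, so a `?*` motif is exactly the pair `("?*", "?*")`.
#'
#' @param sequence_part Token string over `A`, `C`, `G`, `U`, `?`, `?*`.
#' @param structure_part Token string over `.`, `(`, `)`, `?`, `?*`.
#' @return An object of class `rna_motif`.
#' @export
motif <- function(sequence_part, structure_part) {
  st <- tokenize_constraints(sequence_part, c("A", "C", "G", "U", "?"), "sequence")
  tt <- tokenize_constraints(structure_part, c(".", "(", ")", "?"), "structure")
  is_var_s <- st$tokens == "?*"
  is_var_t <- tt$tokens == "?*"
  if (any(is_var_s) || any(is_var_t)) {
    if (!(identical(st$tokens, "?*") && identical(tt$tokens, "?*"))) {
      stop("a variable-length region must be unconstrained in both channels: ",
           "a '?*' motif is exactly (\"?*\", \"?*\")")
    }
  } else if (length(st$tokens) != length(tt$tokens)) {
    stop("fixed-length motif: sequence part has ", length(st$tokens),
         " tokens but structure part has ", length(tt$tokens))
  }
  structure(list(sequence_part = sequence_part,
                 structure_part = structure_part,
                 variable = any(is_var_s),
                 fixed_length = if (any(is_var_s)) 0L else length(st$tokens)),
            class = "rna_motif")
}

#' @export
print.rna_motif <- function(x, ...) {
  cat("<motif ", x$sequence_part, " / ", x$structure_part, ">\n", sep = "")
  invisible(x)
}

#' Parse a design space from two constraint lines
#'
#' The two lines are aligned position by position. Maximal runs between `?*`
#' wildcards become fixed-length motifs; every `?*` becomes a variable-length
#' motif `("?*", "?*")`. Length bounds are required exactly when a `?*` occurs;
#' the stored lower bound is clamped to the total fixed token count.
#'
#' @param sequence_line Sequence constraints over `A`, `C`, `G`, `U`, `?`, `?*`.
#' @param structure_line Structure constraints over `.`, `(`, `)`, `?`, `?*`.
#' @param min_len,max_len Inclusive bounds on the total candidate length;
#'   required iff the lines contain `?*`.
#' @return An object of class `rna_design_space`.
#' @examples
#' parse_design_space("????????", "((....))")
#' parse_design_space("?*?GNRA??*", "?*(....)?*", min_len = 6, max_len = 60)
#' @export
parse_design_space <- function(sequence_line, structure_line,
                               min_len = NULL, max_len = NULL) {
  if (!nzchar(sequence_line) || !nzchar(structure_line)) {
    stop("constraint lines must be non-empty")
  }
  st <- tokenize_constraints(sequence_line, SEQ_TOKENS, "sequence")
  tt <- tokenize_constraints(structure_line, STRUCT_TOKENS, "structure")

  split_at_var <- function(tk) {
    idx <- which(tk$tokens == "?*")
    segs <- list()
    start <- 1L
    for (i in c(idx, length(tk$tokens) + 1L)) {
      segs[[length(segs) + 1L]] <- tk$tokens[seq_len(i - start) + start - 1L]
      start <- i + 1L
    }
    segs
  }
  seq_segs <- split_at_var(st)
  struct_segs <- split_at_var(tt)
  if (length(seq_segs) != length(struct_segs)) {
    stop("sequence line has ", length(seq_segs) - 1L,
         " '?*' regions but structure line has ", length(struct_segs) - 1L,
         "; a variable-length region must be unconstrained in both channels")
  }
  seg_len_s <- lengths(seq_segs)
  seg_len_t <- lengths(struct_segs)
  if (any(seg_len_s != seg_len_t)) {
    k <- which(seg_len_s != seg_len_t)[1]
    stop("fixed-length region ", k, " has ", seg_len_s[k],
         " sequence tokens but ", seg_len_t[k], " structure tokens")
  }

  motifs <- list()
  for (k in seq_along(seq_segs)) {
    if (seg_len_s[k] > 0) {
      motifs[[length(motifs) + 1L]] <-
        motif(paste(seq_segs[[k]], collapse = ""),
              paste(struct_segs[[k]], collapse = ""))
    }
    if (k < length(seq_segs)) {
      motifs[[length(motifs) + 1L]] <- motif("?*", "?*")
    }
  }
  if (length(motifs) == 0) motifs <- list(motif("?*", "?*"))

  n_fixed <- sum(seg_len_s)
  has_var <- any(st$tokens == "?*")
  if (has_var) {
    if (is.null(min_len) || is.null(max_len)) {
      stop("the design space contains '?*' regions: min_len and max_len ",
           "are required, otherwise the space is unbounded")
    }
  } else {
    min_len <- min_len %||% n_fixed
    max_len <- max_len %||% n_fixed
    if (min_len != n_fixed || max_len != n_fixed) {
      stop("no '?*' region: length bounds must equal the fixed length ", n_fixed)
    }
  }
  if (min_len > max_len) stop("min_len (", min_len, ") exceeds max_len (", max_len, ")")
  if (max_len < n_fixed) {
    stop("max_len (", max_len, ") is below the fixed token count (", n_fixed, ")")
  }
  structure(list(motifs = motifs,
                 min_total_length = as.integer(max(min_len, n_fixed)),
                 max_total_length = as.integer(max_len),
                 n_fixed = as.integer(n_fixed)),
            class = "rna_design_space")
}

#' Render a design space back to its two constraint lines
#'
#' @param x An `rna_design_space`.
#' @param ... Unused.
#' @return Named character vector with elements `sequence` and `structure`.
#' @method format rna_design_space
#' @export
format.rna_design_space <- function(x, ...) {
  c(sequence = paste(vapply(x$motifs, `[[`, "", "sequence_part"), collapse = ""),
    structure = paste(vapply(x$motifs, `[[`, "", "structure_part"), collapse = ""))
}

#' @export
print.rna_design_space <- function(x, ...) {
  lines <- format(x)
  b <- length_bounds(x)
  cat("<rna_design_space: ", length(x$motifs), " motifs, length ",
      b[1], "-", b[2], ">\n", sep = "")
  cat("  sequence:  ", lines[["sequence"]], "\n", sep = "")
  cat("  structure: ", lines[["structure"]], "\n", sep = "")
  invisible(x)
}

#' Feasible total-length interval of a design space
#'
#' @param space An `rna_design_space`.
#' @return Integer vector `c(lower, upper)`; the lower bound is clamped to the
#'   fixed token count.
#' @export
length_bounds <- function(space) {
  stopifnot(inherits(space, "rna_design_space"))
  c(max(space$min_total_length, space$n_fixed), space$max_total_length)
}

#' Create a fixed-length task
#'
#' A task is a fixed-length instantiation of a design space: per-position
#' sequence and structure constraints with no variable-length wildcard left.
#'
#' @param sequence_constraints String over `A`, `C`, `G`, `U`, `?`.
#' @param structure_constraints String over `.`, `(`, `)`, `?`; same length.
#' @return An object of class `rna_task`.
#' @export
task <- function(sequence_constraints, structure_constraints) {
  tokenize_constraints(sequence_constraints, c("A", "C", "G", "U", "?"), "sequence")
  tokenize_constraints(structure_constraints, c(".", "(", ")", "?"), "structure")
  if (nchar(sequence_constraints) != nchar(structure_constraints)) {
    stop("task constraint strings differ in length (",
         nchar(sequence_constraints), " vs ", nchar(structure_constraints), ")")
  }
  structure(list(sequence_constraints = sequence_constraints,
                 structure_constraints = structure_constraints,
                 length = nchar(sequence_constraints)),
            class = "rna_task")
}

#' @export
print.rna_task <- function(x, ...) {
  cat("<rna_task length ", x$length, ">\n  ", x$sequence_constraints, "\n  ",
      x$structure_constraints, "\n", sep = "")
  invisible(x)
}

# Uniform draw over weak compositions of `n` into `k` parts (stars and bars).
sample_composition <- function(n, k) {
  if (k == 1) return(n)
  if (n == 0) return(rep(0L, k))
  bars <- sort(sample.int(n + k - 1L, k - 1L))
  diff(c(0L, bars, n + k)) - 1L
}

#' Sample a fixed-length task from a design space
#'
#' Every `?*` region is replaced by a (possibly empty) run of unconstrained
#' positions. When `total_length` is `NULL` it is drawn uniformly from
#' [length_bounds()]; the surplus length beyond the fixed tokens is split over
#' the `?*` regions uniformly at random over weak compositions. Uses the
#' current R random number generator, so determinism is controlled by
#' `set.seed()`.
#'
#' @param space An `rna_design_space`.
#' @param total_length Requested length, or `NULL` to draw one.
#' @return An [task()] whose constraints contain all fixed tokens in order.
#' @export
sample_task <- function(space, total_length = NULL) {
  stopifnot(inherits(space, "rna_design_space"))
  b <- length_bounds(space)
  if (is.null(total_length)) {
    total_length <- b[1] + sample.int(b[2] - b[1] + 1L, 1L) - 1L
  }
  if (total_length < b[1] || total_length > b[2]) {
    stop("requested length ", total_length, " outside feasible bounds [",
         b[1], ", ", b[2], "]")
  }
  var_idx <- which(vapply(space$motifs, `[[`, logical(1), "variable"))
  surplus <- total_length - space$n_fixed
  if (length(var_idx) == 0 && surplus != 0) {
    stop("no '?*' region but requested length ", total_length,
         " differs from fixed length ", space$n_fixed)
  }
  alloc <- if (length(var_idx) > 0) sample_composition(surplus, length(var_idx))
  seq_parts <- character(length(space$motifs))
  struct_parts <- character(length(space$motifs))
  j <- 0L
  for (i in seq_along(space$motifs)) {
    m <- space$motifs[[i]]
    if (m$variable) {
      j <- j + 1L
      seq_parts[i] <- strrep("?", alloc[j])
      struct_parts[i] <- strrep("?", alloc[j])
    } else {
      seq_parts[i] <- m$sequence_part
      struct_parts[i] <- m$structure_part
    }
  }
  task(paste(seq_parts, collapse = ""), paste(struct_parts, collapse = ""))
}

#' Create a candidate
#'
#' @param sequence Fully specified RNA sequence over A, C, G, U.
#' @param folded_structure Optional dot-bracket string of the same length.
#' @param scores Named list of objective scores.
#' @return An object of class `rna_candidate`.
#' @export
candidate <- function(sequence, folded_structure = NULL, scores = list()) {
  check_rna_alphabet(sequence)
  if (!is.null(folded_structure) &&
      nchar(folded_structure) != nchar(sequence)) {
    stop("folded_structure length differs from sequence length")
  }
  structure(list(sequence = sequence, folded_structure = folded_structure,
                 scores = scores),
            class = "rna_candidate")
}

#' @export
print.rna_candidate <- function(x, ...) {
  cat("<rna_candidate length ", nchar(x$sequence), ">\n  ", x$sequence, "\n",
      sep = "")
  if (!is.null(x$folded_structure)) cat("  ", x$folded_structure, "\n", sep = "")
  invisible(x)
}

#' Hard-constraint relation
#'
#' TRUE iff the candidate matches every concrete nucleotide of the task's
#' sequence constraints and (where the structure constraints have concrete
#' symbols) its folded structure matches them position by position.
#'
#' @param task An [task()].
#' @param candidate An [candidate()]; `folded_structure` is required when the
#'   task has concrete structure symbols.
#' @return Logical scalar.
#' @export
satisfies_hard_constraints <- function(task, candidate) {
  stopifnot(inherits(task, "rna_task"), inherits(candidate, "rna_candidate"))
  if (nchar(candidate$sequence) != task$length) {
    stop("candidate length ", nchar(candidate$sequence),
         " differs from task length ", task$length)
  }
  phi_bar <- strsplit(task$sequence_constraints, "")[[1]]
  seq_chars <- strsplit(candidate$sequence, "")[[1]]
  fixed <- phi_bar != "?"
  if (any(seq_chars[fixed] != phi_bar[fixed])) return(FALSE)
  omega_bar <- strsplit(task$structure_constraints, "")[[1]]
  constrained <- omega_bar != "?"
  if (!any(constrained)) return(TRUE)
  if (is.null(candidate$folded_structure)) {
    stop("candidate has no folded_structure but the task has concrete ",
         "structure constraints")
  }
  db <- strsplit(candidate$folded_structure, "")[[1]]
  all(db[constrained] == omega_bar[constrained])
}

#' Folding relation
#'
#' Folds the candidate sequence with the given engine and checks that every
#' concrete symbol of the task's structure constraints is satisfied.
#'
#' @param candidate An [candidate()].
#' @param task An [task()].
#' @param engine A [folding_engine()].
#' @return Logical scalar.
#' @export
satisfies_folding_relation <- function(candidate, task, engine) {
  stopifnot(inherits(candidate, "rna_candidate"), inherits(task, "rna_task"))
  folded <- fold(engine, candidate$sequence)
  omega_bar <- strsplit(task$structure_constraints, "")[[1]]
  db <- strsplit(folded, "")[[1]]
  constrained <- omega_bar != "?"
  all(db[constrained] == omega_bar[constrained])
}

#' Read a design space file
#'
#' The file holds two records introduced by `sequence:` and `structure:`
#' headers (in that order), the constraint string on the following line.
#' `#`-prefixed comment lines are ignored. Optional `min_length:` and
#' `max_length:` headers carry the total-length bounds required when the
#' constraints contain `?*`; bounds given as arguments take precedence.
#'
#' @param path File path.
#' @param min_len,max_len Optional total-length bounds.
#' @return An `rna_design_space`.
#' @export
read_design_space <- function(path, min_len = NULL, max_len = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  take <- function(header) {
    i <- which(startsWith(lines, header))
    if (length(i) == 0) return(NULL)
    rest <- trimws(sub(header, "", lines[i[1]], fixed = TRUE))
    if (nzchar(rest)) rest else trimws(lines[i[1] + 1L])
  }
  seq_line <- take("sequence:")
  struct_line <- take("structure:")
  if (is.null(seq_line) || is.null(struct_line)) {
    stop("design space file needs 'sequence:' and 'structure:' records")
  }
  fmin <- take("min_length:")
  fmax <- take("max_length:")
  parse_design_space(seq_line, struct_line,
                     min_len = min_len %||% if (!is.null(fmin)) as.integer(fmin),
                     max_len = max_len %||% if (!is.null(fmax)) as.integer(fmax))
}

#' Write a design space file
#'
#' @param space An `rna_design_space`.
#' @param path Output path.
#' @export
write_design_space <- function(space, path) {
  lines <- format(space)
  b <- length_bounds(space)
  out <- c("# rnamotiflib design space",
           paste0("sequence: ", lines[["sequence"]]),
           paste0("structure: ", lines[["structure"]]))
  if (any(vapply(space$motifs, `[[`, logical(1), "variable"))) {
    out <- c(out, paste0("min_length: ", b[1]), paste0("max_length: ", b[2]))
  }
  writeLines(out, path)
  invisible(path)
}

#' Write candidates as FASTA plus an optional TSV sidecar
#'
#' @param candidates A data frame with at least `id` and `sequence` columns;
#'   columns `structure`, `length`, `gc`, reward/score columns are carried into
#'   the sidecar when present.
#' @param fasta Output FASTA path.
#' @param tsv Optional sidecar path (tab-separated).
#' @export
write_candidates <- function(candidates, fasta, tsv = NULL) {
  stopifnot(is.data.frame(candidates), all(c("id", "sequence") %in% names(candidates)))
  set <- Biostrings::RNAStringSet(stats::setNames(candidates$sequence,
                                                  candidates$id))
  Biostrings::writeXStringSet(set, fasta)
  if (!is.null(tsv)) {
    utils::write.table(candidates, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(fasta)
}

#' Read sequences from a FASTA file
#'
#' Reads RNA (or DNA; T is converted to U) sequences for batch folding.
#'
#' @param path FASTA path.
#' @return Named character vector of RNA sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- chartr("Tt", "Uu", toupper(as.character(set)))
  stats::setNames(unname(seqs), names(set))
}
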