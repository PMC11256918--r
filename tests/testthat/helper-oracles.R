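# Independent oracles used across the suite. These deliberately avoid the
# package's own implementation paths.

oracle_can_pair <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

# Exhaustive maximum base-pairing count over all nested structures
# (plain recursion, pair-first decomposition; no memoisation).
oracle_max_pairs <- function(chars, min_hairpin = 3) {
  go <- function(i, j) {
    if (j - i < min_hairpin + 1) return(0L)
    best <- go(i + 1L, j)  # i unpaired
    for (k in (i + min_hairpin + 1L):j) {
      if (oracle_can_pair(chars[i], chars[k])) {
        best <- max(best, 1L + go(i + 1L, k - 1L) + go(k + 1L, j))
      }
    }
    best
  }
  if (length(chars) < min_hairpin + 2) return(0L)
  go(1L, length(chars))
}

count_pairs <- function(db) sum(strsplit(db, "")[[1]] == "(")

# All fixed-length instantiations of a design space with <= 2 variable
# regions, as "<seq>/<struct>" strings.
oracle_enumerate_instantiations <- function(seq_line, struct_line, lo, hi) {
  split_keep <- function(x) {
    out <- strsplit(paste0(x, "#"), "?*", fixed = TRUE)[[1]]
    out[length(out)] <- sub("#$", "", out[length(out)])
    out
  }
  seq_segs <- split_keep(seq_line)
  struct_segs <- split_keep(struct_line)
  n_var <- length(seq_segs) - 1L
  stopifnot(n_var >= 1, n_var <= 2)
  fixed <- sum(nchar(seq_segs))
  out <- character(0)
  for (L in lo:hi) {
    surplus <- L - fixed
    if (surplus < 0) next
    comps <- if (n_var == 1) matrix(surplus, ncol = 1) else
      cbind(0:surplus, surplus:0)
    for (r in seq_len(nrow(comps))) {
      sq <- seq_segs[1]; stx <- struct_segs[1]
      for (v in seq_len(n_var)) {
        sq <- paste0(sq, strrep("?", comps[r, v]), seq_segs[v + 1L])
        stx <- paste0(stx, strrep("?", comps[r, v]), struct_segs[v + 1L])
      }
      out <- c(out, paste0(sq, "/", stx))
    }
  }
  unique(out)
}

# Position-wise constraint check written independently of the package.
oracle_matches_constraints <- function(value, constraints) {
  v <- strsplit(value, "")[[1]]
  k <- strsplit(constraints, "")[[1]]
  all(k == "?" | v == k)
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
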