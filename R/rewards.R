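#' Reward configuration
#'
#' Bundles the tunable constants of the objective functions: the reward
#' shaping exponent `alpha`, the structure/GC weights `beta` and `gamma`, the
#' desired GC content and its tolerance `gc_tolerance`, and the number of
#' label-refinement rounds used by the Weisfeiler-Lehman structure distance.
#'
#' @param alpha Exponent applied to the normalised reward (> 0, default 1).
#' @param beta Weight of the normalised structure loss (>= 0, default 1).
#' @param gamma Weight of the GC loss (>= 0, default 1).
#' @param gc_desired Target GC fraction in `[0, 1]`, or `NULL` for no GC
#'   objective.
#' @param gc_tolerance Tolerance epsilon on the GC deviation (default 0.01).
#' @param wl_iterations Label-refinement rounds for [wl_distance()] (default 2).
#' @return An object of class `reward_config`.
#' @export
reward_config <- function(alpha = 1, beta = 1, gamma = 1, gc_desired = NULL,
                          gc_tolerance = 0.01, wl_iterations = 2) {
  stopifnot(alpha > 0, beta >= 0, gamma >= 0,
            gc_tolerance >= 0, gc_tolerance < 1, wl_iterations >= 0)
  if (!is.null(gc_desired)) stopifnot(gc_desired >= 0, gc_desired <= 1)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 gc_desired = gc_desired, gc_tolerance = gc_tolerance,
                 wl_iterations = as.integer(wl_iterations)),
            class = "reward_config")
}

#' Structure loss
#'
#' Number of constrained structure positions that disagree with the folded
#' structure: a Hamming distance restricted to positions where the constraint
#' is a concrete `.`, `(` or `)` symbol; `?` positions contribute 0.
#'
#' @param omega_bar Structure-constraint string over `.`, `(`, `)`, `?`.
#' @param folded Dot-bracket string of the same length.
#' @return Integer count of violated constraints.
#' @export
structure_loss <- function(omega_bar, folded) {
  if (nchar(omega_bar) != nchar(folded)) {
    stop("constraint string length ", nchar(omega_bar),
         " differs from folded structure length ", nchar(folded))
  }
  ob <- strsplit(omega_bar, "")[[1]]
  fb <- strsplit(folded, "")[[1]]
  sum(ob != "?" & ob != fb)
}

#' Structure reward
#'
#' The normalised, exponentiated structure objective
#' `(1 - loss / length)^alpha`, bounded in `[0, 1]`.
#'
#' @param loss Structure loss (see [structure_loss()]).
#' @param length Length of the structure constraints (> 0).
#' @param alpha Shaping exponent (> 0).
#' @return Reward in `[0, 1]`.
#' @export
structure_reward <- function(loss, length, alpha = 1) {
  stopifnot(length > 0, loss >= 0, loss <= length, alpha > 0)
  (1 - loss / length)^alpha
}

#' GC content of a sequence
#'
#' @param sequence RNA sequence.
#' @return Fraction of G and C among all positions.
#' @export
gc_content <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  sum(chars %in% c("G", "C")) / length(chars)
}

#' GC loss
#'
#' Absolute deviation of the sequence GC content from the desired value; zero
#' inside the tolerance band.
#'
#' @param sequence RNA sequence (non-empty).
#' @param gc_desired Target GC fraction.
#' @param epsilon Tolerance (default 0.01).
#' @return Non-negative deviation.
#' @export
gc_loss <- function(sequence, gc_desired, epsilon = 0.01) {
  stopifnot(nchar(sequence) > 0)
  dev <- abs(gc_desired - gc_content(sequence))
  if (dev <= epsilon) 0 else dev
}

#' Combined structure + GC reward
#'
#' Weighted sum of the normalised structure loss and the GC loss, clipped to
#' zero when the sum exceeds one, then exponentiated:
#' `(1 - (beta * loss/length + gamma * gc_l))^alpha`.
#'
#' @param loss Structure loss.
#' @param length Constraint length (> 0).
#' @param gc_l GC loss value.
#' @param cfg A [reward_config()].
#' @return Reward in `[0, 1]`.
#' @export
combined_reward <- function(loss, length, gc_l, cfg = reward_config()) {
  stopifnot(length > 0, loss >= 0, loss <= length, gc_l >= 0)
  s <- cfg$beta * loss / length + cfg$gamma * gc_l
  if (s > 1) 0 else (1 - s)^cfg$alpha
}

# Structure graph for the WL distance: nodes are positions labelled with their
# dot-bracket symbol, edges are backbone adjacencies plus matched base pairs.
structure_graph <- function(structure) {
  n <- nchar(structure)
  labels <- strsplit(structure, "")[[1]]
  partner <- pair_table(structure)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- integer(0)
    if (i > 1) nb <- c(nb, i - 1L)
    if (i < n) nb <- c(nb, i + 1L)
    if (!is.na(partner[i])) nb <- c(nb, partner[i])
    adj[[i]] <- nb
  }
  list(labels = labels, adj = adj)
}

#' Weisfeiler-Lehman distance between two secondary structures
#'
#' Both structures are turned into graphs (positions labelled by their
#' structure symbol; backbone plus base-pair edges). The labels are refined
#' for `iterations` rounds by hashing each node's label together with the
#' sorted multiset of its neighbours' labels. The feature vector of a graph
#' counts every label observed across all rounds; the distance is one minus
#' the cosine similarity of the two feature vectors, so it lies in `[0, 1]`,
#' is symmetric and is zero on identical structures.
#'
#' @param structure_a,structure_b Non-empty dot-bracket strings (lengths may
#'   differ).
#' @param iterations Number of refinement rounds `h` (default 2).
#' @return Distance in `[0, 1]`.
#' @export
wl_distance <- function(structure_a, structure_b, iterations = 2) {
  stopifnot(nchar(structure_a) > 0, nchar(structure_b) > 0, iterations >= 0)
  ga <- structure_graph(structure_a)
  gb <- structure_graph(structure_b)
  la <- ga$labels
  lb <- gb$labels
  feats_a <- la
  feats_b <- lb
  for (h in seq_len(iterations)) {
    refine <- function(labels, adj) {
      vapply(seq_along(labels), function(i) {
        nb <- sort(labels[adj[[i]]])
        paste0(h, ":", labels[i], "|", paste(nb, collapse = ","))
      }, character(1))
    }
    la <- refine(la, ga$adj)
    lb <- refine(lb, gb$adj)
    feats_a <- c(feats_a, la)
    feats_b <- c(feats_b, lb)
  }
  dict <- union(feats_a, feats_b)
  va <- tabulate(match(feats_a, dict), nbins = length(dict))
  vb <- tabulate(match(feats_b, dict), nbins = length(dict))
  sim <- sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
  max(0, min(1, 1 - sim))
}

#' Plug-in reward transforms
#'
#' Transforms a raw external score into a reward: `bitscore` passes the raw
#' covariance-model bitscore through, substituting -200 when the scorer
#' reports no match; `rri_energy` returns the cubed negated interaction energy
#' `(-energy)^3`, so lower (more favourable) energies yield larger rewards.
#'
#' @param raw Raw score (bitscore or interaction energy in kcal/mol).
#' @param kind `"bitscore"` or `"rri_energy"`.
#' @param no_match For `bitscore`: did the scorer report no match? Defaults to
#'   `TRUE` when `raw` is `NA`.
#' @return Numeric reward.
#' @export
plugin_reward_transform <- function(raw, kind = c("bitscore", "rri_energy"),
                                    no_match = is.na(raw)) {
  kind <- match.arg(kind)
  if (kind == "bitscore") {
    if (isTRUE(no_match)) -200.0 else as.numeric(raw)
  } else {
    (-as.numeric(raw))^3
  }
}

#' Construct an objective
#'
#' An objective names a reward function `R_T(candidate, task)` together with a
#' predicate deciding whether a candidate counts as solved.
#'
#' @param name Identifier.
#' @param reward_fun Function `(candidate, task) -> numeric`; candidates carry
#'   their folded structure.
#' @param solved_fun Function `(candidate, task) -> logical`; defaults to
#'   reward equal to 1.
#' @return An object of class `rna_objective`.
#' @export
objective <- function(name, reward_fun, solved_fun = NULL) {
  stopifnot(is.function(reward_fun))
  if (is.null(solved_fun)) {
    solved_fun <- function(candidate, task) {
      isTRUE(all.equal(reward_fun(candidate, task), 1))
    }
  }
  structure(list(name = name, reward_fun = reward_fun, solved_fun = solved_fun),
            class = "rna_objective")
}

#' Built-in objectives
#'
#' `structure_objective()` rewards satisfaction of the structure constraints;
#' when `cfg$gc_desired` is set it automatically becomes the combined
#' structure + GC objective. `plugin_objective()` wraps an external scorer
#' (e.g. a covariance-model bitscore or an interaction-energy predictor)
#' behind the objective contract via [plugin_reward_transform()].
#'
#' @param cfg A [reward_config()].
#' @return An `rna_objective`.
#' @export
structure_objective <- function(cfg = reward_config()) {
  reward_fun <- function(candidate, task) {
    loss <- structure_loss(task$structure_constraints, candidate$folded_structure)
    if (is.null(cfg$gc_desired)) {
      structure_reward(loss, task$length, cfg$alpha)
    } else {
      gl <- gc_loss(candidate$sequence, cfg$gc_desired, cfg$gc_tolerance)
      combined_reward(loss, task$length, gl, cfg)
    }
  }
  solved_fun <- function(candidate, task) {
    loss <- structure_loss(task$structure_constraints, candidate$folded_structure)
    ok <- loss == 0
    if (!is.null(cfg$gc_desired)) {
      ok <- ok && gc_loss(candidate$sequence, cfg$gc_desired, cfg$gc_tolerance) == 0
    }
    ok
  }
  name <- if (is.null(cfg$gc_desired)) "structure" else "structure+gc"
  objective(name, reward_fun, solved_fun)
}

#' @param name Plug-in identifier used in reports.
#' @param scorer Function `character -> numeric` scoring one sequence; return
#'   `NA` to signal no match.
#' @param kind Transform kind, see [plugin_reward_transform()].
#' @param solved_threshold Reward at or above which a candidate counts as
#'   solved (default `Inf`: plug-in objectives are open-ended).
#' @rdname structure_objective
#' @export
plugin_objective <- function(name, scorer, kind = c("bitscore", "rri_energy"),
                             solved_threshold = Inf) {
  kind <- match.arg(kind)
  stopifnot(is.function(scorer))
  reward_fun <- function(candidate, task) {
    plugin_reward_transform(scorer(candidate$sequence), kind)
  }
  solved_fun <- function(candidate, task) {
    reward_fun(candidate, task) >= solved_threshold
  }
  objective(paste0("plugin:", name), reward_fun, solved_fun)
}

unconstrained_positions <- function(task) {
  which(strsplit(task$sequence_constraints, "")[[1]] == "?")
}

constrained_struct_positions <- function(task) {
  which(strsplit(task$structure_constraints, "")[[1]] != "?")
}

mutate_at <- function(sequence, positions, nucleotides) {
  chars <- strsplit(sequence, "")[[1]]
  chars[positions] <- nucleotides
  paste(chars, collapse = "")
}

#' Local improvement step (LIS)
#'
#' When a candidate is close to satisfying the structure constraints (at most
#' `max_mismatches` violated positions), all nucleotide assignments over the
#' unconstrained sequence positions within `radius` of a mismatch are tried
#' exhaustively (capped at `max_eval` assignments, folded in one batch) and
#' the assignment with minimal [structure_loss()] is returned, ties resolved
#' by enumeration order. Constrained sequence positions are never altered.
#'
#' @param candidate An [candidate()] satisfying the task's sequence channel.
#' @param task An [task()].
#' @param engine A [folding_engine()].
#' @param max_mismatches Gate: more mismatches than this returns the input
#'   unchanged (default 5).
#' @param radius Neighbourhood half-width around each mismatch (default 1).
#' @param max_eval Enumeration budget on assignments (default 256).
#' @return A possibly improved `rna_candidate` with its folded structure.
#' @export
local_improvement <- function(candidate, task, engine, max_mismatches = 5,
                              radius = 1, max_eval = 256) {
  stopifnot(inherits(candidate, "rna_candidate"), inherits(task, "rna_task"))
  if (is.null(candidate$folded_structure)) {
    candidate$folded_structure <- fold(engine, candidate$sequence)
  }
  ob <- strsplit(task$structure_constraints, "")[[1]]
  fb <- strsplit(candidate$folded_structure, "")[[1]]
  mismatches <- which(ob != "?" & ob != fb)
  if (length(mismatches) == 0 || length(mismatches) > max_mismatches) {
    return(candidate)
  }
  free <- unconstrained_positions(task)
  nbh <- unique(unlist(lapply(mismatches, function(m) (m - radius):(m + radius))))
  sites <- intersect(free, nbh)
  if (length(sites) == 0) return(candidate)
  k_max <- max(1L, floor(log(max_eval) / log(4)))
  if (length(sites) > k_max) sites <- sites[seq_len(k_max)]
  grid <- expand.grid(rep(list(c("A", "C", "G", "U")), length(sites)),
                      stringsAsFactors = FALSE)
  variants <- apply(as.matrix(grid), 1L, function(nt) {
    mutate_at(candidate$sequence, sites, nt)
  })
  folded <- fold(engine, variants)
  losses <- vapply(folded, function(f) structure_loss(task$structure_constraints, f),
                   numeric(1), USE.NAMES = FALSE)
  best <- which.min(losses)
  candidate(variants[best], folded_structure = folded[best],
            scores = candidate$scores)
}

#' GC improvement step (GIS)
#'
#' Greedily mutates unconstrained sequence positions toward the desired GC
#' content (A/U to G or C to raise it, G/C to A or U to lower it), each step
#' taking the mutation with the smallest structure-loss increase, until the GC
#' deviation is within tolerance or no mutation reduces it. Constrained
#' positions are never altered.
#'
#' @param candidate An [candidate()].
#' @param task An [task()].
#' @param cfg A [reward_config()] with `gc_desired` set.
#' @param engine A [folding_engine()].
#' @return A possibly improved `rna_candidate`.
#' @export
gc_improvement <- function(candidate, task, cfg, engine) {
  stopifnot(inherits(candidate, "rna_candidate"), inherits(task, "rna_task"),
            !is.null(cfg$gc_desired))
  cand <- candidate
  free <- unconstrained_positions(task)
  if (length(free) == 0) return(cand)
  if (is.null(cand$folded_structure)) {
    cand$folded_structure <- fold(engine, cand$sequence)
  }
  n <- task$length
  for (iter in seq_len(n)) {
    gc <- gc_content(cand$sequence)
    dev <- abs(cfg$gc_desired - gc)
    if (dev <= cfg$gc_tolerance) break
    raise <- gc < cfg$gc_desired
    chars <- strsplit(cand$sequence, "")[[1]]
    from <- if (raise) c("A", "U") else c("G", "C")
    to <- if (raise) c("G", "C") else c("A", "U")
    sites <- free[chars[free] %in% from]
    if (length(sites) == 0) break
    # one swap moves GC by 1/n; stop when that no longer reduces the deviation
    new_dev <- abs(cfg$gc_desired - (gc + (if (raise) 1 else -1) / n))
    if (new_dev >= dev) break
    moves <- expand.grid(site = sites, nt = to, stringsAsFactors = FALSE)
    variants <- vapply(seq_len(nrow(moves)), function(i) {
      mutate_at(cand$sequence, moves$site[i], moves$nt[i])
    }, character(1))
    folded <- fold(engine, variants)
    losses <- vapply(folded, function(f) structure_loss(task$structure_constraints, f),
                     numeric(1), USE.NAMES = FALSE)
    best <- which.min(losses)
    cand <- candidate(variants[best], folded_structure = folded[best],
                      scores = cand$scores)
  }
  cand
}
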