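SEQ_ORDER <- c("A", "C", "G", "U", "?")
STRUCT_ORDER <- c(".", "(", ")", "?")
PAD_INDEX <- 20L
N_SYMBOLS <- 21L
ACTION_NUCLEOTIDES <- c("A", "G", "C", "U")  # action 0..3
WC_COMPLEMENT <- c(A = "U", G = "C", C = "G", U = "A")

#' Environment configuration
#'
#' @param state_radius Half-width kappa of the observation window (>= 0).
#' @param include_actions_in_state When `TRUE` (sigma), nucleotides already
#'   placed replace their wildcard in the encoding, so later observations
#'   reflect earlier actions.
#' @param action_semantics When `TRUE`, an action at a matched opening bracket
#'   whose partner is an unconstrained sequence position also places the
#'   Watson-Crick complement at the partner site.
#' @param reward_cfg A [reward_config()].
#' @param engine A [folding_engine()] used at the terminal step.
#' @param objective An [objective()]; defaults to [structure_objective()] on
#'   `reward_cfg` (which becomes structure+GC when `gc_desired` is set).
#' @return An object of class `env_config`.
#' @export
env_config <- function(state_radius = 16, include_actions_in_state = TRUE,
                       action_semantics = TRUE, reward_cfg = reward_config(),
                       engine = nussinov_engine(), objective = NULL) {
  stopifnot(state_radius >= 0, inherits(engine, "folding_engine"))
  if (is.null(objective)) objective <- structure_objective(reward_cfg)
  structure(list(state_radius = as.integer(state_radius),
                 include_actions_in_state = isTRUE(include_actions_in_state),
                 action_semantics = isTRUE(action_semantics),
                 reward_cfg = reward_cfg, engine = engine,
                 objective = objective),
            class = "env_config")
}

symbol_index <- function(seq_chars, struct_chars) {
  si <- match(seq_chars, SEQ_ORDER) - 1L
  ti <- match(struct_chars, STRUCT_ORDER) - 1L
  4L * si + ti
}

#' Encode a task as a padded symbol-index vector
#'
#' Each position maps to `4 * s + t` where `s` indexes the sequence symbol in
#' the order A, C, G, U, `?` and `t` the structure symbol in the order `.`,
#' `(`, `)`, `?`; the pad symbol pair maps to 20. `kappa` pads are added on
#' both ends so a centred window exists at every position.
#'
#' @param task An [task()].
#' @param kappa State radius (number of pads per side).
#' @return Integer vector of length `task$length + 2 * kappa` with values in
#'   0..20.
#' @export
encode_task <- function(task, kappa) {
  stopifnot(inherits(task, "rna_task"), kappa >= 0)
  body <- symbol_index(strsplit(task$sequence_constraints, "")[[1]],
                       strsplit(task$structure_constraints, "")[[1]])
  c(rep(PAD_INDEX, kappa), body, rep(PAD_INDEX, kappa))
}

#' Observation window at an episode step
#'
#' Returns the `(2 * kappa + 1)`-gram of the encoded task centred on the
#' `t`-th unconstrained sequence position (`t` is 0-based). The encoded vector
#' is expected to already reflect any placed nucleotides when the
#' include-actions state composition is active.
#'
#' @param encoded Encoding from [encode_task()].
#' @param task The corresponding [task()].
#' @param t 0-based step index over unconstrained sequence positions.
#' @param cfg An [env_config()] (supplies `state_radius`).
#' @return Integer vector of length `2 * cfg$state_radius + 1`.
#' @export
observe <- function(encoded, task, t, cfg) {
  free <- unconstrained_positions(task)
  if (t < 0 || t >= length(free)) {
    stop("step t = ", t, " out of range: the task has ", length(free),
         " unconstrained sequence positions")
  }
  kappa <- cfg$state_radius
  centre <- free[t + 1L] + kappa
  encoded[(centre - kappa):(centre + kappa)]
}

#' Episode length of a task
#'
#' The number of agent decisions: unconstrained sequence positions minus the
#' partner positions that are auto-filled when action semantics places
#' Watson-Crick pairs at matched brackets.
#'
#' @param task An [task()].
#' @param action_semantics Logical flag.
#' @return Integer count.
#' @export
episode_length <- function(task, action_semantics = TRUE) {
  free <- unconstrained_positions(task)
  if (!action_semantics || length(free) == 0) return(length(free))
  partner <- pair_table(task$structure_constraints)
  ob <- strsplit(task$structure_constraints, "")[[1]]
  auto <- sum(vapply(free, function(i) {
    ob[i] == "(" && !is.na(partner[i]) && partner[i] %in% free
  }, logical(1)))
  length(free) - auto
}

#' Create a design episode
#'
#' Returns a mutable environment object over which [env_observe()] and
#' [env_step()] operate. Unconstrained positions are visited left to right;
#' auto-filled partner positions are removed from the visit order.
#'
#' @param task An [task()].
#' @param cfg An [env_config()].
#' @return An object of class `rna_env`.
#' @export
rna_env <- function(task, cfg = env_config()) {
  stopifnot(inherits(task, "rna_task"), inherits(cfg, "env_config"))
  e <- new.env(parent = emptyenv())
  e$task <- task
  e$cfg <- cfg
  e$partner <- pair_table(task$structure_constraints)
  e$struct_chars <- strsplit(task$structure_constraints, "")[[1]]
  e$seq_chars <- strsplit(task$sequence_constraints, "")[[1]]
  class(e) <- "rna_env"
  env_reset(e)
  e
}

#' Reset an episode to its initial state
#'
#' @param env An [rna_env()].
#' @return The environment, invisibly.
#' @export
env_reset <- function(env) {
  env$fills <- env$seq_chars
  env$pending <- unconstrained_positions(env$task)
  env$encoded <- encode_task(env$task, env$cfg$state_radius)
  env$t <- 0L
  env$terminal_length <- episode_length(env$task, env$cfg$action_semantics)
  env$done <- length(env$pending) == 0
  env$actions <- integer(0)
  env$windows <- list()
  invisible(env)
}

#' Current observation of an episode
#'
#' @param env An [rna_env()].
#' @return Integer window, or `NULL` when the episode is terminal.
#' @export
env_observe <- function(env) {
  if (env$done) return(NULL)
  kappa <- env$cfg$state_radius
  centre <- env$pending[1L] + kappa
  env$encoded[(centre - kappa):(centre + kappa)]
}

write_position <- function(env, pos, nucleotide) {
  env$fills[pos] <- nucleotide
  if (env$cfg$include_actions_in_state) {
    env$encoded[pos + env$cfg$state_radius] <-
      symbol_index(nucleotide, env$struct_chars[pos])
  }
}

#' Advance an episode by one action
#'
#' Writes the chosen nucleotide at the current unconstrained position. With
#' action semantics, a matched opening bracket whose partner is an
#' unconstrained, still-unfilled position also receives the Watson-Crick
#' complement and is skipped in the visit order. At the terminal step the full
#' sequence is folded and the configured objective's reward is returned.
#'
#' @param env An [rna_env()].
#' @param action Integer 0..3 coding A, G, C, U.
#' @return A list with elements `done`, and on the terminal step `reward` and
#'   `candidate` (an [candidate()] with folded structure and scores).
#' @export
env_step <- function(env, action) {
  if (env$done) stop("episode is terminal; call env_reset()")
  if (!action %in% 0:3) stop("action must be in 0..3 (A, G, C, U)")
  pos <- env$pending[1L]
  env$pending <- env$pending[-1L]
  nt <- ACTION_NUCLEOTIDES[action + 1L]
  env$windows[[length(env$windows) + 1L]] <- {
    kappa <- env$cfg$state_radius
    centre <- pos + kappa
    env$encoded[(centre - kappa):(centre + kappa)]
  }
  write_position(env, pos, nt)
  if (env$cfg$action_semantics && env$struct_chars[pos] == "(") {
    j <- env$partner[pos]
    if (!is.na(j) && j %in% env$pending) {
      write_position(env, j, WC_COMPLEMENT[[nt]])
      env$pending <- env$pending[env$pending != j]
    }
  }
  env$actions <- c(env$actions, as.integer(action))
  env$t <- env$t + 1L
  if (length(env$pending) > 0) {
    return(list(done = FALSE))
  }
  env$done <- TRUE
  list(done = TRUE)
}

#' Evaluate the terminal candidate of a finished episode
#'
#' @param env A terminal [rna_env()].
#' @return List with `candidate` (folded, scored) and `reward`.
#' @export
env_finalise <- function(env) {
  if (!env$done) stop("episode is not terminal yet")
  seq <- paste(env$fills, collapse = "")
  if (nchar(seq) == 0) stop("task has zero length")
  folded <- fold(env$cfg$engine, seq)
  cand <- candidate(seq, folded_structure = folded)
  reward <- env$cfg$objective$reward_fun(cand, env$task)
  cand$scores[[env$cfg$objective$name]] <- reward
  list(candidate = cand, reward = reward)
}

#' Run one episode with an action-choosing function
#'
#' @param task An [task()].
#' @param cfg An [env_config()].
#' @param act Function `window -> integer action in 0..3`.
#' @return List with `candidate`, `reward`, `windows` (matrix, one row per
#'   step) and `actions`.
#' @export
run_episode <- function(task, cfg, act) {
  env <- rna_env(task, cfg)
  while (!env$done) {
    w <- env_observe(env)
    env_step(env, act(w))
  }
  fin <- env_finalise(env)
  width <- 2L * cfg$state_radius + 1L
  windows <- if (length(env$windows) > 0) {
    do.call(rbind, env$windows)
  } else {
    matrix(integer(0), ncol = width)
  }
  list(candidate = fin$candidate, reward = fin$reward,
       windows = windows, actions = env$actions)
}
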