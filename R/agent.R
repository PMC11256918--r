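#' Policy configuration
#'
#' The policy maps an observation window of symbol indices to a probability
#' vector over the four nucleotide actions: an embedding of the 21 task
#' symbols, one or more dense ReLU layers, and a softmax output, trained by
#' policy gradient with an entropy bonus using Adam. `conv_layers` and
#' `lstm_layers` are part of the configuration surface of the wider
#' architecture space; this release implements the dense policy only and
#' rejects other settings with a configuration error.
#'
#' @param embedding_size Embedding dimension per symbol (default 8).
#' @param dense_units Integer vector of hidden layer widths (default 32).
#' @param learning_rate Adam step size (default 0.01).
#' @param batch_size Episodes per policy update (default 8).
#' @param entropy_weight Weight of the entropy bonus (default 1e-3).
#' @param grad_clip Global gradient-norm clip (default 5).
#' @param conv_layers Unsupported; must be `NULL`.
#' @param lstm_layers Unsupported; must be 0.
#' @return An object of class `policy_config`.
#' @export
policy_config <- function(embedding_size = 8, dense_units = 32,
                          learning_rate = 0.01, batch_size = 8,
                          entropy_weight = 1e-3, grad_clip = 5,
                          conv_layers = NULL, lstm_layers = 0) {
  if (!is.null(conv_layers) || lstm_layers != 0) {
    stop("configuration error: convolutional and LSTM policy layers are not ",
         "implemented in this release; use dense_units")
  }
  stopifnot(embedding_size >= 1, length(dense_units) >= 1, all(dense_units >= 1),
            learning_rate > 0, batch_size >= 1, entropy_weight >= 0)
  structure(list(embedding_size = as.integer(embedding_size),
                 dense_units = as.integer(dense_units),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 entropy_weight = entropy_weight,
                 grad_clip = grad_clip),
            class = "policy_config")
}

#' Build a policy network
#'
#' Initial parameters are drawn from the current R random number generator
#' (seed with `set.seed()` for reproducibility) and kept alongside the live
#' parameters so a restart can restore the exact initial values.
#'
#' @param cfg A [policy_config()].
#' @param kappa State radius of the environment the policy will observe.
#' @return An object of class `rna_policy`.
#' @export
build_policy <- function(cfg = policy_config(), kappa = 16) {
  width <- 2L * as.integer(kappa) + 1L
  dims <- c(width * cfg$embedding_size, cfg$dense_units, 4L)
  params <- list(E = matrix(stats::rnorm(N_SYMBOLS * cfg$embedding_size, sd = 0.1),
                            nrow = N_SYMBOLS))
  for (l in seq_len(length(dims) - 1L)) {
    params[[paste0("W", l)]] <- matrix(
      stats::rnorm(dims[l] * dims[l + 1L], sd = sqrt(2 / dims[l])),
      nrow = dims[l])
    params[[paste0("b", l)]] <- rep(0, dims[l + 1L])
  }
  pol <- list(cfg = cfg, kappa = as.integer(kappa), n_layers = length(dims) - 1L,
              params = params, init_params = params,
              adam = list(m = lapply(params, function(p) p * 0),
                          v = lapply(params, function(p) p * 0), t = 0L),
              baseline = NULL)
  class(pol) <- "rna_policy"
  pol
}

#' @export
print.rna_policy <- function(x, ...) {
  cat("<rna_policy kappa=", x$kappa, ", embedding=", x$cfg$embedding_size,
      ", dense=[", paste(x$cfg$dense_units, collapse = ","), "]>\n", sep = "")
  invisible(x)
}

policy_forward <- function(policy, windows) {
  if (is.null(dim(windows))) windows <- matrix(windows, nrow = 1)
  p <- policy$params
  idx <- windows + 1L
  X <- do.call(cbind, lapply(seq_len(ncol(windows)),
                             function(j) p$E[idx[, j], , drop = FALSE]))
  acts <- list(X)
  H <- X
  for (l in seq_len(policy$n_layers)) {
    Z <- sweep(H %*% p[[paste0("W", l)]], 2, p[[paste0("b", l)]], "+")
    H <- if (l < policy$n_layers) pmax(Z, 0) else Z
    acts[[l + 1L]] <- H
  }
  Z <- acts[[policy$n_layers + 1L]]
  Z <- sweep(Z, 1, apply(Z, 1, max), "-")
  P <- exp(Z)
  P <- P / rowSums(P)
  list(probs = P, acts = acts, windows = windows)
}

#' Action probabilities of a policy
#'
#' @param policy An [build_policy()] result.
#' @param windows Integer vector (one window) or matrix (one window per row)
#'   of symbol indices in 0..20.
#' @return Matrix of action probabilities, rows summing to one.
#' @export
policy_probs <- function(policy, windows) {
  policy_forward(policy, windows)$probs
}

policy_act <- function(policy, window) {
  p <- policy_forward(policy, window)$probs[1, ]
  sample.int(4L, 1L, prob = p) - 1L
}

# One Adam policy-gradient update from a batch of episodes
# (list of list(windows, actions, reward)). Returns the updated policy.
policy_update <- function(policy, episodes) {
  episodes <- Filter(function(e) nrow(e$windows) > 0, episodes)
  if (length(episodes) == 0) return(policy)
  rewards <- vapply(episodes, `[[`, numeric(1), "reward")
  if (is.null(policy$baseline)) policy$baseline <- mean(rewards)
  adv <- rewards - policy$baseline
  policy$baseline <- 0.9 * policy$baseline + 0.1 * mean(rewards)

  windows <- do.call(rbind, lapply(episodes, `[[`, "windows"))
  actions <- unlist(lapply(episodes, `[[`, "actions"))
  step_adv <- rep(adv, vapply(episodes, function(e) nrow(e$windows), integer(1)))
  fw <- policy_forward(policy, windows)
  P <- fw$probs
  n <- nrow(P)
  one_hot <- matrix(0, n, 4L)
  one_hot[cbind(seq_len(n), actions + 1L)] <- 1
  logP <- log(pmax(P, 1e-12))
  H <- -rowSums(P * logP)
  # d/dlogits of [-adv * log pi(a)] and of [-entropy_weight * H]
  dZ <- (step_adv * (P - one_hot) +
           policy$cfg$entropy_weight * P * (logP + H)) / n

  p <- policy$params
  grads <- list()
  dH <- dZ
  for (l in rev(seq_len(policy$n_layers))) {
    Hin <- fw$acts[[l]]
    grads[[paste0("W", l)]] <- t(Hin) %*% dH
    grads[[paste0("b", l)]] <- colSums(dH)
    if (l > 1) {
      dH <- (dH %*% t(p[[paste0("W", l)]])) * (Hin > 0)
    } else {
      dX <- dH %*% t(p$W1)
    }
  }
  d <- policy$cfg$embedding_size
  gE <- matrix(0, N_SYMBOLS, d)
  idx <- fw$windows + 1L
  for (j in seq_len(ncol(idx))) {
    block <- dX[, ((j - 1L) * d + 1L):(j * d), drop = FALSE]
    for (s in unique(idx[, j])) {
      rows <- idx[, j] == s
      gE[s, ] <- gE[s, ] + colSums(block[rows, , drop = FALSE])
    }
  }
  grads$E <- gE

  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(policy$cfg$grad_clip) && gnorm > policy$cfg$grad_clip) {
    grads <- lapply(grads, function(g) g * policy$cfg$grad_clip / gnorm)
  }

  a <- policy$adam
  a$t <- a$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- policy$cfg$learning_rate
  for (nm in names(policy$params)) {
    g <- grads[[nm]]
    a$m[[nm]] <- b1 * a$m[[nm]] + (1 - b1) * g
    a$v[[nm]] <- b2 * a$v[[nm]] + (1 - b2) * g^2
    mhat <- a$m[[nm]] / (1 - b1^a$t)
    vhat <- a$v[[nm]] / (1 - b2^a$t)
    policy$params[[nm]] <- policy$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  policy$adam <- a
  policy
}

#' Restore a policy's initial parameters
#'
#' Resets the live parameters to the values drawn at [build_policy()] time and
#' clears the optimiser state, as done by the periodic restart of the design
#' loop.
#'
#' @param policy An `rna_policy`.
#' @return The restarted policy.
#' @export
policy_restart <- function(policy) {
  policy$params <- policy$init_params
  policy$adam <- list(m = lapply(policy$params, function(p) p * 0),
                      v = lapply(policy$params, function(p) p * 0), t = 0L)
  policy$baseline <- NULL
  policy
}

#' Training configuration
#'
#' @param episodes Number of training episodes (> 0).
#' @param seed Optional integer seed set at the start of training.
#' @param restart_interval Seconds between parameter restarts (default `Inf`
#'   during training; the design loop defaults to 1800 s).
#' @param dataset_choice Optional identifier of the training corpus, recorded
#'   in the log.
#' @return An object of class `training_config`.
#' @export
training_config <- function(episodes, seed = NULL, restart_interval = Inf,
                            dataset_choice = NULL) {
  stopifnot(episodes > 0, restart_interval > 0)
  structure(list(episodes = as.integer(episodes), seed = seed,
                 restart_interval = restart_interval,
                 dataset_choice = dataset_choice),
            class = "training_config")
}

as_task_source <- function(task_source) {
  if (inherits(task_source, "rna_design_space")) {
    function() sample_task(task_source)
  } else if (inherits(task_source, "rna_task")) {
    function() task_source
  } else if (is.list(task_source)) {
    stopifnot(all(vapply(task_source, inherits, logical(1), "rna_task")))
    function() task_source[[sample.int(length(task_source), 1L)]]
  } else if (is.function(task_source)) {
    task_source
  } else {
    stop("task_source must be a design space, a task, a list of tasks or a function")
  }
}

#' Train a policy by policy gradient
#'
#' Runs episodes on tasks drawn from `task_source`, updating the policy on
#' terminal rewards in minibatches. Fully reproducible from the seed.
#'
#' @param policy An `rna_policy`.
#' @param task_source A design space, task, list of tasks, or a function
#'   returning a task.
#' @param env_cfg An [env_config()].
#' @param train_cfg A [training_config()].
#' @return List with the trained `policy` and a `log` data frame (one row per
#'   episode: episode index, task id, reward, structure loss).
#' @export
train <- function(policy, task_source, env_cfg, train_cfg) {
  stopifnot(inherits(policy, "rna_policy"), inherits(env_cfg, "env_config"),
            inherits(train_cfg, "training_config"))
  if (!is.null(train_cfg$seed)) set.seed(train_cfg$seed)
  source_fn <- as_task_source(task_source)
  n <- train_cfg$episodes
  log <- data.frame(episode = seq_len(n), task = character(n),
                    reward = NA_real_, loss = NA_real_,
                    stringsAsFactors = FALSE)
  batch <- list()
  started <- Sys.time()
  for (i in seq_len(n)) {
    tk <- source_fn()
    if (tk$length == 0) {
      warning("skipping zero-length task at episode ", i)
      next
    }
    ep <- run_episode(tk, env_cfg, function(w) policy_act(policy, w))
    log$task[i] <- tk$sequence_constraints
    log$reward[i] <- ep$reward
    log$loss[i] <- structure_loss(tk$structure_constraints,
                                  ep$candidate$folded_structure)
    batch[[length(batch) + 1L]] <- ep
    if (length(batch) >= policy$cfg$batch_size) {
      policy <- policy_update(policy, batch)
      batch <- list()
    }
    if (is.finite(train_cfg$restart_interval) &&
        as.numeric(Sys.time() - started, units = "secs") >= train_cfg$restart_interval) {
      policy <- policy_restart(policy)
      started <- Sys.time()
    }
  }
  if (length(batch) > 0) policy <- policy_update(policy, batch)
  list(policy = policy, log = log)
}

#' Design a library of candidates from a design space
#'
#' Repeatedly samples a fixed-length task from the design space, fills its
#' unconstrained positions with one policy rollout, optionally applies the
#' local improvement step (and the GC improvement step whenever a desired GC
#' content is configured), and emits the candidate with its scores and a
#' solved flag. With `adapt = TRUE` the policy is updated between episodes on
#' the episode rewards; every `restart_interval` seconds the parameters are
#' reset to their initial values.
#'
#' @param policy An `rna_policy` (or `NULL` for uniform random actions).
#' @param space An `rna_design_space`.
#' @param objective An [objective()]; also used for the solved flag.
#' @param n_candidates Exact number of candidates to emit (or `NULL` when
#'   `timeout` is given).
#' @param timeout Wall-clock budget in seconds, checked between episodes.
#' @param env_cfg An [env_config()]; its objective is replaced by `objective`.
#' @param adapt Update the policy between episodes (default `TRUE`).
#' @param restart_interval Seconds between parameter restarts (default 1800).
#' @param local_improve Apply [local_improvement()] (and [gc_improvement()]
#'   when a GC target is configured) to each candidate (default `TRUE`).
#' @param max_mismatches Gate for the local improvement step (default 5).
#' @param seed Optional seed set before the loop.
#' @return Data frame with one row per candidate: `id`, `length`, `sequence`,
#'   `structure`, `gc`, `reward`, `solved`, plus the instantiated task
#'   constraints `task_sequence`, `task_structure`.
#' @export
design <- function(policy, space, objective, n_candidates = NULL,
                   timeout = NULL, env_cfg = env_config(), adapt = TRUE,
                   restart_interval = 1800, local_improve = TRUE,
                   max_mismatches = 5, seed = NULL) {
  stopifnot(inherits(space, "rna_design_space"), inherits(objective, "rna_objective"))
  if (is.null(n_candidates) && is.null(timeout)) {
    stop("give a candidate budget (n_candidates) or a wall-clock budget (timeout)")
  }
  if (!is.null(seed)) set.seed(seed)
  cfg <- env_cfg
  cfg$objective <- objective
  use_policy <- !is.null(policy)
  act <- if (use_policy) function(w) policy_act(policy, w) else
    function(w) sample.int(4L, 1L) - 1L
  gc_cfg <- cfg$reward_cfg
  rows <- list()
  batch <- list()
  started <- Sys.time()
  restart_clock <- started
  i <- 0L
  repeat {
    if (!is.null(n_candidates) && i >= n_candidates) break
    if (!is.null(timeout) &&
        as.numeric(Sys.time() - started, units = "secs") >= timeout) break
    i <- i + 1L
    tk <- sample_task(space)
    ep <- run_episode(tk, cfg, act)
    cand <- ep$candidate
    if (local_improve) {
      cand <- local_improvement(cand, tk, cfg$engine,
                                max_mismatches = max_mismatches)
      if (!is.null(gc_cfg$gc_desired)) {
        cand <- gc_improvement(cand, tk, gc_cfg, cfg$engine)
      }
    }
    reward <- objective$reward_fun(cand, tk)
    solved <- objective$solved_fun(cand, tk)
    rows[[i]] <- data.frame(
      id = sprintf("cand_%06d", i), length = tk$length,
      sequence = cand$sequence, structure = cand$folded_structure,
      gc = gc_content(cand$sequence), reward = reward, solved = solved,
      task_sequence = tk$sequence_constraints,
      task_structure = tk$structure_constraints,
      stringsAsFactors = FALSE)
    if (use_policy && adapt) {
      batch[[length(batch) + 1L]] <- ep
      if (length(batch) >= policy$cfg$batch_size) {
        policy <- policy_update(policy, batch)
        batch <- list()
      }
      if (is.finite(restart_interval) &&
          as.numeric(Sys.time() - restart_clock, units = "secs") >= restart_interval) {
        policy <- policy_restart(policy)
        restart_clock <- Sys.time()
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "objective") <- objective$name
  attr(out, "engine") <- cfg$engine$name
  out
}

#' Uniform random designer
#'
#' Same candidate stream contract as [design()] but actions are uniform over
#' the four nucleotides, with no policy updates, restarts or refinement.
#'
#' @inheritParams design
#' @return Data frame as in [design()].
#' @export
random_agent <- function(space, objective, n_candidates = NULL, timeout = NULL,
                         env_cfg = env_config(), seed = NULL) {
  design(policy = NULL, space = space, objective = objective,
         n_candidates = n_candidates, timeout = timeout, env_cfg = env_cfg,
         adapt = FALSE, local_improve = FALSE, seed = seed)
}

#' Save and load policy checkpoints
#'
#' Checkpoints are versioned, self-describing JSON files holding the live and
#' initial parameters, the optimiser state and the full configuration.
#'
#' @param policy An `rna_policy`.
#' @param path File path.
#' @return `load_policy` returns the restored `rna_policy`.
#' @export
save_policy <- function(policy, path) {
  ser <- list(
    format = "rnamotiflib-policy",
    version = 1L,
    kappa = policy$kappa,
    n_layers = policy$n_layers,
    cfg = unclass(policy$cfg),
    params = lapply(policy$params, function(p)
      list(dim = dim(p) %||% length(p), data = as.numeric(p))),
    init_params = lapply(policy$init_params, function(p)
      list(dim = dim(p) %||% length(p), data = as.numeric(p))),
    baseline = policy$baseline,
    adam_t = policy$adam$t
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_policy
#' @export
load_policy <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(ser$format, "rnamotiflib-policy")) {
    stop(path, " is not a policy checkpoint")
  }
  unpack <- function(ps) {
    out <- lapply(ps, function(p) {
      if (length(p$dim) == 2) matrix(p$data, nrow = p$dim[1]) else as.numeric(p$data)
    })
    names(out) <- names(ps)
    out
  }
  cfg <- do.call(policy_config, ser$cfg[c("embedding_size", "dense_units",
                                          "learning_rate", "batch_size",
                                          "entropy_weight", "grad_clip")])
  pol <- build_policy(cfg, ser$kappa)
  pol$params <- unpack(ser$params)
  pol$init_params <- unpack(ser$init_params)
  pol$adam <- list(m = lapply(pol$params, function(p) p * 0),
                   v = lapply(pol$params, function(p) p * 0),
                   t = ser$adam_t %||% 0L)
  pol$baseline <- if (length(ser$baseline) == 0) NULL else as.numeric(ser$baseline)
  pol
}
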