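#' Create the team of 21 learning automata
#'
#' One automaton per configurable layer: 19 over the convolution action
#' space (or a documented subspace of it) and 2 binary automata for the
#' encoder pooling stages.  All start uniform: 1/375 per action for a
#' full-space convolution automaton and \{1/2, 1/2\} for a pooling
#' automaton.
#'
#' @param n_conv_actions size of the convolution action space each of the
#'   19 convolution automata selects from (default 375, the full space).
#' @param reward_coeff,penalty_coeff,exploration_rate passed to [la_new()];
#'   defaults follow the study protocol (a = b = 0.5, 30% random
#'   selection).
#' @return A list of 21 `learning_automaton` objects (19 convolution + 2
#'   pooling).
#' @export
make_automata_team <- function(n_conv_actions = 375L, reward_coeff = 0.5,
                               penalty_coeff = 0.5, exploration_rate = 0.3) {
  c(
    lapply(1:19, function(i) la_new(n_conv_actions, reward_coeff,
                                    penalty_coeff, exploration_rate)),
    lapply(1:2, function(i) la_new(2L, reward_coeff, penalty_coeff,
                                   exploration_rate))
  )
}

#' Termination test for the configuration search
#'
#' The search stops when any of three conditions holds: the best quality
#' has reached the ceiling `q_max`; the quality has not improved for `K`
#' consecutive iterations (the stall count is `iteration -
#' best_iteration`); or the iteration budget `T` is exhausted.
#'
#' @param state a list (or `search_state`) with `iteration`,
#'   `best_quality` and `best_iteration`.
#' @param T maximum number of iterations.
#' @param K no-improvement threshold (consecutive iterations).
#' @param q_max quality ceiling in (0, 1]; the test is `best_quality >=
#'   q_max`.
#' @return A list with `stop` (logical) and `reason` (`"quality_ceiling"`,
#'   `"stalled"`, `"max_iterations"`, or `NA` when continuing).
#' @examples
#' # last improvement at cycle 93, K = 15: the stall rule fires at cycle 108
#' st <- list(iteration = 108, best_quality = 0.94, best_iteration = 93)
#' check_termination(st, T = 200, K = 15, q_max = 1)$reason
#' @export
check_termination <- function(state, T, K, q_max = 1) {
  stall <- state$iteration - state$best_iteration
  if (is.finite(state$best_quality) && state$best_quality >= q_max) {
    list(stop = TRUE, reason = "quality_ceiling")
  } else if (stall >= K) {
    list(stop = TRUE, reason = "stalled")
  } else if (state$iteration >= T) {
    list(stop = TRUE, reason = "max_iterations")
  } else {
    list(stop = FALSE, reason = NA_character_)
  }
}

#' Run the learning-automaton configuration search
#'
#' The outer reinforcement loop.  Each iteration every automaton selects an
#' action (uniformly at random with probability `exploration_rate`,
#' otherwise from its probability vector), the joint action is evaluated by
#' the environment, and the feedback is broadcast to the whole team: if the
#' quality strictly exceeds the best seen so far, every automaton rewards
#' its chosen action and the configuration is saved as the new best;
#' otherwise (including ties) every automaton is penalised.  The first
#' iteration always improves on the initial best of -Inf.  The loop ends at
#' the iteration budget `T`, after `K` iterations without improvement, or
#' when the quality ceiling `q_max` is reached; the best configuration ever
#' seen is returned, not the last.
#'
#' An environment error is not fatal: the iteration is scored 0, the team
#' is penalised, and the search continues.
#'
#' @param env an environment: any list with an `evaluate(actions)` function
#'   returning a quality in `[0, 1]`, e.g. [make_oracle_table()] or
#'   [make_cnn_environment()].
#' @param automata list of `learning_automaton` objects, e.g. from
#'   [make_automata_team()].
#' @param T iteration budget (default 200).
#' @param K no-improvement threshold (default 15).
#' @param q_max quality ceiling (default 1).
#' @param seed optional integer seed for the selection randomness.
#' @param log_path optional path: one JSON record per iteration is appended
#'   (JSONL) with the iteration, actions, quality, best-so-far and a digest
#'   of each automaton's state.
#' @return An object of class `search_state`: a list with `best_actions`,
#'   `best_quality`, `best_iteration`, `best_configuration` (when the
#'   environment provides an `assemble` function), `iteration`,
#'   `stall_count`, `stop_reason`, `history` (data.frame: iteration,
#'   quality, best_quality, improved) and `actions` (iterations x automata
#'   integer matrix), plus the final `automata`.
#' @export
run_search <- function(env, automata, T = 200L, K = 15L, q_max = 1,
                       seed = NULL, log_path = NULL) {
  if (T < 1L || K < 1L || K > T) {
    stop("need T >= 1 and 1 <= K <= T", call. = FALSE)
  }
  if (q_max <= 0 || q_max > 1) stop("`q_max` must lie in (0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_auto <- length(automata)
  best_quality <- -Inf
  best_iteration <- 0L
  best_actions <- NULL
  history <- vector("list", T)
  action_log <- matrix(NA_integer_, nrow = T, ncol = n_auto)
  stop_reason <- "max_iterations"
  log_con <- if (!is.null(log_path)) file(log_path, open = "a") else NULL
  on.exit(if (!is.null(log_con)) close(log_con), add = TRUE)
  iter <- 0L
  while (iter < T) {
    iter <- iter + 1L
    actions <- integer(n_auto)
    for (i in seq_len(n_auto)) {
      sel <- la_select(automata[[i]])
      actions[i] <- sel$action
      automata[[i]] <- sel$la
    }
    quality <- tryCatch(env$evaluate(actions), error = function(e) {
      warning("environment evaluation failed at iteration ", iter, ": ",
              conditionMessage(e), call. = FALSE)
      0
    })
    if (!is.finite(quality)) quality <- 0
    improved <- quality > best_quality
    if (improved) {
      best_quality <- quality
      best_iteration <- iter
      best_actions <- actions
      for (i in seq_len(n_auto)) {
        automata[[i]] <- la_reward(automata[[i]], actions[i])
      }
    } else {
      for (i in seq_len(n_auto)) {
        automata[[i]] <- la_penalty(automata[[i]], actions[i])
      }
    }
    action_log[iter, ] <- actions
    history[[iter]] <- data.frame(iteration = iter, quality = quality,
                                  best_quality = best_quality,
                                  improved = improved)
    if (!is.null(log_con)) {
      rec <- list(
        iteration = iter, actions = actions, quality = quality,
        best_quality = best_quality, improved = improved,
        automata_max_p = vapply(automata,
                                function(a) max(a$probabilities), numeric(1))
      )
      writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE,
                                               digits = NA)), log_con)
      flush(log_con)
    }
    term <- check_termination(list(iteration = iter,
                                   best_quality = best_quality,
                                   best_iteration = best_iteration),
                              T, K, q_max)
    if (term$stop) {
      stop_reason <- term$reason
      break
    }
  }
  state <- list(
    best_actions = best_actions,
    best_quality = best_quality,
    best_iteration = best_iteration,
    best_configuration = if (!is.null(env$assemble) && !is.null(best_actions))
      env$assemble(best_actions) else NULL,
    iteration = iter,
    stall_count = iter - best_iteration,
    stop_reason = stop_reason,
    history = do.call(rbind, history[seq_len(iter)]),
    actions = action_log[seq_len(iter), , drop = FALSE],
    automata = automata
  )
  class(state) <- "search_state"
  state
}

#' @export
print.search_state <- function(x, ...) {
  cat("<search_state> ", x$iteration, " iterations, stopped: ",
      x$stop_reason, "\n  best quality ", signif(x$best_quality, 5),
      " at iteration ", x$best_iteration, "\n", sep = "")
  invisible(x)
}

#' Build a CNN training environment for the search
#'
#' Wraps candidate training and evaluation as the environment of the
#' automata team: `evaluate(actions)` decodes the joint action into a
#' network configuration, builds the model, trains it on the training set,
#' segments the validation volumes and returns the mean Dice over the
#' tissue labels.  A training failure (divergent loss or any error) is
#' reported as quality 0.  The candidate training seed is fixed across the
#' whole search so that quality differences reflect configuration
#' differences rather than initialisation luck.
#'
#' @param train_data,val_data sample lists as produced by
#'   [generate_dataset()] (fields `image`, `labels`).
#' @param settings a [training_settings()] used for every candidate.
#' @param labels tissue labels entering the quality average (default 1:3 =
#'   CSF, GM, WM).
#' @param n_classes number of classes including background.
#' @param spatial_rank 2 or 3 (default: inferred from the data).
#' @param action_subset optional integer vector of convolution action
#'   indices (into the full 375-action space): the 19 convolution automata
#'   then select positions in this subspace.  `NULL` means the full space.
#' @param model_seed weight-initialisation seed shared by all candidates.
#' @param val_shape optional spatial extent: validation volumes are
#'   centre-cropped to this extent before segmentation (keeps desk-scale
#'   evaluation cheap); `NULL` uses the full volumes.
#' @return An environment list with `evaluate`, `assemble` and
#'   `n_conv_actions`, usable with [run_search()].
#' @export
make_cnn_environment <- function(train_data, val_data,
                                 settings = training_settings(),
                                 labels = 1:3, n_classes = 4L,
                                 spatial_rank = NULL, action_subset = NULL,
                                 model_seed = 1L, val_shape = NULL) {
  if (length(train_data) == 0L || length(val_data) == 0L) {
    stop("training and validation datasets must be non-empty", call. = FALSE)
  }
  n_modalities <- dim(train_data[[1L]]$image)[1L]
  if (is.null(spatial_rank)) {
    spatial_rank <- length(dim(train_data[[1L]]$image)) - 1L
  }
  if (!is.null(action_subset)) action_subset <- as.integer(action_subset)
  crop <- function(sample) {
    if (is.null(val_shape)) return(sample)
    d <- dim(sample$labels$labels)
    start <- pmax((d - val_shape) %/% 2L, 0L) + 1L
    ix <- lapply(seq_along(d), function(a) start[a] + seq_len(val_shape[a]) - 1L)
    if (spatial_rank == 3L) {
      list(image = sample$image[, ix[[1L]], ix[[2L]], ix[[3L]], drop = FALSE],
           labels = label_volume(sample$labels$labels[ix[[1L]], ix[[2L]], ix[[3L]]],
                                 spacing = sample$labels$spacing))
    } else {
      list(image = sample$image[, ix[[1L]], ix[[2L]], drop = FALSE],
           labels = label_volume(sample$labels$labels[ix[[1L]], ix[[2L]]],
                                 spacing = sample$labels$spacing))
    }
  }
  val_cropped <- lapply(val_data, crop)
  assemble <- function(actions) {
    stopifnot(length(actions) == 21L)
    conv_idx <- if (is.null(action_subset)) actions[1:19] else
      action_subset[actions[1:19]]
    assemble_configuration(conv_idx, actions[20:21] - 1L)
  }
  evaluate <- function(actions) {
    config <- assemble(actions)
    model <- build_model(config, n_modalities = n_modalities,
                         n_classes = n_classes, spatial_rank = spatial_rank,
                         seed = model_seed)
    fit <- train_candidate(model, train_data, settings)
    if (fit$failed) return(0)
    qs <- vapply(val_cropped, function(s) {
      pred <- predict_segmentation(fit$model, s$image,
                                   spacing = s$labels$spacing)
      mean_quality(pred, s$labels, labels)
    }, numeric(1))
    mean(qs)
  }
  list(evaluate = evaluate, assemble = assemble,
       n_conv_actions = if (is.null(action_subset)) 375L else
         length(action_subset),
       spatial_rank = spatial_rank)
}

#' Read a JSONL search log
#'
#' Parses the per-iteration records written by [run_search()]'s
#' `log_path`.  Truncated trailing lines (e.g. after a crash) are dropped
#' with a warning, so a log is always resumable.
#'
#' @param path the JSONL file.
#' @return A list of records (one per complete line).
#' @export
read_search_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- vector("list", length(lines))
  ok <- logical(length(lines))
  for (i in seq_along(lines)) {
    parsed <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    if (!is.null(parsed)) {
      recs[[i]] <- parsed
      ok[i] <- TRUE
    }
  }
  if (any(!ok)) {
    warning(sum(!ok), " malformed log line(s) dropped", call. = FALSE)
  }
  recs[ok]
}
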