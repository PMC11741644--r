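#' Variable-structure learning automaton
#'
#' A learning automaton (LA) holds a probability vector over a finite set of
#' actions and adapts it from reward/penalty feedback supplied by an
#' environment.  `la_new()` creates an automaton with a uniform probability
#' vector; [la_select()] draws an action, and [la_reward()] / [la_penalty()]
#' apply the linear reward-penalty updates.
#'
#' The reward operator moves probability mass towards the chosen action
#' \eqn{i} with coefficient \eqn{a}:
#' \deqn{p_i \leftarrow p_i + a(1 - p_i), \qquad p_j \leftarrow (1-a)p_j \; (j \ne i)}
#' and the penalty operator moves mass away from it with coefficient
#' \eqn{b}, redistributing uniformly over the other \eqn{K-1} actions:
#' \deqn{p_i \leftarrow (1-b)p_i, \qquad p_j \leftarrow \frac{b}{K-1} + (1-b)p_j \; (j \ne i).}
#' Both maps conserve \eqn{\sum_j p_j = 1} exactly; the implementation
#' renormalises after every update to absorb floating-point drift.
#'
#' @param n_actions number of selectable actions (at least 2).
#' @param reward_coeff reward coefficient \eqn{a} in (0, 1]; default 0.5.
#' @param penalty_coeff penalty coefficient \eqn{b} in [0, 1); default 0.5.
#'   `penalty_coeff = 0` gives the linear reward-inaction scheme.
#' @param exploration_rate fraction of selections drawn uniformly at random
#'   instead of from the probability vector; default 0.3.
#'
#' @return An object of class `learning_automaton`: a list with elements
#'   `n_actions`, `probabilities`, `reward_coeff`, `penalty_coeff`,
#'   `exploration_rate`, `last_action` (NA until a selection is made) and
#'   `update_count`.
#'
#' @examples
#' la <- la_new(4)
#' set.seed(1)
#' a <- la_select(la)
#' la <- la_reward(la, a$action)
#' la$probabilities
#' @export
la_new <- function(n_actions, reward_coeff = 0.5, penalty_coeff = 0.5,
                   exploration_rate = 0.3) {
  if (length(n_actions) != 1L || !is.finite(n_actions) ||
      n_actions != round(n_actions) || n_actions < 2) {
    stop("`n_actions` must be a single integer >= 2 (degenerate action ",
         "spaces cannot learn)", call. = FALSE)
  }
  n_actions <- as.integer(n_actions)
  if (!is.numeric(reward_coeff) || length(reward_coeff) != 1L ||
      reward_coeff <= 0 || reward_coeff > 1) {
    stop("`reward_coeff` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(penalty_coeff) || length(penalty_coeff) != 1L ||
      penalty_coeff < 0 || penalty_coeff >= 1) {
    stop("`penalty_coeff` must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(exploration_rate) || length(exploration_rate) != 1L ||
      exploration_rate < 0 || exploration_rate > 1) {
    stop("`exploration_rate` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      n_actions = n_actions,
      probabilities = rep(1 / n_actions, n_actions),
      reward_coeff = reward_coeff,
      penalty_coeff = penalty_coeff,
      exploration_rate = exploration_rate,
      last_action = NA_integer_,
      update_count = 0L
    ),
    class = "learning_automaton"
  )
}

#' @export
print.learning_automaton <- function(x, ...) {
  cat("<learning_automaton> ", x$n_actions, " actions, a = ", x$reward_coeff,
      ", b = ", x$penalty_coeff, ", exploration = ", x$exploration_rate,
      "\n", sep = "")
  cat("  updates: ", x$update_count,
      "; last action: ", ifelse(is.na(x$last_action), "<none>", x$last_action),
      "; max p = ", signif(max(x$probabilities), 4),
      " (action ", which.max(x$probabilities), ")\n", sep = "")
  invisible(x)
}

check_la_action <- function(la, action) {
  if (length(action) != 1L || is.na(action) || action != round(action) ||
      action < 1 || action > la$n_actions) {
    stop("action index must be a single integer in [1, ", la$n_actions, "]",
         call. = FALSE)
  }
  as.integer(action)
}

#' Select an action from a learning automaton
#'
#' With probability `exploration_rate` the action is drawn uniformly over all
#' actions; otherwise it is drawn from the automaton's current probability
#' vector.  The draw consumes R's global random stream, so wrap calls with
#' `set.seed()` for reproducibility.
#'
#' @param la a [la_new()] automaton.
#' @return A list with `action` (the 1-based index) and `la` (the automaton
#'   with `last_action` recorded).
#' @export
la_select <- function(la) {
  stopifnot(inherits(la, "learning_automaton"))
  explore <- stats::runif(1) < la$exploration_rate
  action <- if (explore) {
    sample.int(la$n_actions, 1L)
  } else {
    sample.int(la$n_actions, 1L, prob = la$probabilities)
  }
  la$last_action <- action
  list(action = action, la = la)
}

#' Linear reward update
#'
#' Increases the probability of the chosen action by the reward coefficient
#' `a` and shrinks all others by `1 - a`; see [la_new()] for the update map.
#'
#' @param la a [la_new()] automaton.
#' @param action index of the rewarded action.
#' @return The updated automaton.
#' @export
la_reward <- function(la, action) {
  stopifnot(inherits(la, "learning_automaton"))
  i <- check_la_action(la, action)
  a <- la$reward_coeff
  p <- la$probabilities * (1 - a)
  p[i] <- la$probabilities[i] + a * (1 - la$probabilities[i])
  la$probabilities <- p / sum(p)
  la$update_count <- la$update_count + 1L
  la
}

#' Linear penalty update
#'
#' Decreases the probability of the chosen action by the penalty coefficient
#' `b`, redistributing `b / (K - 1)` to each of the other `K - 1` actions;
#' see [la_new()] for the update map.
#'
#' @inheritParams la_reward
#' @return The updated automaton.
#' @export
la_penalty <- function(la, action) {
  stopifnot(inherits(la, "learning_automaton"))
  i <- check_la_action(la, action)
  b <- la$penalty_coeff
  K <- la$n_actions
  p <- b / (K - 1) + (1 - b) * la$probabilities
  p[i] <- (1 - b) * la$probabilities[i]
  la$probabilities <- p / sum(p)
  la$update_count <- la$update_count + 1L
  la
}

#' Serialise / restore an automaton
#'
#' Round-trips the full automaton state (probabilities, coefficients, update
#' counter, last action) through a JSON document, for checkpointing and the
#' search history log.
#'
#' @param la a [la_new()] automaton.
#' @param path optional file to write to; if `NULL` the JSON string is
#'   returned.
#' @return `la_to_json()`: a JSON string (invisibly, if `path` is given);
#'   `la_from_json()`: the restored `learning_automaton`.
#' @export
la_to_json <- function(la, path = NULL) {
  stopifnot(inherits(la, "learning_automaton"))
  doc <- jsonlite::toJSON(unclass(la), auto_unbox = TRUE, digits = NA,
                          na = "null")
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}

#' @rdname la_to_json
#' @param json a JSON string or path to a JSON file produced by
#'   [la_to_json()].
#' @export
la_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  la <- la_new(x$n_actions, x$reward_coeff, x$penalty_coeff,
               x$exploration_rate)
  p <- as.numeric(x$probabilities)
  if (length(p) != la$n_actions || any(!is.finite(p)) || any(p < 0)) {
    stop("invalid probability vector in serialised automaton", call. = FALSE)
  }
  la$probabilities <- p / sum(p)
  la$last_action <- if (is.null(x$last_action)) NA_integer_ else
    as.integer(x$last_action)
  la$update_count <- as.integer(x$update_count)
  la
}
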