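#' Specification of a synthetic choice agent
#'
#' A synthetic subject whose risky-pair (types 6/7) choices follow the
#' decision model with the given parameters and whose dominance-pair
#' (types 1-5) choices pick the dominant member with a per-type Bernoulli
#' accuracy. The default parameters are the Monkey-H published means
#' (`omega_G = 0.28`, `omega_L = -0.71`, `alpha_G = 0.63`,
#' `alpha_L = 0.21`, `lambda_G = 2.52`, `lambda_L = 1.82`); the default
#' accuracies mimic the reported per-type performance pattern, with the
#' lowest accuracy for loss-magnitude discrimination (type 3).
#'
#' @param params A [model_params()] object.
#' @param dominance_accuracy Named numeric vector, probabilities in
#'   \[0.5, 1\] of choosing the dominant member for types 1-5.
#' @param subject Subject identifier recorded in the trial table.
#' @param seed Integer seed; choices are reproducible given the seed.
#' @return A list of class `"agent_spec"`.
#' @export
agent_spec <- function(params = model_params(omega_G = 0.28,
                                             omega_L = -0.71,
                                             alpha_G = 0.63,
                                             alpha_L = 0.21,
                                             lambda_G = 2.52,
                                             lambda_L = 1.82),
                       dominance_accuracy = c(`1` = 0.97, `2` = 0.90,
                                              `3` = 0.62, `4` = 0.92,
                                              `5` = 0.85),
                       subject = "synthetic",
                       seed = 1L) {
  stopifnot(inherits(params, "model_params"))
  if (!all(as.character(1:5) %in% names(dominance_accuracy))) {
    stop("'dominance_accuracy' needs entries named 1..5", call. = FALSE)
  }
  acc <- dominance_accuracy[as.character(1:5)]
  if (any(acc < 0.5) || any(acc > 1)) {
    stop("dominance accuracies must lie in [0.5, 1]", call. = FALSE)
  }
  structure(list(params = params, dominance_accuracy = acc,
                 subject = subject, seed = as.integer(seed)),
            class = "agent_spec")
}

#' @export
print.agent_spec <- function(x, ...) {
  cat("Synthetic choice agent '", x$subject, "' (seed ", x$seed, ")\n",
      sep = "")
  print(x$params)
  cat("Dominance accuracies (types 1-5):\n")
  print(x$dominance_accuracy)
  invisible(x)
}

#' Build a multi-day trial schedule
#'
#' Draws per-day trial counts from a truncated normal (floored at one
#' trial) and, within each day, samples lottery pairs from the design
#' (uniformly by default), a uniform left/right placement of the first
#' canonical member, and a uniform stimulus rotation angle. Defaults
#' follow the published session structure: 151 days at 195.07 +/- 102.42
#' trials per day.
#'
#' @param n_days Number of sessions.
#' @param trials_per_day_mean,trials_per_day_sd Normal parameters for
#'   per-day trial counts (floored at 1).
#' @param design A [design_table()] (or compatible pair data frame).
#' @param weights Optional per-pair sampling weights (length `nrow(design)`).
#' @param seed Integer seed; the schedule is reproducible given the seed.
#' @return A data frame with columns `day`, `trial`, `chrono`, `type`,
#'   `x1`, `p1`, `x2`, `p2`, `side_of_L1`, `rotation_deg`.
#' @export
build_schedule <- function(n_days = 151L,
                           trials_per_day_mean = 195.07,
                           trials_per_day_sd = 102.42,
                           design = design_table(),
                           weights = NULL,
                           seed = 1L) {
  if (n_days < 1L) stop("'n_days' must be positive", call. = FALSE)
  if (nrow(design) == 0L) stop("empty design", call. = FALSE)
  if (!is.null(weights) && length(weights) != nrow(design)) {
    stop("'weights' must match the design rows", call. = FALSE)
  }
  set.seed(seed)
  counts <- pmax(1L, round(stats::rnorm(n_days, trials_per_day_mean,
                                        trials_per_day_sd)))
  total <- sum(counts)
  rows <- sample.int(nrow(design), total, replace = TRUE, prob = weights)
  out <- data.frame(day = rep(seq_len(n_days), times = counts),
                    trial = unlist(lapply(counts, seq_len),
                                   use.names = FALSE),
                    chrono = seq_len(total),
                    type = design$type[rows],
                    x1 = design$x1[rows], p1 = design$p1[rows],
                    x2 = design$x2[rows], p2 = design$p2[rows],
                    side_of_L1 = sample(c("left", "right"), total,
                                        replace = TRUE),
                    rotation_deg = sample(0:359, total, replace = TRUE))
  rownames(out) <- NULL
  out
}

#' Realize a lottery outcome and the token-gauge reward
#'
#' The outcome is `x_tokens` with probability `p` and 0 otherwise. The
#' subject starts every trial with 3 tokens, so the end-of-trial gauge is
#' `3 + outcome` (always in \[0, 6\]) and the water reward is 100 units
#' per token remaining (so in \[0, 600\]).
#'
#' @param L A [lottery()].
#' @param u A uniform draw in \[0, 1) (defaults to `runif(1)`); the
#'   outcome is `x` when `u < p`.
#' @return A list: `outcome_tokens`, `end_tokens`, `reward_volume`.
#' @examples
#' realize_outcome(lottery(3, 1))  # 6 tokens, 600 units
#' @export
realize_outcome <- function(L, u = stats::runif(1)) {
  stopifnot(inherits(L, "lottery"))
  out <- if (u < L$p) L$x else 0L
  end <- 3L + out
  list(outcome_tokens = out, end_tokens = end,
       reward_volume = 100 * end)
}

#' Simulate a synthetic subject on a trial schedule
#'
#' For risky pairs (types 6/7) the probability of choosing the riskier
#' member is the model's [choice_prob_risky()]; for dominance pairs
#' (types 1-5) the dominant member is chosen with the agent's per-type
#' accuracy. The chosen lottery's outcome is then realized and the
#' token-gauge bookkeeping filled in.
#'
#' @param agent An [agent_spec()].
#' @param schedule A schedule from [build_schedule()].
#' @param probabilities Indifference-point mode, see
#'   [indifference_omega()].
#' @return A trial table: the schedule columns plus `subject`, `choice`
#'   (1 = first canonical member, 2 = second), `chose_risky_or_dominant`,
#'   `outcome_tokens`, `end_tokens`, `reward_volume`.
#' @export
simulate_agent <- function(agent, schedule,
                           probabilities = c("distorted", "raw")) {
  stopifnot(inherits(agent, "agent_spec"))
  probabilities <- match.arg(probabilities)
  n <- nrow(schedule)
  set.seed(agent$seed)
  p_first <- numeric(n)
  risky <- schedule$type %in% 6:7
  if (any(risky)) {
    p_first[risky] <- .choice_prob_vec(schedule[risky, , drop = FALSE],
                                       unclass(agent$params),
                                       probabilities)
  }
  if (any(!risky)) {
    p_first[!risky] <-
      agent$dominance_accuracy[as.character(schedule$type[!risky])]
  }
  chose_first <- stats::runif(n) < p_first
  x_ch <- ifelse(chose_first, schedule$x1, schedule$x2)
  p_ch <- ifelse(chose_first, schedule$p1, schedule$p2)
  outcome <- ifelse(stats::runif(n) < p_ch, x_ch, 0L)
  out <- schedule
  out$subject <- agent$subject
  out$choice <- ifelse(chose_first, 1L, 2L)
  out$chose_risky_or_dominant <- chose_first
  out$outcome_tokens <- as.integer(outcome)
  out$end_tokens <- 3L + out$outcome_tokens
  out$reward_volume <- 100 * out$end_tokens
  stopifnot(all(out$end_tokens >= 0L), all(out$end_tokens <= 6L))
  out[, c("subject", "day", "trial", "chrono", "type", "x1", "p1",
          "x2", "p2", "side_of_L1", "rotation_deg", "choice",
          "chose_risky_or_dominant", "outcome_tokens", "end_tokens",
          "reward_volume")]
}
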