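.trial_columns <- c("subject", "day", "trial", "chrono", "type",
                    "x1", "p1", "x2", "p2", "side_of_L1", "rotation_deg",
                    "choice", "chose_risky_or_dominant", "outcome_tokens",
                    "end_tokens", "reward_volume")

#' Write / read a trial table as CSV
#'
#' The on-disk schema has one row per trial with columns `subject`, `day`,
#' `trial`, `chrono`, `type`, `x1`, `p1`, `x2`, `p2`, `side_of_L1`,
#' `rotation_deg`, `choice`, `chose_risky_or_dominant`, `outcome_tokens`,
#' `end_tokens`, `reward_volume` (header required, decimal point, UTF-8).
#' Reading validates the schema: probabilities must lie on the design grid,
#' amounts must be non-zero integers in \[-3, 3\], and the token-gauge
#' invariants must hold; violations name the offending field and rows.
#'
#' @param trials A trial table (see [simulate_agent()]).
#' @param path CSV file path.
#' @return `read_trials` returns the validated trial table.
#' @export
write_trials <- function(trials, path) {
  miss <- setdiff(.trial_columns, names(trials))
  if (length(miss)) {
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(trials[, .trial_columns], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, fileEncoding = "UTF-8")
  miss <- setdiff(.trial_columns, names(tr))
  if (length(miss)) {
    stop("trial file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tr$chose_risky_or_dominant <- as.logical(tr$chose_risky_or_dominant)
  .fail_rows <- function(bad, what) {
    if (any(bad)) {
      stop(sprintf("%s in row(s): %s", what,
                   paste(utils::head(which(bad), 10L), collapse = ", ")),
           call. = FALSE)
    }
  }
  on_grid <- function(p) {
    vapply(p, function(v) any(abs(v - prob_grid) < 1e-9), logical(1))
  }
  .fail_rows(!on_grid(tr$p1), "p1 off the probability grid")
  .fail_rows(!on_grid(tr$p2), "p2 off the probability grid")
  .fail_rows(!(tr$x1 %in% amount_grid), "x1 not a non-zero integer in [-3, 3]")
  .fail_rows(!(tr$x2 %in% amount_grid), "x2 not a non-zero integer in [-3, 3]")
  .fail_rows(!(tr$type %in% 1:7), "type outside 1..7")
  .fail_rows(!(tr$choice %in% 1:2), "choice outside {1, 2}")
  .fail_rows(is.na(tr$chose_risky_or_dominant),
             "chose_risky_or_dominant not binary")
  .fail_rows(tr$end_tokens != 3L + tr$outcome_tokens |
               tr$end_tokens < 0L | tr$end_tokens > 6L,
             "end_tokens violates the token-gauge rule")
  .fail_rows(tr$reward_volume != 100 * tr$end_tokens,
             "reward_volume is not 100 units per token")
  .fail_rows(diff(c(-Inf, tr$chrono)) <= 0, "chrono not strictly increasing")
  tr
}

#' Analysis run configuration
#'
#' Bundles the settings of the end-to-end analysis with the study's stated
#' defaults: 20 chronological chunks, significance threshold 0.01,
#' Bonferroni multiplicity 3, distorted-probability indifference points.
#'
#' @param n_chunks Number of chronological chunks.
#' @param threshold Significance threshold.
#' @param bonferroni_m Bonferroni multiplicity for the parameter contrasts.
#' @param probabilities Indifference-point probability mode.
#' @param seed Integer seed for the simulation entry point.
#' @param n_days,trials_per_day_mean,trials_per_day_sd Schedule settings
#'   (see [build_schedule()]).
#' @param agent An [agent_spec()] for the simulation entry point.
#' @param fit A [fit_options()] list.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(n_chunks = 20L, threshold = 0.01, bonferroni_m = 3L,
                       probabilities = c("distorted", "raw"), seed = 1L,
                       n_days = 151L, trials_per_day_mean = 195.07,
                       trials_per_day_sd = 102.42,
                       agent = agent_spec(seed = seed),
                       fit = fit_options(
                         probabilities = match.arg(probabilities))) {
  probabilities <- match.arg(probabilities)
  structure(list(n_chunks = as.integer(n_chunks), threshold = threshold,
                 bonferroni_m = as.integer(bonferroni_m),
                 probabilities = probabilities, seed = as.integer(seed),
                 n_days = as.integer(n_days),
                 trials_per_day_mean = trials_per_day_mean,
                 trials_per_day_sd = trials_per_day_sd,
                 agent = agent, fit = fit),
            class = "run_config")
}

#' Load a run configuration from a flat YAML file
#'
#' Recognised top-level keys mirror the [run_config()] arguments; model
#' parameters and dominance accuracies for the synthetic agent sit under
#' `agent:` as flat key-value maps. Unknown keys are an error.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's value (CLI flags beat
#'   the config file).
#' @return A [run_config()] list.
#' @export
load_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  known <- c("n_chunks", "threshold", "bonferroni_m", "probabilities",
             "seed", "n_days", "trials_per_day_mean", "trials_per_day_sd",
             "agent")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(seed)) raw$seed <- as.integer(seed)
  agent <- NULL
  if (!is.null(raw$agent)) {
    a <- raw$agent
    par_keys <- c("omega_G", "omega_L", "alpha_G", "alpha_L",
                  "lambda_G", "lambda_L")
    params <- if (all(par_keys %in% names(a))) {
      do.call(model_params, a[par_keys])
    } else {
      agent_spec()$params
    }
    acc <- if (!is.null(a$dominance_accuracy)) {
      unlist(a$dominance_accuracy)
    } else {
      agent_spec()$dominance_accuracy
    }
    agent <- agent_spec(params = params, dominance_accuracy = acc,
                        subject = if (!is.null(a$subject)) a$subject
                                  else "synthetic",
                        seed = if (!is.null(raw$seed)) raw$seed else 1L)
  }
  args <- raw[setdiff(names(raw), "agent")]
  if (!is.null(agent)) args$agent <- agent
  do.call(run_config, args)
}

#' Simulate a synthetic subject and write its trial table
#'
#' Builds the schedule and agent described by the configuration, simulates
#' the choices, and writes the trial CSV. Fully deterministic given the
#' configuration seed.
#'
#' @param config A [run_config()].
#' @param out Output CSV path.
#' @param quiet Suppress the log line.
#' @return The trial table, invisibly.
#' @export
run_simulation <- function(config = run_config(), out = NULL,
                           quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  sched <- build_schedule(n_days = config$n_days,
                          trials_per_day_mean = config$trials_per_day_mean,
                          trials_per_day_sd = config$trials_per_day_sd,
                          seed = config$seed)
  trials <- simulate_agent(config$agent, sched,
                           probabilities = config$probabilities)
  if (!is.null(out)) write_trials(trials, out)
  if (!quiet) {
    message(sprintf("simulated %d trials over %d days (seed %d)%s",
                    nrow(trials), config$n_days, config$seed,
                    if (is.null(out)) "" else paste0(" -> ", out)))
  }
  invisible(trials)
}

#' Run the full behavioural analysis on a trial table
#'
#' Reproduces the analysis pipeline in order: certainty-risk contrast (on
#' the two certainty pairs, when present), dominance performance (types
#' 1-5), expected-value-difference sigmoid fits per domain, chunked
#' maximum-likelihood model fit, gain-vs-loss parameter contrasts, and
#' per-parameter temporal trends. When `out` is given, per-analysis
#' delimited tables and a key-value summary report are written there.
#'
#' @param trials A trial table or a CSV path readable by [read_trials()].
#' @param config A [run_config()].
#' @param out Optional output directory for the report files.
#' @return A list of class `"risk_report"` with components
#'   `certainty_risk`, `dominance`, `sigmoid` (gain/loss), `fit`
#'   (`risk_fit_set`), `contrasts`, `trends`.
#' @export
run_analysis <- function(trials, config = run_config(), out = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(trials)) trials <- read_trials(trials)
  report <- list()

  cert_g <- trials[trials$type == 6L & trials$x1 == 2L & trials$p1 == 0.5 &
                     trials$x2 == 1L & trials$p2 == 1, , drop = FALSE]
  cert_l <- trials[trials$type == 7L & trials$x1 == -2L & trials$p1 == 0.5 &
                     trials$x2 == -1L & trials$p2 == 1, , drop = FALSE]
  report$certainty_risk <- if (nrow(cert_g) && nrow(cert_l)) {
    certainty_risk_test(cert_g, cert_l, threshold = config$threshold)
  }

  report$dominance <- if (any(trials$type %in% 1:5)) {
    dominance_performance(trials)
  }

  ds <- aggregate_choices(trials)
  report$sigmoid <- list(gain = NULL, loss = NULL)
  for (dom in c("gain", "loss")) {
    sub <- ds[ds$type == if (dom == "gain") 6L else 7L, , drop = FALSE]
    if (nrow(sub) >= 4L) {
      delta <- sub$p1 * sub$x1 - sub$p2 * sub$x2
      report$sigmoid[[dom]] <- fit_risk_sigmoid(delta, sub$k / sub$n,
                                                n = sub$n,
                                                threshold = config$threshold)
    }
  }

  n_risky <- sum(trials$type %in% 6:7)
  if (n_risky >= config$n_chunks) {
    report$fit <- chunked_fit(trials, n_chunks = config$n_chunks,
                              options = config$fit)
    both <- !anyNA(report$fit$per_chunk[, c("omega_G", "omega_L")])
    report$contrasts <- if (both) {
      compare_gain_loss_params(report$fit, m = config$bonferroni_m,
                               threshold = config$threshold)
    } else {
      warning("a domain is unidentified; gain-vs-loss contrasts skipped",
              call. = FALSE)
      NULL
    }
    report$trends <- lapply(
      stats::setNames(nm = colnames(report$fit$per_chunk)[2:7]),
      function(p) {
        v <- report$fit$per_chunk[[p]]
        if (anyNA(v)) NULL else parameter_trend(v)
      })
  } else {
    warning("too few risky trials for the model fit; stage skipped",
            call. = FALSE)
  }

  class(report) <- "risk_report"
  if (!is.null(out)) .write_report(report, out)
  report
}

.write_report <- function(report, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  lines <- c("analysis: risky-choice gain/loss asymmetry")
  if (!is.null(report$certainty_risk)) {
    ct <- report$certainty_risk
    utils::write.csv(as.data.frame(ct$table),
                     file.path(out, "certainty_risk_counts.csv"))
    lines <- c(lines,
               sprintf("certainty_risk.chi_square: %.4f", ct$statistic),
               sprintf("certainty_risk.p_value: %.6g", ct$p_value),
               sprintf("certainty_risk.freq_gain: %.4f", ct$freq[["gain"]]),
               sprintf("certainty_risk.freq_loss: %.4f", ct$freq[["loss"]]))
  }
  if (!is.null(report$dominance)) {
    utils::write.csv(report$dominance$per_pair,
                     file.path(out, "dominance_per_pair.csv"),
                     row.names = FALSE)
    utils::write.csv(report$dominance$per_type,
                     file.path(out, "dominance_per_type.csv"),
                     row.names = FALSE)
    med <- report$dominance$per_type
    lines <- c(lines, sprintf("dominance.type%d.median: %.4f",
                              med$type, med$median))
  }
  for (dom in c("gain", "loss")) {
    sf <- report$sigmoid[[dom]]
    if (!is.null(sf)) {
      lines <- c(lines,
                 sprintf("sigmoid.%s.beta: %.4f", dom, sf$beta),
                 sprintf("sigmoid.%s.beta_ci: [%.4f, %.4f]", dom,
                         sf$ci_beta[1], sf$ci_beta[2]),
                 sprintf("sigmoid.%s.gamma: %.4f", dom, sf$gamma))
    }
  }
  if (!is.null(report$fit)) {
    utils::write.csv(report$fit$per_chunk,
                     file.path(out, "fit_per_chunk.csv"), row.names = FALSE)
    lines <- c(lines,
               sprintf("fit.mean.%s: %.4f", names(report$fit$mean),
                       report$fit$mean),
               sprintf("fit.sd.%s: %.4f", names(report$fit$sd),
                       report$fit$sd))
  }
  if (!is.null(report$contrasts)) {
    utils::write.csv(as.data.frame(report$contrasts),
                     file.path(out, "gain_loss_contrasts.csv"),
                     row.names = FALSE)
    cc <- report$contrasts
    lines <- c(lines, sprintf("contrast.%s.p_adjusted: %.6g",
                              cc$family, cc$p_adjusted))
  }
  if (!is.null(report$trends)) {
    ok <- !vapply(report$trends, is.null, logical(1))
    if (any(ok)) {
      tr <- do.call(rbind, lapply(names(report$trends)[ok], function(p) {
        t <- report$trends[[p]]
        data.frame(parameter = p, slope = t$slope,
                   F_statistic = t$F_statistic, p_value = t$p_value)
      }))
      utils::write.csv(tr, file.path(out, "parameter_trends.csv"),
                       row.names = FALSE)
    }
  }
  writeLines(lines, file.path(out, "summary.txt"))
  invisible(out)
}

#' @export
print.risk_report <- function(x, ...) {
  cat("Risky-choice analysis report\n\n")
  if (!is.null(x$certainty_risk)) { print(x$certainty_risk); cat("\n") }
  if (!is.null(x$dominance)) { print(x$dominance); cat("\n") }
  for (dom in c("gain", "loss")) {
    if (!is.null(x$sigmoid[[dom]])) {
      cat("[", dom, " domain] ", sep = "")
      print(x$sigmoid[[dom]])
    }
  }
  if (!is.null(x$fit)) { cat("\n"); print(x$fit) }
  if (!is.null(x$contrasts)) { cat("\n"); print(x$contrasts) }
  invisible(x)
}
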