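#' Aggregate trial-level choices into a per-pair choice dataset
#'
#' Groups risky-pair trials (types 6 and 7) by lottery pair and counts, for
#' each pair, the number of trials `n` and the number of risky choices `k`.
#' Dominance-pair trials (types 1-5) are not part of the model likelihood
#' and are dropped; error trials must be excluded upstream.
#'
#' @param trials A trial table as produced by [simulate_agent()] or
#'   [read_trials()]: must contain columns `type`, `x1`, `p1`, `x2`, `p2`
#'   and the binary flag `chose_risky_or_dominant`.
#' @return A data frame of class `"choice_dataset"` with columns `type`,
#'   `x1`, `p1`, `x2`, `p2`, `n`, `k`, one row per distinct pair.
#' @export
aggregate_choices <- function(trials) {
  need <- c("type", "x1", "p1", "x2", "p2", "chose_risky_or_dominant")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("trials lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(is.na(trials$type) | !trials$type %in% 1:7)
  if (length(bad)) {
    stop("unclassifiable pair type in trial row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  risky <- trials[trials$type %in% 6:7, , drop = FALSE]
  if (nrow(risky) == 0L) {
    out <- data.frame(type = integer(), x1 = integer(), p1 = numeric(),
                      x2 = integer(), p2 = numeric(),
                      n = integer(), k = integer())
    class(out) <- c("choice_dataset", "data.frame")
    return(out)
  }
  key <- interaction(risky$type, risky$x1, risky$p1, risky$x2, risky$p2,
                     drop = TRUE)
  idx <- split(seq_len(nrow(risky)), key)
  rows <- lapply(idx, function(i) {
    r <- risky[i[1L], c("type", "x1", "p1", "x2", "p2")]
    r$n <- length(i)
    r$k <- sum(risky$chose_risky_or_dominant[i])
    r
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$type, out$x1, out$p1, out$x2, out$p2), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("choice_dataset", "data.frame")
  out
}

#' Construct a choice dataset directly from per-pair counts
#'
#' @param pairs A data frame with columns `type`, `x1`, `p1`, `x2`, `p2`
#'   (canonical risky pairs, types 6/7), e.g. from [enumerate_pairs()].
#' @param n,k Integer vectors: trials per pair and risky choices per pair.
#' @return A `"choice_dataset"` data frame.
#' @export
choice_dataset <- function(pairs, n, k) {
  stopifnot(nrow(pairs) == length(n), length(n) == length(k))
  if (any(k < 0) || any(k > n)) stop("need 0 <= k <= n", call. = FALSE)
  if (!all(pairs$type %in% 6:7)) {
    stop("choice datasets hold risky pairs (types 6/7) only", call. = FALSE)
  }
  out <- data.frame(type = as.integer(pairs$type),
                    x1 = as.integer(pairs$x1), p1 = pairs$p1,
                    x2 = as.integer(pairs$x2), p2 = pairs$p2,
                    n = as.integer(n), k = as.integer(k))
  if (anyDuplicated(out[, c("type", "x1", "p1", "x2", "p2")])) {
    stop("pairs must be unique within a choice dataset", call. = FALSE)
  }
  class(out) <- c("choice_dataset", "data.frame")
  out
}

#' Binomial log-likelihood of a choice dataset under the decision model
#'
#' For each pair `i` with `n_i` trials and `k_i` risky choices, the model
#' contributes the log binomial mass
#' `ln C(n_i, k_i) + k_i ln p_i + (n_i - k_i) ln (1 - p_i)` with `p_i` the
#' model's risky-choice probability. Computed in log space throughout; a
#' probability that is numerically 0 or 1 against contradicting counts
#' yields `-Inf` rather than an error. The binomial coefficient is
#' included, so values are comparable across aggregation granularities.
#'
#' @param dataset A [choice_dataset()] (types 6/7 only).
#' @param params A [model_params()] object.
#' @param probabilities Passed to the choice rule; see
#'   [indifference_omega()].
#' @return The log-likelihood (natural log), a scalar `<= 0`.
#' @export
log_likelihood <- function(dataset, params,
                           probabilities = c("distorted", "raw")) {
  stopifnot(inherits(dataset, "choice_dataset"),
            inherits(params, "model_params"))
  probabilities <- match.arg(probabilities)
  if (nrow(dataset) == 0L) return(0)
  .loglik_vec(dataset, unclass(params), probabilities)
}

## Overflow-safe log-likelihood on plain numeric theta (named vector).
.loglik_vec <- function(dataset, theta, mode) {
  gain <- dataset$type == 6L
  alpha <- ifelse(gain, theta[["alpha_G"]], theta[["alpha_L"]])
  omega <- ifelse(gain, theta[["omega_G"]], theta[["omega_L"]])
  lambda <- ifelse(gain, theta[["lambda_G"]], theta[["lambda_L"]])
  ws <- .omega_star_by_alpha(dataset, alpha, mode)
  z <- lambda * (ws - omega)
  logp <- stats::plogis(z, log.p = TRUE)
  log1mp <- stats::plogis(-z, log.p = TRUE)
  k <- dataset$k
  n <- dataset$n
  term <- lchoose(n, k) +
    ifelse(k > 0L, k * logp, 0) +
    ifelse(k < n, (n - k) * log1mp, 0)
  sum(term)
}

#' Options controlling the maximum-likelihood fit
#'
#' @param n_starts Number of deterministic multi-start points (a fixed
#'   2x2x2 factorial over the parameter box when 8, otherwise the first
#'   `n_starts` of that grid).
#' @param lambda_bounds Search box for `lambda`; the optimisation runs on
#'   `log(lambda)` for conditioning.
#' @param alpha_min Open-interval proxy for the lower `alpha` bound.
#' @param probabilities Indifference-point probability mode; see
#'   [indifference_omega()].
#' @param control Passed to [stats::optim()] (`L-BFGS-B`).
#' @return A list of class `"fit_options"`.
#' @export
fit_options <- function(n_starts = 8L,
                        lambda_bounds = c(1e-3, 1e3),
                        alpha_min = 1e-6,
                        probabilities = c("distorted", "raw"),
                        control = list(maxit = 500L)) {
  probabilities <- match.arg(probabilities)
  stopifnot(n_starts >= 1L, lambda_bounds[1] > 0,
            lambda_bounds[2] > lambda_bounds[1])
  structure(list(n_starts = as.integer(n_starts),
                 lambda_bounds = lambda_bounds,
                 alpha_min = alpha_min,
                 probabilities = probabilities,
                 control = control),
            class = "fit_options")
}

## Deterministic multi-start grid on (omega, alpha, log lambda).
.start_grid <- function(n_starts) {
  g <- expand.grid(omega = c(-0.5, 0.5),
                   alpha = c(0.3, 0.8),
                   loglam = log(c(0.5, 5)),
                   KEEP.OUT.ATTRS = FALSE)
  g[seq_len(min(n_starts, nrow(g))), , drop = FALSE]
}

## Fit one domain (gain: type 6, loss: type 7). Returns the 3 parameters,
## the maximized log-likelihood and diagnostics.
.fit_domain <- function(dataset, domain, options) {
  sub <- dataset[dataset$type == if (domain == "gain") 6L else 7L, ,
                 drop = FALSE]
  out <- list(domain = domain, n_pairs = nrow(sub),
              n_trials = sum(sub$n), estimate = c(omega = NA_real_,
                                                  alpha = NA_real_,
                                                  lambda = NA_real_),
              loglik = NA_real_, convergence = NA_integer_,
              identified = FALSE, starts = NULL)
  if (nrow(sub) == 0L) return(out)
  mode <- options$probabilities
  lb <- c(-1, options$alpha_min, log(options$lambda_bounds[1]))
  ub <- c(1, 1, log(options$lambda_bounds[2]))
  key <- if (domain == "gain") c("omega_G", "alpha_G", "lambda_G") else
    c("omega_L", "alpha_L", "lambda_L")
  negll <- function(par) {
    theta <- stats::setNames(c(par[1], par[2], exp(par[3])), key)
    ll <- .loglik_vec(sub, theta, mode)
    if (!is.finite(ll)) 1e12 else -ll
  }
  starts <- .start_grid(options$n_starts)
  runs <- lapply(seq_len(nrow(starts)), function(i) {
    p0 <- as.numeric(starts[i, ])
    tryCatch(
      stats::optim(p0, negll, method = "L-BFGS-B", lower = lb, upper = ub,
                   control = options$control),
      error = function(e) list(par = p0, value = Inf, convergence = 99L,
                               message = conditionMessage(e))
    )
  })
  vals <- vapply(runs, function(r) r$value, numeric(1))
  if (all(!is.finite(vals))) {
    stop("all optimizer starts failed for the ", domain, " domain",
         call. = FALSE)
  }
  best <- runs[[which.min(vals)]]
  out$estimate <- c(omega = best$par[1], alpha = best$par[2],
                    lambda = exp(best$par[3]))
  out$loglik <- -best$value
  out$convergence <- best$convergence
  # fewer than 2 distinct pairs cannot pin 3 parameters
  out$identified <- nrow(sub) >= 2L
  out$starts <- data.frame(start = seq_along(runs),
                           value = vals,
                           convergence = vapply(runs, function(r)
                             as.integer(r$convergence), integer(1)))
  out
}

#' Fit the decision model by binomial maximum likelihood
#'
#' Maximizes the binomial [log_likelihood()] over the parameter box
#' (`omega` in \[-1, 1\], `alpha` in (0, 1\], `lambda` in (0, Inf) searched
#' on a log scale) with bounded quasi-Newton optimisation (`L-BFGS-B`) from
#' a deterministic grid of starting points. Gain-domain (type 6) and
#' loss-domain (type 7) parameters enter disjoint likelihood terms, so the
#' joint fit separates exactly into two 3-parameter problems; a domain with
#' no pairs is reported as unidentified (`NA` estimates), and a domain with
#' a single distinct pair is fitted but flagged unidentified.
#'
#' @param dataset A [choice_dataset()], or a trial table that
#'   [aggregate_choices()] can reduce.
#' @param options A [fit_options()] list.
#' @return An object of class `"risk_fit"` with components `coefficients`
#'   (named length-6 vector, `NA` for unidentified domains), `loglik`,
#'   `domains` (per-domain diagnostics), `dataset`, and `options`. Methods:
#'   `print`, `summary`, `coef`, `logLik`, `predict`, `residuals`,
#'   `simulate`, `plot`.
#' @examples
#' pairs <- enumerate_pairs(6)[1:6, ]
#' set.seed(1)
#' ds <- choice_dataset(pairs, n = rep(50, 6), k = rbinom(6, 50, 0.4))
#' fit <- fit_mle(ds)
#' coef(fit)
#' @export
fit_mle <- function(dataset, options = fit_options()) {
  if (!inherits(dataset, "choice_dataset")) {
    dataset <- aggregate_choices(dataset)
  }
  if (nrow(dataset) == 0L) stop("empty choice dataset", call. = FALSE)
  gain <- .fit_domain(dataset, "gain", options)
  loss <- .fit_domain(dataset, "loss", options)
  cf <- c(omega_G = gain$estimate[["omega"]],
          omega_L = loss$estimate[["omega"]],
          alpha_G = gain$estimate[["alpha"]],
          alpha_L = loss$estimate[["alpha"]],
          lambda_G = gain$estimate[["lambda"]],
          lambda_L = loss$estimate[["lambda"]])
  ll <- sum(c(gain$loglik, loss$loglik), na.rm = TRUE)
  structure(list(coefficients = cf, loglik = ll,
                 domains = list(gain = gain, loss = loss),
                 dataset = dataset, options = options),
            class = "risk_fit")
}

#' @export
print.risk_fit <- function(x, ...) {
  cat("Risky-choice decision model fit (binomial ML)\n")
  cat(sprintf("  %d pairs, %d trials; log-likelihood %.3f\n",
              nrow(x$dataset), sum(x$dataset$n), x$loglik))
  print(round(x$coefficients, 4))
  for (d in x$domains) {
    if (d$n_pairs > 0L && !d$identified) {
      cat(sprintf("  note: %s domain under-identified (%d distinct pair%s)\n",
                  d$domain, d$n_pairs, if (d$n_pairs > 1L) "s" else ""))
    }
  }
  invisible(x)
}

#' @export
coef.risk_fit <- function(object, ...) object$coefficients

#' @export
logLik.risk_fit <- function(object, ...) {
  n_par <- 3L * sum(vapply(object$domains, function(d) d$n_pairs > 0L,
                           logical(1)))
  structure(object$loglik, df = n_par, nobs = sum(object$dataset$n),
            class = "logLik")
}

## Coefficients as a validated model_params object (identified fits only).
.params_of <- function(fit) {
  cf <- fit$coefficients
  if (any(is.na(cf))) {
    stop("fit has unidentified domains; no complete parameter set",
         call. = FALSE)
  }
  do.call(model_params, as.list(cf))
}

#' @export
predict.risk_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$dataset
  cf <- object$coefficients
  gain <- newdata$type == 6L
  p <- rep(NA_real_, nrow(newdata))
  ok_g <- gain & !is.na(cf[["omega_G"]])
  ok_l <- !gain & !is.na(cf[["omega_L"]])
  ok <- ok_g | ok_l
  if (any(ok)) {
    cf0 <- cf
    cf0[is.na(cf0)] <- 1  # placeholders; rows needing them are masked out
    p[ok] <- .choice_prob_vec(newdata[ok, , drop = FALSE], cf0,
                              object$options$probabilities)
  }
  p
}

#' @export
residuals.risk_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  p <- predict(object)
  obs <- object$dataset$k / object$dataset$n
  if (type == "response") return(obs - p)
  (object$dataset$k - object$dataset$n * p) /
    sqrt(object$dataset$n * p * (1 - p))
}

#' @export
simulate.risk_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object)
  n <- object$dataset$n
  lapply(seq_len(nsim), function(s) {
    ds <- object$dataset
    ds$k <- stats::rbinom(length(n), n, p)
    ds
  })
}

#' @export
summary.risk_fit <- function(object, ...) {
  out <- list(coefficients = object$coefficients,
              loglik = object$loglik,
              n_pairs = nrow(object$dataset),
              n_trials = sum(object$dataset$n),
              domains = object$domains,
              residuals = residuals(object))
  class(out) <- "summary.risk_fit"
  out
}

#' @export
print.summary.risk_fit <- function(x, ...) {
  cat("Risky-choice decision model fit (binomial ML)\n")
  cat(sprintf("  pairs: %d, trials: %d\n", x$n_pairs, x$n_trials))
  cat(sprintf("  log-likelihood: %.3f\n", x$loglik))
  cat("  coefficients:\n")
  print(round(x$coefficients, 4))
  cat("  Pearson residuals summary:\n")
  print(summary(x$residuals))
  invisible(x)
}

#' @export
plot.risk_fit <- function(x, ...) {
  p <- predict(x)
  obs <- x$dataset$k / x$dataset$n
  gain <- x$dataset$type == 6L
  graphics::plot(p, obs, xlim = c(0, 1), ylim = c(0, 1),
                 col = ifelse(gain, "steelblue", "darkorange"), pch = 19,
                 xlab = "model risky-choice probability",
                 ylab = "observed risky-choice frequency", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", legend = c("gains (type 6)", "losses (type 7)"),
                   col = c("steelblue", "darkorange"), pch = 19, bty = "n")
  invisible(x)
}

#' Split indices into contiguous near-equal chronological chunks
#'
#' The remainder is spread over the first chunks: 205 trials in 20 chunks
#' gives five chunks of 11 followed by fifteen of 10.
#'
#' @param n_trials Total number of trials.
#' @param n_chunks Number of chunks.
#' @return Integer vector of length `n_trials` with chunk labels 1..n_chunks.
#' @export
chunk_index <- function(n_trials, n_chunks) {
  if (n_trials < n_chunks) {
    stop("fewer trials than chunks", call. = FALSE)
  }
  base <- n_trials %/% n_chunks
  rem <- n_trials %% n_chunks
  sizes <- rep(base, n_chunks) + c(rep(1L, rem), rep(0L, n_chunks - rem))
  rep(seq_len(n_chunks), times = sizes)
}

#' Chronological chunked cross-validation fit
#'
#' Orders the trials chronologically, splits them into `n_chunks`
#' contiguous near-equal chunks, fits the decision model independently on
#' each chunk, and summarises the per-chunk estimates by their mean and
#' standard deviation per parameter.
#'
#' @param trials A trial table (see [aggregate_choices()]) with a `chrono`
#'   column giving the global chronological index.
#' @param n_chunks Number of chunks (default 20).
#' @param options A [fit_options()] list.
#' @return An object of class `"risk_fit_set"` with components `per_chunk`
#'   (data frame: chunk, the six parameters, loglik, n_trials), `mean`,
#'   `sd` (named length-6 vectors over the per-chunk values), `fits` (list
#'   of `risk_fit`), and `n_chunks`.
#' @export
chunked_fit <- function(trials, n_chunks = 20L, options = fit_options()) {
  if (!"chrono" %in% names(trials)) {
    stop("trials need a 'chrono' chronological index column", call. = FALSE)
  }
  risky <- trials[trials$type %in% 6:7, , drop = FALSE]
  risky <- risky[order(risky$chrono), , drop = FALSE]
  idx <- chunk_index(nrow(risky), n_chunks)
  fits <- lapply(seq_len(n_chunks), function(ch) {
    fit_mle(aggregate_choices(risky[idx == ch, , drop = FALSE]), options)
  })
  cf <- t(vapply(fits, coef, numeric(6)))
  per_chunk <- data.frame(chunk = seq_len(n_chunks), cf,
                          loglik = vapply(fits, function(f) f$loglik,
                                          numeric(1)),
                          n_trials = as.integer(table(idx)))
  structure(list(per_chunk = per_chunk,
                 mean = colMeans(cf),
                 sd = apply(cf, 2, stats::sd),
                 fits = fits, n_chunks = n_chunks, options = options),
            class = "risk_fit_set")
}

#' @export
print.risk_fit_set <- function(x, ...) {
  cat(sprintf("Chunked decision-model fit: %d chronological chunks\n",
              x$n_chunks))
  tab <- rbind(mean = x$mean, sd = x$sd)
  print(round(tab, 4))
  invisible(x)
}

#' @export
coef.risk_fit_set <- function(object, ...) object$mean

#' @export
summary.risk_fit_set <- function(object, ...) {
  out <- list(mean = object$mean, sd = object$sd,
              n_chunks = object$n_chunks, per_chunk = object$per_chunk)
  class(out) <- "summary.risk_fit_set"
  out
}

#' @export
print.summary.risk_fit_set <- function(x, ...) {
  cat(sprintf("Chunked decision-model fit over %d chunks\n", x$n_chunks))
  cat("  per-parameter mean +/- sd over chunks:\n")
  tab <- rbind(mean = x$mean, sd = x$sd)
  print(round(tab, 4))
  cat("  per-chunk log-likelihoods:\n")
  print(summary(x$per_chunk$loglik))
  invisible(x)
}

#' @export
plot.risk_fit_set <- function(x, pars = c("omega_G", "omega_L"), ...) {
  pc <- x$per_chunk
  graphics::matplot(pc$chunk, pc[, pars, drop = FALSE], type = "b",
                    pch = 19, lty = 1, xlab = "chunk (chronological)",
                    ylab = "parameter value", ...)
  graphics::legend("topright", legend = pars, col = seq_along(pars),
                   pch = 19, lty = 1, bty = "n")
  invisible(x)
}
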