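#' Certainty-risk trade-off contrast
#'
#' Compares risky-choice counts between the gain-domain certainty pair
#' (1 token for sure vs 2 tokens half of the time) and its loss-domain
#' mirror (-1 for sure vs -2 half of the time) with a 2x2 chi-square test
#' on domain x (risky, safe) counts, 1 degree of freedom, no continuity
#' correction. The null hypothesis is an equal risky-choice rate in the
#' two domains.
#'
#' @param gain_trials,loss_trials Either logical/0-1 vectors of risky-choice
#'   flags, or trial tables carrying a `chose_risky_or_dominant` column (in
#'   which case the rows are checked to be the two certainty pairs).
#' @param threshold Significance threshold (default 0.01).
#' @return A list of class `"risk_test"`: `statistic`, `df`, `p_value`,
#'   `table` (2x2 counts), `freq` (per-domain risky-choice frequency),
#'   `significant`.
#' @examples
#' certainty_risk_test(rbinom(100, 1, 0.2), rbinom(100, 1, 0.8))
#' @export
certainty_risk_test <- function(gain_trials, loss_trials, threshold = 0.01) {
  g <- .risky_flags(gain_trials, domain = "gain")
  l <- .risky_flags(loss_trials, domain = "loss")
  tab <- rbind(gain = c(risky = sum(g), safe = sum(!g)),
               loss = c(risky = sum(l), safe = sum(!l)))
  if (any(rowSums(tab) == 0L)) {
    stop("each domain needs at least one trial", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value),
                 table = tab,
                 freq = c(gain = mean(g), loss = mean(l)),
                 threshold = threshold,
                 significant = unname(ct$p.value) < threshold,
                 method = "2x2 chi-square, no continuity correction"),
            class = "risk_test")
}

.risky_flags <- function(x, domain) {
  if (is.data.frame(x)) {
    if (!"chose_risky_or_dominant" %in% names(x)) {
      stop("trial table lacks 'chose_risky_or_dominant'", call. = FALSE)
    }
    if (all(c("type", "x1", "p1", "x2", "p2") %in% names(x))) {
      want <- if (domain == "gain") {
        x$type == 6L & x$x1 == 2L & x$p1 == 0.5 & x$x2 == 1L & x$p2 == 1
      } else {
        x$type == 7L & x$x1 == -2L & x$p1 == 0.5 & x$x2 == -1L & x$p2 == 1
      }
      if (!all(want)) {
        stop("trials are not all on the ", domain,
             "-domain certainty pair", call. = FALSE)
      }
    }
    x <- x$chose_risky_or_dominant
  }
  as.logical(x)
}

#' @export
print.risk_test <- function(x, ...) {
  cat("Certainty-risk trade-off contrast\n")
  cat(sprintf("  chi-square = %.3f, df = %d, p = %.3g (threshold %.2g)%s\n",
              x$statistic, x$df, x$p_value, x$threshold,
              if (x$significant) " *" else ""))
  cat(sprintf("  risky-choice frequency: gains %.3f, losses %.3f\n",
              x$freq[["gain"]], x$freq[["loss"]]))
  invisible(x)
}

#' Performance on stochastic-dominance pairs
#'
#' For trials on pair types 1-5 (those containing a first-order dominant
#' member), computes the per-pair frequency of choosing the dominant
#' option, and per type the median, quartiles and 1.5-IQR whiskers of
#' those frequencies (the summaries drawn as box plots in task reports).
#'
#' @param trials Trial table with columns `type`, `x1`, `p1`, `x2`, `p2`
#'   and `chose_risky_or_dominant` (here: chose the dominant member).
#' @return A list of class `"dominance_performance"`: `per_pair` (data
#'   frame with pair columns, `n`, `success`), `per_type` (data frame with
#'   `type`, `n_pairs`, `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`).
#' @export
dominance_performance <- function(trials) {
  dom <- trials[trials$type %in% 1:5, , drop = FALSE]
  if (nrow(dom) == 0L) stop("no dominance-pair trials (types 1-5)",
                            call. = FALSE)
  key <- interaction(dom$type, dom$x1, dom$p1, dom$x2, dom$p2, drop = TRUE)
  idx <- split(seq_len(nrow(dom)), key)
  per_pair <- do.call(rbind, lapply(idx, function(i) {
    r <- dom[i[1L], c("type", "x1", "p1", "x2", "p2")]
    r$n <- length(i)
    r$success <- mean(dom$chose_risky_or_dominant[i])
    r
  }))
  per_pair <- per_pair[order(per_pair$type, per_pair$x1, per_pair$p1,
                             per_pair$x2, per_pair$p2), , drop = FALSE]
  rownames(per_pair) <- NULL
  per_type <- do.call(rbind, lapply(split(per_pair, per_pair$type),
                                    function(d) {
    q <- stats::quantile(d$success, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(type = d$type[1L], n_pairs = nrow(d),
               median = q[2], q1 = q[1], q3 = q[3],
               whisker_lo = max(min(d$success), q[1] - 1.5 * iqr),
               whisker_hi = min(max(d$success), q[3] + 1.5 * iqr))
  }))
  rownames(per_type) <- NULL
  structure(list(per_pair = per_pair, per_type = per_type),
            class = "dominance_performance")
}

#' @export
print.dominance_performance <- function(x, ...) {
  cat("Dominant-choice performance by pair type\n")
  print(round_df(x$per_type, 3))
  invisible(x)
}

round_df <- function(d, digits) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], round, digits = digits)
  d
}

#' Sigmoid fit of risky-choice frequency on expected-value difference
#'
#' Fits `f(delta) = 1 / (1 + exp(-beta * (delta - gamma)))` to per-pair
#' risky-choice frequencies by nonlinear least squares
#' (Levenberg-Marquardt), optionally weighting each point by its trial
#' count. `delta` is the expected-value difference riskier-minus-safer in
#' token units; `beta` is the slope per token and `gamma` the
#' indifference intercept in tokens. Confidence margins are Wald intervals
#' from the parameter covariance at the stated threshold.
#'
#' @param delta Numeric vector of per-pair expected-value differences
#'   (tokens), at least 4 distinct values.
#' @param freq Risky-choice frequency per pair, in \[0, 1\].
#' @param n Optional trial counts per pair (weights).
#' @param weighted Weight points by `n` (default TRUE when `n` given).
#' @param threshold Two-sided significance level for the margins
#'   (default 0.01, i.e. 99% intervals).
#' @return A list of class `"sigmoid_fit"`: `beta`, `gamma`, `ci_beta`,
#'   `ci_gamma`, `fitted`, `residuals`, and the underlying `nls` object.
#' @examples
#' d <- seq(-1, 1, length.out = 9)
#' f <- 1 / (1 + exp(-1.83 * d))
#' fit_risk_sigmoid(d, f)
#' @export
fit_risk_sigmoid <- function(delta, freq, n = NULL,
                             weighted = !is.null(n), threshold = 0.01) {
  stopifnot(length(delta) == length(freq))
  if (length(unique(delta)) < 4L) {
    stop("need at least 4 distinct expected-value differences",
         call. = FALSE)
  }
  if (any(freq < 0) || any(freq > 1)) {
    stop("'freq' must lie in [0, 1]", call. = FALSE)
  }
  w <- if (weighted && !is.null(n)) as.numeric(n) else rep(1, length(delta))
  sw <- sqrt(w)
  sig <- function(par) 1 / (1 + exp(-par[1] * (delta - par[2])))
  res_fn <- function(par) sw * (freq - sig(par))
  jac_fn <- function(par) {
    s <- sig(par)
    ds <- s * (1 - s)
    # jacobian of the residuals (note the leading minus)
    cbind(beta = -sw * ds * (delta - par[2]), gamma = sw * ds * par[1])
  }
  fit <- minpack.lm::nls.lm(par = c(beta = 1, gamma = 0),
                            fn = res_fn, jac = jac_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  if (!fit$info %in% 1:4) {
    stop("sigmoid fit failed to converge (", fit$message, ")",
         "\n  residual sum of squares at stop: ",
         signif(fit$deviance, 6), call. = FALSE)
  }
  est <- fit$par
  df <- length(delta) - 2L
  sigma2 <- fit$deviance / df
  jw <- jac_fn(est)
  se <- tryCatch(sqrt(diag(sigma2 * solve(crossprod(jw)))),
                 error = function(e) c(beta = NA_real_, gamma = NA_real_))
  crit <- stats::qt(1 - threshold / 2, df)
  structure(list(beta = unname(est[["beta"]]),
                 gamma = unname(est[["gamma"]]),
                 ci_beta = unname(est[["beta"]] + c(-1, 1) * crit *
                                    se[["beta"]]),
                 ci_gamma = unname(est[["gamma"]] + c(-1, 1) * crit *
                                     se[["gamma"]]),
                 threshold = threshold,
                 fitted = sig(est),
                 residuals = freq - sig(est),
                 nls = fit),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("Sigmoid fit of risky-choice frequency on EV difference\n")
  cat(sprintf("  beta  = %.3f  [%.3f, %.3f]\n", x$beta,
              x$ci_beta[1], x$ci_beta[2]))
  cat(sprintf("  gamma = %.3f  [%.3f, %.3f]   (margins at p = %.2g)\n",
              x$gamma, x$ci_gamma[1], x$ci_gamma[2], x$threshold))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-sum test reporting the classical U statistic `min(U1, U2)`. The
#' default p-value uses the normal approximation with tie-corrected
#' variance (two-sided, no continuity correction); `exact = TRUE`
#' enumerates the permutation distribution of U (feasible for small
#' samples, ties allowed).
#'
#' @param x,y Numeric samples.
#' @param exact Use exact enumeration of the U distribution.
#' @return A list of class `"mw_test"`: `u` (min of the two U values),
#'   `u_x` (U of the first sample), `p_value`, `n_x`, `n_y`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact = FALSE) {
  m <- length(x); n <- length(y)
  stopifnot(m > 0L, n > 0L)
  r <- rank(c(x, y))
  u_x <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  u_y <- m * n - u_x
  u <- min(u_x, u_y)
  if (exact) {
    if (choose(m + n, m) > 5e5) {
      stop("exact enumeration infeasible for these sample sizes",
           call. = FALSE)
    }
    sets <- utils::combn(m + n, m)
    u_all <- colSums(matrix(r[sets], nrow = m)) - m * (m + 1) / 2
    p <- min(1, 2 * min(mean(u_all <= u_x), mean(u_all >= u_x)))
    method <- "exact enumeration"
  } else {
    mu <- m * n / 2
    ties <- table(r)
    sigma2 <- m * n / 12 *
      (m + n + 1 - sum(ties^3 - ties) / ((m + n) * (m + n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u_x - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation, tie-corrected"
  }
  structure(list(u = u, u_x = u_x, u_y = u_y, p_value = p,
                 n_x = m, n_y = n, method = method),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U: u = %.1f, p = %.4g (%s; n = %d vs %d)\n",
              x$u, x$p_value, x$method, x$n_x, x$n_y))
  invisible(x)
}

#' Gain-versus-loss contrasts of the fitted parameter families
#'
#' For each parameter family (`omega`, `alpha`, `lambda`), compares the
#' per-chunk gain-domain values against the per-chunk loss-domain values
#' with a two-sided Mann-Whitney U test and applies a Bonferroni
#' correction over the three families.
#'
#' @param fit A `"risk_fit_set"` from [chunked_fit()].
#' @param m Bonferroni multiplicity (default 3, the three families).
#' @param threshold Familywise significance threshold (default 0.01).
#' @param exact Use exact enumeration in [mann_whitney_u()].
#' @return A data frame of class `"gain_loss_comparison"`: one row per
#'   family with `u`, `p_value`, `p_adjusted`, `significant`, `n_gain`,
#'   `n_loss`.
#' @export
compare_gain_loss_params <- function(fit, m = 3L, threshold = 0.01,
                                     exact = FALSE) {
  stopifnot(inherits(fit, "risk_fit_set"))
  pc <- fit$per_chunk
  fams <- c("omega", "alpha", "lambda")
  rows <- lapply(fams, function(f) {
    g <- pc[[paste0(f, "_G")]]
    l <- pc[[paste0(f, "_L")]]
    if (length(g) != length(l)) {
      stop("unequal chunk counts between domains", call. = FALSE)
    }
    if (anyNA(g) || anyNA(l)) {
      stop("per-chunk values contain NA (unidentified domain)",
           call. = FALSE)
    }
    tst <- mann_whitney_u(g, l, exact = exact)
    data.frame(family = f, u = tst$u, p_value = tst$p_value,
               p_adjusted = min(1, tst$p_value * m),
               significant = min(1, tst$p_value * m) < threshold,
               n_gain = tst$n_x, n_loss = tst$n_y)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "bonferroni_m") <- m
  class(out) <- c("gain_loss_comparison", "data.frame")
  out
}

#' @export
print.gain_loss_comparison <- function(x, ...) {
  cat(sprintf(
    "Gain-vs-loss parameter contrasts (Mann-Whitney, Bonferroni m = %d, threshold %.2g)\n",
    attr(x, "bonferroni_m"), attr(x, "threshold")))
  print(round_df(as.data.frame(x), 4))
  invisible(x)
}

#' Temporal trend of per-chunk parameter values
#'
#' Ordinary least squares of a chronologically ordered series of per-chunk
#' best-fit values on the chunk index, with the F test of the slope.
#'
#' @param series Numeric vector of per-chunk values in chronological order.
#' @return A list of class `"trend_fit"`: `slope`, `intercept`,
#'   `F_statistic`, `p_value`, `df`, `note`. A constant series has an
#'   undefined F statistic, reported as `NA` with a note.
#' @export
parameter_trend <- function(series) {
  stopifnot(is.numeric(series), length(series) >= 3L)
  idx <- seq_along(series)
  if (stats::sd(series) == 0) {
    return(structure(list(slope = 0, intercept = series[1L],
                          F_statistic = NA_real_, p_value = NA_real_,
                          df = c(1L, length(series) - 2L),
                          note = "constant series: F undefined"),
                     class = "trend_fit"))
  }
  fit <- stats::lm(series ~ idx)
  an <- stats::anova(fit)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 F_statistic = an$`F value`[1L],
                 p_value = an$`Pr(>F)`[1L],
                 df = c(an$Df[1L], an$Df[2L]),
                 note = NULL),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("Per-chunk parameter trend (OLS on chunk index)\n")
  if (!is.null(x$note)) {
    cat("  ", x$note, "\n", sep = "")
  } else {
    cat(sprintf("  slope = %.4f, F(%d, %d) = %.3f, p = %.4g\n",
                x$slope, x$df[1], x$df[2], x$F_statistic, x$p_value))
  }
  invisible(x)
}
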