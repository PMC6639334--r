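#' Decision-model parameters
#'
#' The model has six free parameters, three per outcome domain:
#' risk attitude `omega` (utility curvature; in \[-1, 1\], positive =
#' risk-averse for gains and, through the loss exponent `1 + omega_L`,
#' negative `omega_L` = risk-seeking for losses), Prelec distortion
#' `alpha` (in (0, 1]; 1 = undistorted, towards 0 = stronger over-weighting
#' of small and under-weighting of large probabilities), and choice
#' precision `lambda` (in (0, Inf); towards 0 = random choice, large =
#' near-deterministic choice at the indifference boundary).
#'
#' Out-of-box values are rejected, never clipped.
#'
#' @param omega_G,omega_L Risk-attitude parameters, each in \[-1, 1\].
#' @param alpha_G,alpha_L Probability-distortion parameters, each in (0, 1].
#' @param lambda_G,lambda_L Choice-precision parameters, each > 0 and finite.
#' @return An object of class `"model_params"`: a named numeric vector of
#'   length 6.
#' @examples
#' model_params(omega_G = 0.28, omega_L = -0.71,
#'              alpha_G = 0.63, alpha_L = 0.21,
#'              lambda_G = 2.52, lambda_L = 1.82)
#' @export
model_params <- function(omega_G = 0, omega_L = 0,
                         alpha_G = 1, alpha_L = 1,
                         lambda_G = 1, lambda_L = 1) {
  th <- c(omega_G = omega_G, omega_L = omega_L,
          alpha_G = alpha_G, alpha_L = alpha_L,
          lambda_G = lambda_G, lambda_L = lambda_L)
  if (any(!is.finite(th))) stop("all parameters must be finite", call. = FALSE)
  if (abs(omega_G) > 1 || abs(omega_L) > 1) {
    stop("omega parameters must lie in [-1, 1]", call. = FALSE)
  }
  if (alpha_G <= 0 || alpha_G > 1 || alpha_L <= 0 || alpha_L > 1) {
    stop("alpha parameters must lie in (0, 1]", call. = FALSE)
  }
  if (lambda_G <= 0 || lambda_L <= 0) {
    stop("lambda parameters must be positive", call. = FALSE)
  }
  structure(th, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Decision-model parameters:\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Normalize a token amount to the model's \[-1, 1\] scale
#'
#' Amounts enter the utility function divided by the maximal absolute
#' amount of the design (3 tokens), so gains map onto \{1/3, 2/3, 1\} and
#' losses onto their negatives.
#'
#' @param x_tokens Numeric token amount(s) in \[-3, 3\].
#' @return `x_tokens / 3`.
#' @export
normalize_amount <- function(x_tokens) {
  if (any(!is.finite(x_tokens)) || any(abs(x_tokens) > 3)) {
    stop("'x_tokens' must lie in [-3, 3]", call. = FALSE)
  }
  x_tokens / 3
}

#' Domain-specific power utility
#'
#' `u(x) = x^(1 - omega_G)` for gains, `u(x) = -|x|^(1 + omega_L)` for
#' losses, and `u(0) = 0`, on normalized amounts `x` in \[-1, 1\]. Positive
#' `omega_G` gives a concave gain branch (risk aversion for gains);
#' negative `omega_L` gives a convex loss branch (risk seeking for losses).
#'
#' @param x_norm Normalized amount(s) in \[-1, 1\] (see
#'   [normalize_amount()]).
#' @param omega_G,omega_L Risk-attitude parameters in \[-1, 1\].
#' @return Utility value(s) in \[-1, 1\].
#' @examples
#' utility(1, omega_G = 0.28)    # 1
#' utility(-2/3, omega_L = -0.71) # -(2/3)^0.29
#' @export
utility <- function(x_norm, omega_G = 0, omega_L = 0) {
  if (any(!is.finite(x_norm)) || any(abs(x_norm) > 1)) {
    stop("'x_norm' must lie in [-1, 1]", call. = FALSE)
  }
  if (abs(omega_G) > 1 || abs(omega_L) > 1) {
    stop("omega parameters must lie in [-1, 1]", call. = FALSE)
  }
  u <- numeric(length(x_norm))
  pos <- x_norm > 0
  neg <- x_norm < 0
  u[pos] <- x_norm[pos]^(1 - omega_G)
  u[neg] <- -abs(x_norm[neg])^(1 + omega_L)
  u
}

#' Prelec one-parameter probability weighting
#'
#' `w(p) = exp(-(-ln p)^alpha)`, with `w(0) = 0` by continuity and
#' `w(1) = 1` exactly. `alpha = 1` is the identity; smaller `alpha`
#' over-weights small probabilities and under-weights large ones, with the
#' fixed point at `p = 1/e`.
#'
#' @param p Probability value(s) in \[0, 1\].
#' @param alpha Distortion parameter in (0, 1].
#' @return Distorted probability value(s) in \[0, 1\].
#' @examples
#' prelec_weight(0.25, 0.5) # exp(-sqrt(log(4)))
#' @export
prelec_weight <- function(p, alpha) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha > 1) {
    stop("'alpha' must lie in (0, 1]", call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("'p' must lie in [0, 1]", call. = FALSE)
  }
  w <- exp(-(-log(p))^alpha)
  w[p == 0] <- 0
  w[p == 1] <- 1
  w
}

#' Subjective value of a lottery
#'
#' `U(L) = w(p) * u(x/3)`, using the gain-domain parameters
#' `(omega_G, alpha_G)` for positive amounts and the loss-domain parameters
#' `(omega_L, alpha_L)` for negative ones.
#'
#' @param L A [lottery()].
#' @param params A [model_params()] object.
#' @return The subjective value, a dimensionless scalar in \[-1, 1\].
#' @export
subjective_value <- function(L, params) {
  stopifnot(inherits(L, "lottery"), inherits(params, "model_params"))
  alpha <- if (L$x > 0) params[["alpha_G"]] else params[["alpha_L"]]
  prelec_weight(L$p, alpha) *
    utility(normalize_amount(L$x), params[["omega_G"]], params[["omega_L"]])
}

## Vectorised indifference point over canonical risky pairs.
## gain: solve w(p1) x1^(1-w) = w(p2) x2^(1-w)  ->  1 - log(w2/w1)/log(x1/x2)
## loss: solve w(p1)(-|x1|^(1+w)) = w(p2)(-|x2|^(1+w))
##                                  ->  log(w2/w1)/log(|x1|/|x2|) - 1
## Amount normalization cancels in the ratios. `mode = "raw"` substitutes
## undistorted probabilities for w(p).
.omega_star <- function(x1, p1, x2, p2, alpha, mode = "distorted") {
  if (mode == "raw") {
    w1 <- p1; w2 <- p2
  } else {
    w1 <- prelec_weight(p1, alpha)
    w2 <- prelec_weight(p2, alpha)
  }
  lr <- log(w2 / w1)
  gains <- x1 > 0
  ifelse(gains,
         1 - lr / log(x1 / x2),
         lr / log(abs(x1) / abs(x2)) - 1)
}

#' Risk-attitude indifference point of a risky pair
#'
#' The `omega` value at which the two members of a type-6/7 pair have equal
#' subjective value under the pair's domain parameters; the choice rule is
#' a logistic in `lambda * (omega_star - omega)`. Computed in closed form
#' from the ratio of (distorted) probabilities and amounts; the value may
#' fall outside \[-1, 1\] and is returned unclamped.
#'
#' @param pair A [lottery_pair()] of type 6 or 7.
#' @param alpha Distortion parameter used to weight the pair's
#'   probabilities, in (0, 1].
#' @param probabilities `"distorted"` (default) weights the probabilities
#'   with the Prelec function before solving; `"raw"` uses them as printed.
#' @return The indifference value `omega_star` (unclamped).
#' @examples
#' indifference_omega(lottery_pair(lottery(3, 0.25), lottery(2, 0.5)), 1)
#' # 1 - log(2)/log(1.5)
#' @export
indifference_omega <- function(pair, alpha,
                               probabilities = c("distorted", "raw")) {
  stopifnot(inherits(pair, "lottery_pair"))
  probabilities <- match.arg(probabilities)
  if (!pair$pair_type %in% 6:7) {
    stop("indifference point requires a riskier member (types 6/7)",
         call. = FALSE)
  }
  if (pair$x1 == pair$x2 || pair$p1 == pair$p2) {
    stop("no unique indifference point when amounts or probabilities tie",
         call. = FALSE)
  }
  .omega_star(pair$x1, pair$p1, pair$x2, pair$p2, alpha, probabilities)
}

#' Probability of choosing the riskier lottery
#'
#' The stochastic choice rule is a logistic in the distance between the
#' pair's indifference point and the subject's risk attitude:
#' `p(risky) = 1 / (1 + exp(-lambda * (omega_star - omega)))`, using the
#' gain-domain parameters for type-6 pairs and the loss-domain parameters
#' for type-7 pairs. This rule is monotone in `omega` by construction (it
#' avoids the preference-reversal pathologies of a direct softmax over
#' subjective values) and crosses 0.5 exactly at `omega = omega_star`.
#'
#' @param pair A [lottery_pair()] of type 6 or 7.
#' @param params A [model_params()] object.
#' @param probabilities Passed to [indifference_omega()].
#' @return The probability of choosing the riskier member, in (0, 1).
#' @export
choice_prob_risky <- function(pair, params,
                              probabilities = c("distorted", "raw")) {
  stopifnot(inherits(pair, "lottery_pair"), inherits(params, "model_params"))
  probabilities <- match.arg(probabilities)
  gain <- pair$pair_type == 6L
  omega  <- if (gain) params[["omega_G"]]  else params[["omega_L"]]
  alpha  <- if (gain) params[["alpha_G"]]  else params[["alpha_L"]]
  lambda <- if (gain) params[["lambda_G"]] else params[["lambda_L"]]
  ws <- indifference_omega(pair, alpha, probabilities)
  stats::plogis(lambda * (ws - omega))
}

## Vectorised choice probability for a canonical risky-pair data frame
## (columns type/x1/p1/x2/p2), one (omega, alpha, lambda) per domain.
.choice_prob_vec <- function(df, theta, mode = "distorted") {
  gain <- df$type == 6L
  alpha <- ifelse(gain, theta[["alpha_G"]], theta[["alpha_L"]])
  omega <- ifelse(gain, theta[["omega_G"]], theta[["omega_L"]])
  lambda <- ifelse(gain, theta[["lambda_G"]], theta[["lambda_L"]])
  ws <- .omega_star_by_alpha(df, alpha, mode)
  stats::plogis(lambda * (ws - omega))
}

## .omega_star with possibly element-wise alpha (prelec_weight takes scalar
## alpha, so split on unique values).
.omega_star_by_alpha <- function(df, alpha, mode) {
  ws <- numeric(nrow(df))
  for (a in unique(alpha)) {
    i <- alpha == a
    ws[i] <- .omega_star(df$x1[i], df$p1[i], df$x2[i], df$p2[i], a, mode)
  }
  ws
}
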