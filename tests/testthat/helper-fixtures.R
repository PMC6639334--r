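# Shared fixtures for the suite. All data are generated in code.

monkey_h_params <- function() {
  model_params(omega_G = 0.28, omega_L = -0.71,
               alpha_G = 0.63, alpha_L = 0.21,
               lambda_G = 2.52, lambda_L = 1.82)
}

# A small risky-only (types 6/7) simulated trial table.
risky_trials <- function(n_trials, seed = 1L, params = monkey_h_params()) {
  design <- design_table(6:7)
  sched <- build_schedule(n_days = ceiling(n_trials / 200),
                          trials_per_day_mean = 200, trials_per_day_sd = 0,
                          design = design, seed = seed)
  sched <- sched[seq_len(n_trials), , drop = FALSE]
  simulate_agent(agent_spec(params = params, seed = seed + 7919L), sched)
}

# Bisection oracle for the indifference point: sign change of the
# subjective-value difference over omega. Independent of the closed form.
bisect_omega_star <- function(x1, p1, x2, p2, alpha,
                              lo = -5, hi = 5, tol = 1e-12) {
  w <- function(p) exp(-(-log(p))^alpha)
  udiff <- function(om) {
    if (x1 > 0) {
      w(p1) * (x1 / 3)^(1 - om) - w(p2) * (x2 / 3)^(1 - om)
    } else {
      -w(p1) * (abs(x1) / 3)^(1 + om) + w(p2) * (abs(x2) / 3)^(1 + om)
    }
  }
  flo <- udiff(lo)
  stopifnot(sign(flo) != sign(udiff(hi)))
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- udiff(mid)
    if (abs(hi - lo) < tol) break
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

# Textbook 2x2 chi-square: n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)).
chisq_2x2_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- sum(tab)
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Brute-force Mann-Whitney: U of x and the exact two-sided p by
# enumerating every assignment of the pooled ranks.
mw_enumeration_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u_x <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  sets <- combn(m + n, m)
  u_all <- apply(sets, 2, function(i) sum(r[i]) - m * (m + 1) / 2)
  p <- min(1, 2 * min(mean(u_all <= u_x), mean(u_all >= u_x)))
  list(u_x = u_x, u = min(u_x, m * n - u_x), p = p)
}
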