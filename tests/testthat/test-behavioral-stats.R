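test_that("certainty-risk chi-square matches the textbook formula", {
  # counts (risky, safe) x (gain, loss): [[10, 90], [90, 10]]
  g <- c(rep(TRUE, 10), rep(FALSE, 90))
  l <- c(rep(TRUE, 90), rep(FALSE, 10))
  ct <- certainty_risk_test(g, l)
  expect_equal(ct$statistic, chisq_2x2_oracle(ct$table))
  expect_equal(ct$statistic, 128)
  expect_identical(ct$df, 1L)
  expect_true(ct$significant)
  # symmetry under swapping domain labels
  ct_swap <- certainty_risk_test(l, g)
  expect_equal(ct_swap$statistic, ct$statistic)
  # identical frequencies -> zero statistic
  ct0 <- certainty_risk_test(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(ct0$statistic, 0)
  expect_error(certainty_risk_test(logical(0), l), "at least one trial")
})

test_that("a gain-averse / loss-seeking agent separates the domains", {
  design <- design_table(6:7)
  cert <- design[(design$x1 == 2 & design$p1 == 0.5 &
                    design$x2 == 1 & design$p2 == 1) |
                   (design$x1 == -2 & design$p1 == 0.5 &
                      design$x2 == -1 & design$p2 == 1), ]
  sched <- build_schedule(n_days = 2, trials_per_day_mean = 150,
                          trials_per_day_sd = 0, design = cert, seed = 31)
  tr <- simulate_agent(agent_spec(seed = 31), sched)
  ct <- certainty_risk_test(tr[tr$type == 6L, ], tr[tr$type == 7L, ])
  expect_lt(ct$p_value, 0.01)
  # the asymmetry has the human direction: risk-averse for gains,
  # risk-seeking for losses
  expect_lt(ct$freq[["gain"]], ct$freq[["loss"]])
})

test_that("dominance performance summarises per-pair success rates", {
  design <- design_table(1:5)
  sched <- build_schedule(n_days = 5, trials_per_day_mean = 400,
                          trials_per_day_sd = 0, design = design, seed = 41)
  # perfect agent: every pair at 1, degenerate IQR
  acc1 <- setNames(rep(1, 5), 1:5)
  tr1 <- simulate_agent(agent_spec(dominance_accuracy = acc1, seed = 42),
                        sched)
  perf1 <- dominance_performance(tr1)
  expect_true(all(perf1$per_pair$success == 1))
  expect_true(all(perf1$per_type$q3 - perf1$per_type$q1 == 0))
  # mixed per-type accuracies: medians track the generating values
  agent <- agent_spec(seed = 43)
  tr2 <- simulate_agent(agent, sched)
  perf2 <- dominance_performance(tr2)
  expect_true(all(abs(perf2$per_type$median -
                        agent$dominance_accuracy[
                          as.character(perf2$per_type$type)]) < 0.07))
  expect_true(which.min(perf2$per_type$median) ==
                which(perf2$per_type$type == 3))
})

test_that("random choice on dominance pairs gives medians near 0.5", {
  design <- design_table(1:5)
  n_per_pair <- 220L
  set.seed(51)
  succ <- rbinom(nrow(design), n_per_pair, 0.5) / n_per_pair
  # binomial sampling oracle, bypassing the agent's [0.5, 1] floor
  med <- tapply(succ, design$type, median)
  expect_true(all(abs(med - 0.5) < 3 * sqrt(0.25 / n_per_pair) + 0.02))
})

test_that("sigmoid fit round-trips noiseless generating parameters", {
  p6 <- enumerate_pairs(6)
  delta <- p6$p1 * p6$x1 - p6$p2 * p6$x2
  freq <- 1 / (1 + exp(-1.83 * (delta - 0)))
  fit <- fit_risk_sigmoid(delta, freq)
  expect_equal(fit$beta, 1.83, tolerance = 1e-6)
  expect_equal(fit$gamma, 0, tolerance = 1e-6)
  expect_true(fit$ci_beta[1] <= fit$beta && fit$beta <= fit$ci_beta[2])
  # equivariance: shifting delta shifts gamma, leaves beta unchanged
  fit_sh <- fit_risk_sigmoid(delta + 0.4, freq)
  expect_equal(fit_sh$beta, fit$beta, tolerance = 1e-6)
  expect_equal(fit_sh$gamma, fit$gamma + 0.4, tolerance = 1e-6)
  # flat data: slope collapses to zero
  flat <- fit_risk_sigmoid(delta, rep(0.5, length(delta)))
  expect_equal(flat$beta, 0, tolerance = 1e-6)
  expect_error(fit_risk_sigmoid(c(0, 0, 1, 1), c(0.2, 0.3, 0.6, 0.7)),
               "distinct")
})

test_that("sigmoid 99% intervals cover the truth in noisy replicates", {
  p6 <- enumerate_pairs(6)
  delta <- p6$p1 * p6$x1 - p6$p2 * p6$x2
  n <- 100L
  truth <- 1.83
  covered <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    freq <- rbinom(length(delta), n, 1 / (1 + exp(-truth * delta))) / n
    fit <- fit_risk_sigmoid(delta, freq, n = rep(n, length(delta)))
    fit$ci_beta[1] <= truth && truth <= fit$ci_beta[2]
  }, logical(1))
  expect_gte(mean(covered), 0.95)
})

test_that("Mann-Whitney matches brute-force enumeration for small n", {
  cases <- list(
    list(x = c(1.2, 3.4, 0.2, 5.5), y = c(2.2, 0.1, 4.4)),
    list(x = c(1, 2, 3, 4, 5, 6, 7, 8), y = c(2.5, 3.5, 9, 10, 0.5, 6.5,
                                              7.5, 1.5)),
    list(x = c(1, 1, 2, 3), y = c(1, 2, 2, 4)),       # ties across groups
    list(x = c(5, 6, 7), y = c(1, 2, 3))              # full separation
  )
  for (cs in cases) {
    got <- mann_whitney_u(cs$x, cs$y, exact = TRUE)
    oracle <- mw_enumeration_oracle(cs$x, cs$y)
    expect_equal(got$u, oracle$u)
    expect_equal(got$u_x, oracle$u_x)
    expect_equal(got$p_value, oracle$p)
  }
  # cross-check against the standard implementation on a tie-free case
  ref <- wilcox.test(cases[[2]]$x, cases[[2]]$y, exact = TRUE)
  got <- mann_whitney_u(cases[[2]]$x, cases[[2]]$y, exact = TRUE)
  expect_equal(got$p_value, ref$p.value)
  expect_equal(got$u_x, unname(ref$statistic))
})

test_that("Mann-Whitney degenerate and separated cases behave", {
  x <- 1:20
  same <- mann_whitney_u(x, x)
  expect_equal(same$u, 200)
  expect_gt(same$p_value, 0.99)
  sep <- mann_whitney_u(x, x + 100)
  expect_equal(sep$u, 0)
  expect_lt(sep$p_value, 0.001)
})

test_that("gain-loss contrasts flag separated families only", {
  # synthetic per-chunk table: omega fully separated, lambda identical
  pc <- data.frame(chunk = 1:20,
                   omega_G = seq(0.2, 0.4, length.out = 20),
                   omega_L = seq(-0.8, -0.6, length.out = 20),
                   alpha_G = seq(0.5, 0.7, length.out = 20),
                   alpha_L = seq(0.1, 0.3, length.out = 20),
                   lambda_G = rep(2, 20), lambda_L = rep(2, 20))
  fake <- structure(list(per_chunk = pc, n_chunks = 20L),
                    class = "risk_fit_set")
  cmp <- compare_gain_loss_params(fake)
  expect_identical(cmp$family, c("omega", "alpha", "lambda"))
  expect_equal(cmp$u[1:2], c(0, 0))
  expect_true(all(cmp$significant[1:2]))
  expect_equal(cmp$u[3], 200)
  expect_false(cmp$significant[3])
  expect_true(all(cmp$p_adjusted >= cmp$p_value))
})

test_that("contrasts under the null reject at most the nominal rate", {
  n_rep <- 500L
  rejects <- vapply(1:n_rep, function(s) {
    set.seed(s)
    pc <- data.frame(chunk = 1:20,
                     omega_G = rnorm(20, 0.2, 0.2),
                     omega_L = rnorm(20, 0.2, 0.2),
                     alpha_G = rnorm(20, 0.5, 0.15),
                     alpha_L = rnorm(20, 0.5, 0.15),
                     lambda_G = rnorm(20, 2, 0.5),
                     lambda_L = rnorm(20, 2, 0.5))
    fake <- structure(list(per_chunk = pc, n_chunks = 20L),
                      class = "risk_fit_set")
    any(compare_gain_loss_params(fake)$significant)
  }, logical(1))
  nominal <- 0.01 # familywise, Bonferroni-controlled
  expect_lte(mean(rejects),
             nominal + 2 * sqrt(nominal * (1 - nominal) / n_rep))
})

test_that("parameter trend regression recovers slopes", {
  perfect <- 0.1 * (1:20)
  tr <- suppressWarnings(parameter_trend(perfect)) # exact fit trips lm's
  # essentially-perfect-fit caution; slope and p are still exact here
  expect_equal(tr$slope, 0.1)
  expect_lt(tr$p_value, 1e-10)
  set.seed(61)
  noisy <- -0.02 * (1:20) + rnorm(20, 0, 0.01)
  tr2 <- parameter_trend(noisy)
  expect_lt(abs(tr2$slope - (-0.02)), 0.002)
  const <- parameter_trend(rep(1.5, 20))
  expect_true(is.na(const$F_statistic))
  expect_match(const$note, "constant")
})

test_that("trend test holds its size under white noise", {
  n_rep <- 200L
  p <- vapply(1:n_rep, function(s) {
    set.seed(s)
    parameter_trend(rnorm(20))$p_value
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep) + 0.01)
  # uniformity of the null p-values, coarse check
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})

test_that("model-generated per-chunk values show the gain-loss asymmetry", {
  tr <- risky_trials(5000, seed = 1)
  cf <- chunked_fit(tr, n_chunks = 20)
  cmp <- compare_gain_loss_params(cf)
  # omega and alpha separate decisively
  expect_true(all(cmp$significant[cmp$family %in% c("omega", "alpha")]))
  # the lambda contrast is far weaker than omega's and alpha's
  expect_gt(cmp$p_adjusted[cmp$family == "lambda"],
            1e3 * max(cmp$p_adjusted[cmp$family != "lambda"], 1e-12))
})
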