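test_that("aggregation counts risky choices per distinct pair", {
  tr <- risky_trials(300, seed = 11)
  ds <- aggregate_choices(tr)
  expect_s3_class(ds, "choice_dataset")
  expect_identical(sum(ds$n), 300L)
  expect_true(all(ds$k >= 0 & ds$k <= ds$n))
  expect_false(anyDuplicated(ds[, c("type", "x1", "p1", "x2", "p2")]) > 0)
  # hand-built three-trial case: risky/safe/risky -> (n = 3, k = 2)
  one <- tr[1, ]
  three <- rbind(one, one, one)
  three$chose_risky_or_dominant <- c(TRUE, FALSE, TRUE)
  agg <- aggregate_choices(three)
  expect_identical(agg$n, 3L)
  expect_identical(agg$k, 2L)
  # empty input -> empty dataset
  expect_identical(nrow(aggregate_choices(tr[0, ])), 0L)
  # unclassifiable rows are rejected with the offending row number
  bad <- tr
  bad$type[5] <- NA
  expect_error(aggregate_choices(bad), "row.*5")
})

test_that("log-likelihood equals the binomial mass in hand cases", {
  p6 <- enumerate_pairs(6)
  pairs <- p6[p6$x1 == 3 & p6$p1 == 0.25 & p6$x2 == 2 & p6$p2 == 0.5, ,
              drop = FALSE] # (3, 0.25) vs (2, 0.5)
  ws <- 1 - log(2) / log(1.5)
  # parameters placing omega exactly at omega*: model p = 0.5
  th <- model_params(omega_G = max(-1, min(1, ws)), alpha_G = 1,
                     lambda_G = 1)
  # omega* is inside [-1, 1] for this pair
  expect_equal(th[["omega_G"]], ws)
  expect_equal(log_likelihood(choice_dataset(pairs, n = 1, k = 1), th),
               log(0.5))
  expect_equal(log_likelihood(choice_dataset(pairs, n = 2, k = 1), th),
               log(2 * 0.25))
  # perfect fit: p numerically 1 with k = n gives the upper bound 0
  th_hi <- model_params(omega_G = -1, alpha_G = 1, lambda_G = 1e3)
  expect_equal(log_likelihood(choice_dataset(pairs, n = 50, k = 50), th_hi),
               0)
  # counts contradicting a near-degenerate probability: a harsh but
  # well-defined penalty (log-space arithmetic never produces NaN)
  ll_bad <- log_likelihood(choice_dataset(pairs, n = 50, k = 0), th_hi)
  expect_false(is.nan(ll_bad))
  expect_lt(ll_bad, -1e4)
})

test_that("log-likelihood is non-positive and permutation-invariant", {
  tr <- risky_trials(1000, seed = 3)
  ds <- aggregate_choices(tr)
  th <- monkey_h_params()
  ll <- log_likelihood(ds, th)
  expect_lte(ll, 0)
  set.seed(42)
  perm <- ds[sample(nrow(ds)), , drop = FALSE]
  class(perm) <- class(ds)
  expect_equal(log_likelihood(perm, th), ll)
  fit1 <- fit_mle(ds)
  fit2 <- fit_mle(perm)
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-6)
})

test_that("gain and loss fits separate exactly", {
  tr <- risky_trials(4000, seed = 5)
  ds <- aggregate_choices(tr)
  joint <- fit_mle(ds)
  gain_only <- fit_mle(ds[ds$type == 6L, , drop = FALSE])
  loss_only <- fit_mle(ds[ds$type == 7L, , drop = FALSE])
  gk <- c("omega_G", "alpha_G", "lambda_G")
  lk <- c("omega_L", "alpha_L", "lambda_L")
  expect_equal(coef(joint)[gk], coef(gain_only)[gk], tolerance = 1e-6)
  expect_equal(coef(joint)[lk], coef(loss_only)[lk], tolerance = 1e-6)
  # the missing domain of a one-domain fit is reported unidentified
  expect_true(all(is.na(coef(gain_only)[lk])))
  expect_false(gain_only$domains$loss$identified)
})

test_that("the MLE is no worse than the generating parameters", {
  tr <- risky_trials(2000, seed = 9)
  ds <- aggregate_choices(tr)
  fit <- fit_mle(ds)
  expect_gte(fit$loglik, log_likelihood(ds, monkey_h_params()))
})

test_that("moderate-n fits recover the generating parameters", {
  tr <- risky_trials(6000, seed = 13)
  fit <- fit_mle(aggregate_choices(tr))
  truth <- unclass(monkey_h_params())
  err <- abs(coef(fit) - truth)
  expect_true(all(err[c("omega_G", "omega_L", "alpha_G", "alpha_L")] < 0.1))
  expect_true(all(err[c("lambda_G", "lambda_L")] < 0.4))
})

test_that("a single distinct pair is flagged under-identified", {
  pairs <- enumerate_pairs(6)[1, , drop = FALSE]
  ds <- choice_dataset(pairs, n = 40, k = 22)
  fit <- fit_mle(ds)
  expect_false(fit$domains$gain$identified)
  expect_output(print(fit), "under-identified")
})

test_that("chunking is contiguous with the remainder spread first", {
  expect_identical(chunk_index(200, 20), rep(1:20, each = 10))
  sizes <- as.integer(table(chunk_index(205, 20)))
  expect_identical(sizes, c(rep(11L, 5), rep(10L, 15)))
  expect_error(chunk_index(10, 20), "fewer trials")
})

test_that("chunked fits scatter around the generating values", {
  tr <- risky_trials(4000, seed = 17)
  cf <- chunked_fit(tr, n_chunks = 10)
  expect_identical(nrow(cf$per_chunk), 10L)
  expect_true(all(abs(cf$per_chunk$omega_G) <= 1))
  expect_true(all(cf$per_chunk$alpha_L > 0 & cf$per_chunk$alpha_L <= 1))
  truth <- unclass(monkey_h_params())
  expect_true(all(abs(cf$mean[c("omega_G", "omega_L")] -
                        truth[c("omega_G", "omega_L")]) < 0.15))
  # mean/sd are computed over exactly the per-chunk values
  expect_equal(cf$mean,
               colMeans(as.matrix(cf$per_chunk[, names(cf$mean)])))
  expect_equal(cf$sd,
               apply(as.matrix(cf$per_chunk[, names(cf$sd)]), 2, sd))
})

test_that("fit methods expose the usual modelling interface", {
  tr <- risky_trials(2000, seed = 21)
  fit <- fit_mle(aggregate_choices(tr))
  expect_named(coef(fit), c("omega_G", "omega_L", "alpha_G", "alpha_L",
                            "lambda_G", "lambda_L"))
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_identical(attr(ll, "df"), 6L)
  p <- predict(fit)
  expect_true(all(p > 0 & p < 1))
  r <- residuals(fit)
  expect_identical(length(r), nrow(fit$dataset))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_identical(length(sims), 2L)
  expect_true(all(sims[[1]]$k <= sims[[1]]$n))
  sims_again <- simulate(fit, nsim = 2, seed = 1)
  expect_identical(sims, sims_again)
  expect_output(print(summary(fit)), "log-likelihood")
})
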