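test_that("data-level R2 is 1 for a perfect fit and matches brute force", {
  # one draw, zero residuals
  fr <- make_frame(y = c(1, 2, 3), plot = c("a", "b", "c"), period = 1)
  fit <- make_fake_fit(fr, alpha = matrix(c(1, 2, 3), 1),
                       beta = matrix(0, 1, 3), sigma_species = 1)
  expect_equal(bayesian_r2(fit, "data")$mean, 1)

  # random small posterior vs direct evaluation of 1 - V(eps)/V(y)
  set.seed(77)
  fr2 <- make_frame(y = rnorm(6, 5), plot = rep(c("a", "b", "c"), 2),
                    period = rep(1:2, each = 3))
  S <- 5
  A <- matrix(rnorm(S * 3, 5), S, 3)
  B <- matrix(rnorm(S * 3, 0, 0.5), S, 3)
  sig <- runif(S, 0.5, 2)
  fit2 <- make_fake_fit(fr2, A, B, sig)
  got <- bayesian_r2(fit2, "data")
  r2_direct <- sapply(1:S, function(s) {
    eps <- fr2$y - (A[s, fr2$j] + B[s, fr2$j] * fr2$x)
    1 - var(eps) / var(fr2$y)
  })
  expect_equal(got$mean, mean(r2_direct), tolerance = 1e-12)
  expect_equal(got$median, median(r2_direct), tolerance = 1e-12)

  # translation invariance: shifting y and alpha by a constant changes nothing
  fr3 <- make_frame(y = fr2$y + 10, plot = fr2$plot, period = fr2$period)
  fit3 <- make_fake_fit(fr3, A + 10, B, sig)
  expect_equal(bayesian_r2(fit3, "data")$mean, got$mean, tolerance = 1e-12)
})

test_that("level-2 R2 for M2 is exactly zero and brute-force exact for M3", {
  # a global mean is a constant shift within each draw -> R2 = 0
  r2a <- bayesian_r2(fit_m2_hab(), "intercepts")
  r2b <- bayesian_r2(fit_m2_hab(), "slopes")
  expect_lt(abs(r2a$mean), 1e-12)
  expect_lt(abs(r2b$mean), 1e-12)

  # M3: direct evaluation on hand-built draws
  set.seed(78)
  fr <- make_frame(y = rnorm(8, 5), plot = rep(letters[1:4], 2),
                   period = rep(1:2, each = 4),
                   habitat = rep(c("h1", "h1", "h2", "h2"), 2))
  S <- 4
  A <- matrix(rnorm(S * 4, 5), S, 4)
  B <- matrix(rnorm(S * 4), S, 4)
  MA <- matrix(rnorm(S * 2, 5), S, 2)
  MB <- matrix(rnorm(S * 2), S, 2)
  fit <- make_fake_fit(fr, A, B, rep(1, S), model = "M3",
                       mu_alpha = MA, mu_beta = MB)
  hk <- attr(fr, "habitat_of_plot")
  r2_direct <- sapply(1:S, function(s) {
    eps <- A[s, ] - MA[s, hk]
    1 - var(eps) / var(A[s, ])
  })
  expect_equal(bayesian_r2(fit, "intercepts")$mean, mean(r2_direct),
               tolerance = 1e-12)
  expect_error(bayesian_r2(fit_m1_hab(), "intercepts"), "M1")
})

test_that("pooling factor hits its complete- and no-pooling limits", {
  # complete pooling: all plots share one intercept; many plots are needed
  # for the posterior of sigma_alpha to concentrate near its true zero
  sim <- cached("survey_nopool_sd0", function() {
    simulate_survey(sim_params(
      n_habitats = 2, plots_per_habitat = 15, species_per_cell = 100,
      mu_alpha = 5, mu_beta = 0, sigma_alpha = 0, sigma_beta = 0,
      seed = 206))
  })
  f_pool <- cached("fit_m2_sd0", function() {
    suppressWarnings(fit_model(sim$frame, "M2", mcmc = test_mcmc(16)))
  })
  lam <- pooling_factor(f_pool, "intercepts")
  expect_gt(lam$lambda, 0.8)
  expect_equal(lam$lambda, 1 - lam$var_of_means / lam$mean_of_vars)

  # nearly independent estimation: huge spread, many species per plot
  sim2 <- cached("survey_spread", function() {
    simulate_survey(sim_params(
      n_habitats = 2, plots_per_habitat = 8, species_per_cell = 200,
      mu_alpha = 5, mu_beta = 0, sigma_alpha = 5, sigma_beta = 0.2,
      seed = 207))
  })
  f_ind <- cached("fit_m2_spread", function() {
    suppressWarnings(fit_model(sim2$frame, "M2", mcmc = test_mcmc(17)))
  })
  expect_lt(pooling_factor(f_ind, "intercepts")$lambda, 0.1)
  expect_error(pooling_factor(fit_m1_hab()), "pooled models")
})

test_that("habitat structure raises pooling for both levels (M3 over M2)", {
  for (lev in c("intercepts", "slopes")) {
    expect_gt(pooling_factor(fit_m3_hab(), lev)$lambda,
              pooling_factor(fit_m2_hab(), lev)$lambda)
  }
})

test_that("DIC collapses to the plug-in deviance for a degenerate posterior", {
  fr <- make_frame(y = c(4.8, 5.2, 5.1, 4.9), plot = rep(c("a", "b"), 2),
                   period = rep(1:2, each = 2))
  A <- matrix(5, 3, 2)
  B <- matrix(0.1, 3, 2)
  fit <- make_fake_fit(fr, A, B, rep(1.5, 3))
  d <- dic(fit)
  expect_equal(d$pd, 0, tolerance = 1e-10)
  expect_equal(d$dic, d$dhat, tolerance = 1e-10)
})

test_that("DIC matches a brute-force computation from raw draws", {
  set.seed(79)
  fr <- make_frame(y = rnorm(12, 5), plot = rep(c("a", "b", "c"), 4),
                   period = rep(rep(1:2, each = 3), 2))
  S <- 6
  A <- matrix(rnorm(S * 3, 5, 0.3), S, 3)
  B <- matrix(rnorm(S * 3, 0, 0.2), S, 3)
  sig <- runif(S, 1, 2)
  fit <- make_fake_fit(fr, A, B, sig)
  d <- dic(fit)
  dev <- sapply(1:S, function(s) {
    -2 * sum(dnorm(fr$y, A[s, fr$j] + B[s, fr$j] * fr$x, sig[s], log = TRUE))
  })
  dhat <- -2 * sum(dnorm(fr$y, colMeans(A)[fr$j] + colMeans(B)[fr$j] * fr$x,
                         mean(sig), log = TRUE))
  expect_equal(d$dbar, mean(dev), tolerance = 1e-8)
  expect_equal(d$pd, mean(dev) - dhat, tolerance = 1e-8)
  expect_equal(d$dic, mean(dev) + (mean(dev) - dhat), tolerance = 1e-8)
})

test_that("change tables have nested intervals and linear habitat contrasts", {
  ct <- summarize_changes(fit_m3_hab(), "plot")
  expect_equal(nrow(ct), 24)
  expect_true(all(ct$hi50 - ct$lo50 < ct$hi95 - ct$lo95))
  expect_true(all(ct$lo50 >= ct$lo95 & ct$hi50 <= ct$hi95))
  expect_equal(ct$excl0_95, ct$lo95 > 0 | ct$hi95 < 0)

  cth <- summarize_changes(fit_m3_hab(), "habitat")
  hc <- habitat_contrasts(fit_m3_hab())
  expect_equal(nrow(hc), 3)
  # draw-wise linearity: contrast mean equals difference of habitat means
  expect_equal(hc$mean[hc$unit == "hab01 - hab02"],
               cth$mean[cth$unit == "hab01"] - cth$mean[cth$unit == "hab02"],
               tolerance = 1e-12)
  expect_error(summarize_changes(fit_m2_hab(), "habitat"), "M3")
  expect_error(habitat_contrasts(fit_m2_hab()), "M3")
})

test_that("metrics row carries all summary columns for pooled models", {
  row <- metrics_row(fit_m3_hab())
  expect_equal(row$model, "M3")
  cols <- c("sigma_species", "sigma_alpha", "sigma_beta", "r2_data",
            "r2_alpha", "r2_beta", "lambda_alpha", "lambda_beta", "pd", "dic")
  expect_true(all(cols %in% names(row)))
  expect_true(all(!is.na(row[cols])))
  row1 <- metrics_row(fit_m1_hab())
  expect_true(is.na(row1$sigma_alpha) && is.na(row1$lambda_beta))
})
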