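make_raw_means <- function(df) {
  structure(df, class = c("raw_means", "data.frame"))
}

test_that("identical plot means give zero change estimates", {
  plots <- sprintf("p%02d", 1:8)
  df <- expand.grid(plot = plots, period = 1:2, stringsAsFactors = FALSE)
  df$mean <- 5
  df$n <- 10L
  des <- as_plot_design(data.frame(
    plot = plots, habitat = rep(c("heath", "dune"), each = 4)))
  fit <- fit_raw_means_model(make_raw_means(df), des)
  expect_equal(unname(fit$contrasts$estimate), c(0, 0), tolerance = 1e-10)
  expect_lt(sigma(fit$model), 1e-6)
})

test_that("balanced two-habitat design matches the two-way ANOVA solution", {
  # zero plot random-effect variance: habitat change = difference of the
  # habitat x period cell means (closed form)
  set.seed(88)
  plots <- sprintf("p%02d", 1:10)
  hab <- rep(c("heath", "dune"), each = 5)
  df <- expand.grid(plot = plots, period = 1:2, stringsAsFactors = FALSE)
  df$habitat <- hab[match(df$plot, plots)]
  df$mean <- 5 + 0.5 * (df$habitat == "dune") +
    0.3 * (df$period == 2) - 0.6 * (df$habitat == "dune") * (df$period == 2) +
    rnorm(nrow(df), 0, 0.2)
  df$n <- 20L
  des <- as_plot_design(data.frame(plot = plots, habitat = hab))
  fit <- fit_raw_means_model(make_raw_means(df[c("plot", "period", "mean", "n")]),
                             des)
  cell <- tapply(df$mean, list(df$habitat, df$period), mean)
  expected <- cell[, "2"] - cell[, "1"]
  got <- setNames(fit$contrasts$estimate, fit$contrasts$habitat)
  expect_equal(got[names(expected)], expected, tolerance = 1e-8)
})

test_that("habitat change estimates are unbiased with calibrated SEs", {
  # simulated truth (-0.4, 0, 0.4), 10 plots per habitat, 100 replicates;
  # with ~27 residual df the 2-SE nominal coverage is the t one (~94%),
  # so the floor is set at 90%
  true_change <- c(a = -0.4, b = 0, c = 0.4)
  plots <- sprintf("p%02d", 1:30)
  hab <- rep(names(true_change), each = 10)
  des <- as_plot_design(data.frame(plot = plots, habitat = hab))
  hits <- 0L
  total <- 0L
  err <- NULL
  set.seed(89)
  for (r in 1:100) {
    df <- expand.grid(plot = plots, period = 1:2, stringsAsFactors = FALSE)
    df$habitat <- hab[match(df$plot, plots)]
    plot_re <- rnorm(30, 0, 0.3)
    df$mean <- 5 + plot_re[match(df$plot, plots)] +
      true_change[df$habitat] * (df$period == 2) + rnorm(nrow(df), 0, 0.2)
    df$n <- 20L
    fit <- fit_raw_means_model(
      make_raw_means(df[c("plot", "period", "mean", "n")]), des)
    e <- fit$contrasts$estimate - true_change[fit$contrasts$habitat]
    err <- rbind(err, e)
    hits <- hits + sum(abs(e) <= 2 * fit$contrasts$se)
    total <- total + length(e)
  }
  expect_gte(hits / total, 0.90)
  # unbiasedness: mean error per habitat well under one SE
  expect_lt(max(abs(colMeans(err))), 0.03)
})

test_that("family-wise corrections widen intervals as prescribed", {
  set.seed(90)
  plots <- sprintf("p%02d", 1:28)
  hab <- rep(sprintf("h%d", 1:7), each = 4)
  des <- as_plot_design(data.frame(plot = plots, habitat = hab))
  df <- expand.grid(plot = plots, period = 1:2, stringsAsFactors = FALSE)
  df$mean <- 5 + rnorm(nrow(df), 0, 0.3)
  df$n <- 15L
  fit <- fit_raw_means_model(make_raw_means(df), des)

  # Bonferroni with K = 7 uses the alpha/7 normal quantile, by hand
  bon <- corrected_contrasts(fit, alpha = 0.05, method = "bonferroni")
  crit <- qnorm(1 - 0.05 / (2 * 7))
  expect_equal(bon$hi_adj - bon$lo_adj, 2 * crit * bon$se, tolerance = 1e-10)

  # adjusted intervals are at least as wide as unadjusted, for all methods
  for (m in c("single-step", "bonferroni", "none")) {
    cc <- corrected_contrasts(fit, method = m)
    expect_true(all(cc$hi_adj - cc$lo_adj >= cc$hi - cc$lo - 1e-12))
  }
  # single-step lies between unadjusted and Bonferroni
  ss <- corrected_contrasts(fit, method = "single-step")
  expect_lte(attr(ss, "crit")[["adjusted"]], crit + 1e-6)
  expect_error(corrected_contrasts(fit, method = "tukey"), "arg")
})

test_that("a single contrast needs no adjustment", {
  fit <- list(contrasts = data.frame(habitat = "h1", estimate = 0.5,
                                     se = 0.1),
              vcov = matrix(0.01), dropped = character(0), random = "plot")
  class(fit) <- "baseline_fit"
  cc <- corrected_contrasts(fit, method = "single-step")
  expect_equal(cc$lo_adj, cc$lo)
  expect_equal(cc$hi_adj, cc$hi)
})

test_that("single-step critical value agrees with multcomp", {
  set.seed(91)
  plots <- sprintf("p%02d", 1:20)
  hab <- rep(sprintf("h%d", 1:5), each = 4)
  des <- as_plot_design(data.frame(plot = plots, habitat = hab))
  df <- expand.grid(plot = plots, period = 1:2, stringsAsFactors = FALSE)
  df$mean <- 5 + 0.2 * (df$period == 2) + rnorm(nrow(df), 0, 0.3)
  df$n <- 15L
  fit <- fit_raw_means_model(make_raw_means(df), des)
  ss <- corrected_contrasts(fit, method = "single-step")

  fe <- lme4::fixef(fit$model)
  C <- matrix(0, 5, length(fe), dimnames = list(NULL, names(fe)))
  C[, "periodf2"] <- 1
  for (i in 2:5) C[i, paste0("habitath", i, ":periodf2")] <- 1
  g <- multcomp::glht(fit$model, linfct = C)
  ci <- confint(g, level = 0.95)
  expect_equal(unname(ci$confint[, "Estimate"]), ss$estimate,
               tolerance = 1e-8)
  # same single-step quantile up to quasi-MC error
  mc_crit <- attr(ci$confint, "calpha")
  expect_equal(attr(ss, "crit")[["adjusted"]], mc_crit, tolerance = 0.02)
})

test_that("habitats observed in a single period are dropped with a warning", {
  plots <- sprintf("p%02d", 1:9)
  hab <- rep(c("a", "b", "c"), each = 3)
  des <- as_plot_design(data.frame(plot = plots, habitat = hab))
  df <- expand.grid(plot = plots, period = 1:2, stringsAsFactors = FALSE)
  df$mean <- 5 + rnorm(nrow(df), 0, 0.2)
  df$n <- 10L
  df <- df[!(df$plot %in% plots[7:9] & df$period == 2), ]
  expect_warning(fit <- fit_raw_means_model(make_raw_means(df), des), "c")
  expect_equal(fit$dropped, "c")
  expect_equal(sort(fit$contrasts$habitat), c("a", "b"))
})
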