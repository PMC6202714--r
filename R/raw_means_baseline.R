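#' Mixed model on raw plot-mean scores
#'
#' The conventional comparison method: takes the per-(plot, period) raw mean
#' indicator scores as data (each plot mean weighted equally regardless of
#' how many species it averages), and fits a normal-response mixed model
#' `mean ~ habitat * period + (1 | plot)` by REML. Per-habitat
#' between-period change estimates are derived from the fixed effects.
#'
#' @param raw a `raw_means` table from [plot_raw_means()].
#' @param design a `plot_design` supplying habitat labels.
#' @param random random-effect structure: `"plot"` (default; a crossed plot
#'   intercept, accounting for the same plot being sampled in both periods)
#'   or `"plot_by_period"` (independent plot effects per period; with one
#'   raw mean per (plot, period) cell this variance is confounded with the
#'   residual, so lme4's observation-count check is relaxed — provided for
#'   comparability only).
#' @return a `baseline_fit`: list with `model` (the `lmerMod`), `contrasts`
#'   (data frame `habitat`, `estimate`, `se`), `vcov` (covariance of the
#'   contrast estimates), `dropped` (habitats without both periods).
#' @export
fit_raw_means_model <- function(raw, design,
                                random = c("plot", "plot_by_period")) {
  random <- match.arg(random)
  dat <- as.data.frame(raw)
  dat$habitat <- design$habitat[match(dat$plot, design$plot)]
  if (anyNA(dat$habitat)) {
    stop("plot(s) in raw means but absent from design: ",
         paste(unique(dat$plot[is.na(dat$habitat)]), collapse = ", "))
  }
  if (length(unique(dat$habitat)) < 2) stop("need >= 2 habitats")
  if (!all(c(1, 2) %in% dat$period)) stop("need both periods")

  # habitats represented in only one period have no estimable change
  per_hab <- table(dat$habitat, dat$period)
  dropped <- rownames(per_hab)[rowSums(per_hab > 0) < 2]
  if (length(dropped)) {
    warning("habitat(s) with plots in only one period dropped from ",
            "contrasts: ", paste(dropped, collapse = ", "))
    dat <- dat[!dat$habitat %in% dropped, , drop = FALSE]
  }
  dat$habitat <- factor(dat$habitat)
  dat$periodf <- factor(dat$period, levels = c(1, 2))
  dat$plotf <- factor(dat$plot)

  form <- if (random == "plot") {
    mean ~ habitat * periodf + (1 | plotf)
  } else {
    mean ~ habitat * periodf + (1 | periodf:plotf)
  }
  ctrl <- if (random == "plot_by_period") {
    lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                      check.nobs.vs.nRE = "ignore",
                      calc.derivs = FALSE)
  } else {
    lme4::lmerControl(calc.derivs = FALSE)
  }
  mod <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = dat, REML = TRUE, control = ctrl)))

  # contrast matrix: change in habitat k = period2 effect (+ interaction)
  fe <- lme4::fixef(mod)
  habs <- levels(dat$habitat)
  C <- matrix(0, length(habs), length(fe),
              dimnames = list(habs, names(fe)))
  C[, "periodf2"] <- 1
  for (h in habs[-1]) {
    nm <- paste0("habitat", h, ":periodf2")
    if (nm %in% names(fe)) C[h, nm] <- 1
  }
  est <- drop(C %*% fe)
  Vfe <- tryCatch(suppressWarnings(as.matrix(stats::vcov(mod))),
                  error = function(e) NULL)
  if (is.null(Vfe) || anyNA(Vfe)) {
    # degenerate fit (zero residual variance): no sampling variance
    Vfe <- matrix(0, length(fe), length(fe),
                  dimnames = list(names(fe), names(fe)))
  }
  V <- C %*% Vfe %*% t(C)
  structure(list(
    model = mod,
    contrasts = data.frame(habitat = habs, estimate = unname(est),
                           se = sqrt(pmax(diag(V), 0)),
                           stringsAsFactors = FALSE),
    vcov = V,
    dropped = dropped,
    random = random), class = "baseline_fit")
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("baseline_fit: %d habitat change contrasts (random = %s)\n",
              nrow(x$contrasts), x$random))
  print(x$contrasts)
  invisible(x)
}

#' Family-wise corrected habitat-change intervals
#'
#' Simultaneous confidence intervals over the K habitat-change contrasts of
#' a [fit_raw_means_model()] fit. `"single-step"` uses the max-|z| quantile
#' of the multivariate normal with the contrasts' correlation matrix (the
#' standard single-step adjustment); `"bonferroni"` uses the normal
#' `alpha / K` quantile; `"none"` returns unadjusted intervals.
#'
#' @param fit a `baseline_fit`.
#' @param alpha family-wise error level.
#' @param method `"single-step"`, `"bonferroni"` or `"none"`.
#' @return data frame: `habitat`, `estimate`, `se`, `lo`, `hi` (unadjusted
#'   1-alpha interval), `lo_adj`, `hi_adj` (family-wise adjusted), `reject`
#'   (adjusted interval excludes zero); attribute `crit` holds the two
#'   critical values.
#' @export
corrected_contrasts <- function(fit, alpha = 0.05,
                                method = c("single-step", "bonferroni",
                                           "none")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "baseline_fit"), alpha > 0, alpha < 1)
  K <- nrow(fit$contrasts)
  crit0 <- stats::qnorm(1 - alpha / 2)
  crit <- switch(method,
    none = crit0,
    bonferroni = stats::qnorm(1 - alpha / (2 * K)),
    "single-step" = {
      if (K == 1 || any(diag(fit$vcov) <= 0)) crit0 else {
        R <- stats::cov2cor(fit$vcov)
        # deterministic quasi-MC quantile; restore the caller's RNG state
        rng <- if (exists(".Random.seed", globalenv())) {
          get(".Random.seed", globalenv())
        }
        set.seed(20260101)
        q <- mvtnorm::qmvnorm(1 - alpha, tail = "both.tails", corr = R,
                              ptol = 1e-5)$quantile
        if (!is.null(rng)) assign(".Random.seed", rng, globalenv())
        max(q, crit0)
      }
    })
  out <- fit$contrasts
  out$lo <- out$estimate - crit0 * out$se
  out$hi <- out$estimate + crit0 * out$se
  out$lo_adj <- out$estimate - crit * out$se
  out$hi_adj <- out$estimate + crit * out$se
  out$reject <- out$lo_adj > 0 | out$hi_adj < 0
  attr(out, "crit") <- c(unadjusted = crit0, adjusted = crit)
  attr(out, "method") <- method
  out
}
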