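#' Summarize a vector of posterior draws
#'
#' @param x numeric vector of draws.
#' @return a `posterior_summary` list: `mean`, `median`, `lo50`, `hi50`
#'   (central 50% interval) and `lo95`, `hi95` (central 95% interval).
#' @export
posterior_summary <- function(x) {
  q <- stats::quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
  structure(list(mean = mean(x), median = q[3],
                 lo50 = q[2], hi50 = q[4], lo95 = q[1], hi95 = q[5]),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("mean %.4f, median %.4f, 50%% [%.4f, %.4f], 95%% [%.4f, %.4f]\n",
              x$mean, x$median, x$lo50, x$hi50, x$lo95, x$hi95))
  invisible(x)
}

# Level-2 errors: alpha_j (or beta_j) minus its modeled mean (global for M2,
# habitat-specific for M3). Returns list(theta = draws x J, eps = draws x J).
level2_errors <- function(fit, level) {
  what <- if (level == "intercepts") "alpha" else "beta"
  theta <- draw_cols(fit, what)
  mu <- draw_cols(fit, if (level == "intercepts") "mu_alpha" else "mu_beta")
  if (fit$model == "M2") {
    eps <- theta - mu[, 1]
  } else {
    hk <- attr(fit$frame, "habitat_of_plot")
    eps <- theta - mu[, hk, drop = FALSE]
  }
  list(theta = theta, eps = eps)
}

#' Per-level Bayesian R-squared
#'
#' Explained variance at one level of the hierarchy, computed per posterior
#' draw as `1 - V(errors) / V(values)` with V the finite-sample variance
#' across units, then summarized over draws.
#' \describe{
#'   \item{data}{errors `y_i - (alpha_j[i] + beta_j[i] x_i)` against the
#'     observed `y_i`.}
#'   \item{intercepts}{errors `alpha_j - mu_alpha` (M2) or
#'     `alpha_j - mu_alpha[k[j]]` (M3) against the `alpha_j`.}
#'   \item{slopes}{analogous with `beta`.}
#' }
#' For M2 the level-2 values differ from their errors by a constant shift
#' within each draw, so the intercept/slope R-squared is exactly zero:
#' a single global mean explains none of the between-plot variance.
#'
#' @param fit an `eiv_fit`.
#' @param level `"data"`, `"intercepts"` or `"slopes"` (levels other than
#'   `"data"` need a pooled model, M2 or M3).
#' @param frame model frame (defaults to the fitted one); used at the data
#'   level only.
#' @return a `posterior_summary` of the per-draw R-squared.
#' @export
bayesian_r2 <- function(fit, level = c("data", "intercepts", "slopes"),
                        frame = fit$frame) {
  level <- match.arg(level)
  stopifnot(inherits(fit, "eiv_fit"))
  if (level == "data") {
    A <- draw_cols(fit, "alpha")
    B <- draw_cols(fit, "beta")
    S <- nrow(A)
    n <- nrow(frame)
    fitted <- A[, frame$j, drop = FALSE] +
      B[, frame$j, drop = FALSE] * matrix(frame$x, S, n, byrow = TRUE)
    eps <- matrix(frame$y, S, n, byrow = TRUE) - fitted
    vy <- stats::var(frame$y)
    r2 <- 1 - apply(eps, 1, stats::var) / vy
  } else {
    if (fit$model == "M1") {
      stop("level-2 R-squared needs a pooled model (M2 or M3); fit is M1")
    }
    le <- level2_errors(fit, level)
    r2 <- 1 - apply(le$eps, 1, stats::var) / apply(le$theta, 1, stats::var)
  }
  posterior_summary(r2)
}

#' Gelman-Pardoe pooling factor
#'
#' Degree of pooling of the level-2 parameters toward their modeled mean:
#' `lambda = 1 - V_j(E_s[eps_j]) / E_s[V_j(eps_j)]`, with `eps_j` the
#' level-2 errors as in [bayesian_r2()], `E_s` the posterior expectation and
#' `V_j` the finite-sample variance across plots. Values near 1 indicate
#' complete pooling (posterior-mean errors are much less variable than the
#' errors themselves); values near 0 indicate that each plot's error is
#' estimated essentially independently.
#'
#' @param fit an `eiv_fit` for model M2 or M3.
#' @param level `"intercepts"` or `"slopes"`.
#' @return a `pooling_factor` list: `lambda`, plus the two variance
#'   components `var_of_means` and `mean_of_vars`.
#' @export
pooling_factor <- function(fit, level = c("intercepts", "slopes")) {
  level <- match.arg(level)
  stopifnot(inherits(fit, "eiv_fit"))
  if (fit$model == "M1") {
    stop("pooling factors are defined for pooled models (M2 or M3) only")
  }
  le <- level2_errors(fit, level)
  var_of_means <- stats::var(colMeans(le$eps))
  mean_of_vars <- mean(apply(le$eps, 1, stats::var))
  lambda <- 1 - var_of_means / mean_of_vars
  if (lambda < -0.05 || lambda > 1.05) {
    warning(sprintf("pooling factor %.3f outside [0, 1] beyond MC noise",
                    lambda))
  }
  structure(list(lambda = lambda, var_of_means = var_of_means,
                 mean_of_vars = mean_of_vars, level = level),
            class = "pooling_factor")
}

#' @export
print.pooling_factor <- function(x, ...) {
  cat(sprintf("pooling factor (%s): lambda = %.3f\n", x$level, x$lambda))
  invisible(x)
}

#' Deviance information criterion
#'
#' Classic Spiegelhalter DIC with the posterior-mean plug-in:
#' `D(theta) = -2 sum_i log p(y_i | theta)`, `pD = Dbar - D(theta_bar)`,
#' `DIC = Dbar + pD`, where `theta_bar` takes the posterior mean of every
#' `alpha_j`, `beta_j` and of `sigma_species`.
#'
#' @param fit an `eiv_fit`.
#' @param frame model frame (defaults to the fitted one).
#' @return a `dic_result` list: `dic`, `pd`, `dbar`, `dhat`, `model`.
#' @export
dic <- function(fit, frame = fit$frame) {
  lp <- pointwise_log_density(fit, frame)
  dev <- -2 * rowSums(lp)
  dbar <- mean(dev)
  abar <- colMeans(draw_cols(fit, "alpha"))
  bbar <- colMeans(draw_cols(fit, "beta"))
  sbar <- mean(fit$draws[, "sigma_species"])
  mu_hat <- abar[frame$j] + bbar[frame$j] * frame$x
  dhat <- -2 * sum(stats::dnorm(frame$y, mu_hat, sbar, log = TRUE))
  pd <- dbar - dhat
  structure(list(dic = dbar + pd, pd = pd, dbar = dbar, dhat = dhat,
                 model = fit$model), class = "dic_result")
}

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf("%s: DIC %.1f (pD %.1f, Dbar %.1f)\n",
              x$model, x$dic, x$pd, x$dbar))
  invisible(x)
}

#' Compare models by DIC
#'
#' @param ... `eiv_fit` objects (or a single list of them), all fitted to
#'   the same model frame.
#' @return data frame with one row per model: `model`, `pd`, `dic`,
#'   `delta_dic` relative to the smallest DIC.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1]], "eiv_fit")) {
    fits <- fits[[1]]
  }
  rows <- lapply(fits, function(f) {
    d <- dic(f)
    data.frame(model = d$model, pd = d$pd, dic = d$dic,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$delta_dic <- out$dic - min(out$dic)
  out[order(out$dic), , drop = FALSE]
}

#' Summarize between-period changes per plot or habitat
#'
#' Plot level: posterior summaries of the varying slopes `beta_j` (the
#' change in mean indicator score between periods for plot j). Habitat
#' level (M3 only): summaries of the habitat slope means `mu_beta[k]`.
#' Because pooled estimates share information, no multiplicity adjustment
#' is applied.
#'
#' @param fit an `eiv_fit`.
#' @param level `"plot"` or `"habitat"`.
#' @return a `change_table` data frame: `unit`, `mean`, `median`, `lo50`,
#'   `hi50`, `lo95`, `hi95`, and flags `excl0_50`, `excl0_95` marking
#'   intervals that exclude zero.
#' @export
summarize_changes <- function(fit, level = c("plot", "habitat")) {
  level <- match.arg(level)
  stopifnot(inherits(fit, "eiv_fit"))
  if (level == "habitat") {
    if (fit$model != "M3") {
      stop("habitat-level changes need model M3; fit is ", fit$model)
    }
    theta <- draw_cols(fit, "mu_beta")
    units <- attr(fit$frame, "habitat_levels")
  } else {
    theta <- draw_cols(fit, "beta")
    units <- attr(fit$frame, "plot_levels")
  }
  rows <- lapply(seq_along(units), function(u) {
    s <- posterior_summary(theta[, u])
    data.frame(unit = units[u], mean = s$mean, median = s$median,
               lo50 = s$lo50, hi50 = s$hi50, lo95 = s$lo95, hi95 = s$hi95,
               excl0_50 = s$lo50 > 0 | s$hi50 < 0,
               excl0_95 = s$lo95 > 0 | s$hi95 < 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "level") <- level
  class(out) <- c("change_table", "data.frame")
  out
}

#' Pairwise habitat contrasts of between-period change
#'
#' Draw-wise differences `mu_beta[k1] - mu_beta[k2]` for every habitat pair
#' under M3, summarized as posterior intervals (no multiplicity adjustment,
#' as the estimates are pooled).
#'
#' @param fit an `eiv_fit` for model M3.
#' @return a `change_table`-style data frame with `unit` = "k1 - k2".
#' @export
habitat_contrasts <- function(fit) {
  stopifnot(inherits(fit, "eiv_fit"))
  if (fit$model != "M3") stop("habitat contrasts need model M3")
  mu <- draw_cols(fit, "mu_beta")
  habs <- attr(fit$frame, "habitat_levels")
  pairs <- utils::combn(seq_along(habs), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    k1 <- pairs[1, p]; k2 <- pairs[2, p]
    s <- posterior_summary(mu[, k1] - mu[, k2])
    data.frame(unit = paste(habs[k1], "-", habs[k2]),
               mean = s$mean, median = s$median,
               lo50 = s$lo50, hi50 = s$hi50, lo95 = s$lo95, hi95 = s$hi95,
               excl0_50 = s$lo50 > 0 | s$hi50 < 0,
               excl0_95 = s$lo95 > 0 | s$hi95 < 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "level") <- "habitat_contrast"
  class(out) <- c("change_table", "data.frame")
  out
}

#' One-row model summary in the layout of the results table
#'
#' Collects, for one fit, the residual sds, the per-level Bayesian
#' R-squared, the pooling factors, pD and DIC (posterior means throughout;
#' entries undefined for the model are NA).
#'
#' @param fit an `eiv_fit`.
#' @return one-row data frame with columns `model`, `index`,
#'   `sigma_species`, `sigma_alpha`, `sigma_beta`, `r2_data`, `r2_alpha`,
#'   `r2_beta`, `lambda_alpha`, `lambda_beta`, `pd`, `dic`.
#' @export
metrics_row <- function(fit) {
  stopifnot(inherits(fit, "eiv_fit"))
  pooled <- fit$model %in% c("M2", "M3")
  d <- dic(fit)
  data.frame(
    model = fit$model,
    index = attr(fit$frame, "index"),
    sigma_species = mean(fit$draws[, "sigma_species"]),
    sigma_alpha = if (pooled) mean(fit$draws[, "sigma_alpha"]) else NA_real_,
    sigma_beta = if (pooled) mean(fit$draws[, "sigma_beta"]) else NA_real_,
    r2_data = bayesian_r2(fit, "data")$mean,
    r2_alpha = if (pooled) bayesian_r2(fit, "intercepts")$mean else NA_real_,
    r2_beta = if (pooled) bayesian_r2(fit, "slopes")$mean else NA_real_,
    lambda_alpha = if (pooled) pooling_factor(fit, "intercepts")$lambda
                   else NA_real_,
    lambda_beta = if (pooled) pooling_factor(fit, "slopes")$lambda
                  else NA_real_,
    pd = d$pd,
    dic = d$dic,
    stringsAsFactors = FALSE)
}
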