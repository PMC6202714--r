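#' Prior configuration for the hierarchical models
#'
#' Minimally informative defaults: wide normal priors on all location
#' parameters, uniform priors on the standard deviations, and a uniform
#' prior on the intercept-slope correlation.
#'
#' @param location_sd sd of the Normal(0, sd) priors on location parameters
#'   (`alpha_j`, `beta_j` in M1; `mu_alpha`, `mu_beta` in M2;
#'   `mu_alpha[k]`, `mu_beta[k]` in M3).
#' @param sigma_upper upper bound of the Uniform(0, upper) priors on
#'   `sigma_species`, `sigma_alpha`, `sigma_beta`.
#' @param rho_bounds support of the uniform prior on the correlation `rho`.
#' @return a `prior_config` list.
#' @export
prior_config <- function(location_sd = 100, sigma_upper = 100,
                         rho_bounds = c(-1, 1)) {
  stopifnot(location_sd > 0, sigma_upper > 0,
            length(rho_bounds) == 2, rho_bounds[1] < rho_bounds[2],
            rho_bounds[1] >= -1, rho_bounds[2] <= 1)
  structure(list(location_sd = location_sd, sigma_upper = sigma_upper,
                 rho_bounds = rho_bounds),
            class = "prior_config")
}

#' MCMC configuration
#'
#' @param chains number of chains (>= 2 for convergence diagnostics).
#' @param warmup adaptation + burn-in iterations per chain.
#' @param iter retained iterations per chain.
#' @param thin thinning interval.
#' @param seed integer seed; chain RNGs are derived from it, so identical
#'   configurations give identical draws.
#' @return an `mcmc_config` list.
#' @export
mcmc_config <- function(chains = 4, warmup = 1000, iter = 1000, thin = 1,
                        seed = 1) {
  stopifnot(chains >= 1, warmup >= 0, iter >= 1, thin >= 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

# JAGS model definitions. The bivariate normal prior on (alpha_j, beta_j) is
# written as its exact conditional factorization so the covariance is
# parameterized directly by (sigma_alpha, sigma_beta, rho).
jags_model_string <- function(model) {
  data_level <- "
  for (i in 1:n) {
    y[i] ~ dnorm(alpha[plot[i]] + beta[plot[i]] * x[i], tau_y)
  }
  sigma_species ~ dunif(0, sigma_upper)
  tau_y <- pow(sigma_species, -2)"
  switch(model,
    M1 = paste0("model {", data_level, "
  for (j in 1:J) {
    alpha[j] ~ dnorm(0, loc_prec)
    beta[j] ~ dnorm(0, loc_prec)
  }
}"),
    M2 = paste0("model {", data_level, "
  for (j in 1:J) {
    alpha[j] ~ dnorm(mu_alpha, tau_a)
    beta[j] ~ dnorm(mu_beta + rho * (sigma_beta / sigma_alpha) *
                      (alpha[j] - mu_alpha), tau_b_cond)
  }
  mu_alpha ~ dnorm(0, loc_prec)
  mu_beta ~ dnorm(0, loc_prec)
  sigma_alpha ~ dunif(0, sigma_upper)
  sigma_beta ~ dunif(0, sigma_upper)
  rho ~ dunif(rho_lo, rho_hi)
  tau_a <- pow(sigma_alpha, -2)
  tau_b_cond <- 1 / ((1 - rho^2) * pow(sigma_beta, 2))
}"),
    M3 = paste0("model {", data_level, "
  for (j in 1:J) {
    alpha[j] ~ dnorm(mu_alpha[hab[j]], tau_a)
    beta[j] ~ dnorm(mu_beta[hab[j]] + rho * (sigma_beta / sigma_alpha) *
                      (alpha[j] - mu_alpha[hab[j]]), tau_b_cond)
  }
  for (k in 1:K) {
    mu_alpha[k] ~ dnorm(0, loc_prec)
    mu_beta[k] ~ dnorm(0, loc_prec)
  }
  sigma_alpha ~ dunif(0, sigma_upper)
  sigma_beta ~ dunif(0, sigma_upper)
  rho ~ dunif(rho_lo, rho_hi)
  tau_a <- pow(sigma_alpha, -2)
  tau_b_cond <- 1 / ((1 - rho^2) * pow(sigma_beta, 2))
}"),
    stop("unknown model: ", model))
}

# Data-derived starting values: raw per-plot means/differences, overall
# fallbacks for plots seen in only one period.
jags_inits <- function(frame, model) {
  J <- length(attr(frame, "plot_levels"))
  ybar <- mean(frame$y)
  a0 <- rep(ybar, J)
  b0 <- rep(0, J)
  m1 <- tapply(frame$y[frame$x == 0], frame$j[frame$x == 0], mean)
  m2 <- tapply(frame$y[frame$x == 1], frame$j[frame$x == 1], mean)
  a0[as.integer(names(m1))] <- m1
  both <- intersect(names(m1), names(m2))
  b0[as.integer(both)] <- m2[both] - m1[both]
  sy <- max(stats::sd(frame$y), 0.1)
  inits <- list(alpha = a0, beta = b0, sigma_species = sy)
  if (model %in% c("M2", "M3")) {
    inits$sigma_alpha <- max(stats::sd(a0), 0.1)
    inits$sigma_beta <- max(stats::sd(b0), 0.1)
    inits$rho <- 0
    if (model == "M2") {
      inits$mu_alpha <- mean(a0)
      inits$mu_beta <- mean(b0)
    } else {
      hk <- attr(frame, "habitat_of_plot")
      K <- length(attr(frame, "habitat_levels"))
      inits$mu_alpha <- as.numeric(tapply(a0, factor(hk, levels = 1:K), mean))
      inits$mu_beta <- as.numeric(tapply(b0, factor(hk, levels = 1:K), mean))
    }
  }
  inits
}

#' Fit a hierarchical indicator-value model by MCMC
#'
#' Fits one of three nested models to a long-format `model_frame`:
#' \describe{
#'   \item{M1 (no pooling)}{`y_i ~ N(alpha_j[i] + beta_j[i] x_i,
#'     sigma_species)` with independent wide priors on every `alpha_j`,
#'     `beta_j`; each plot is estimated on its own.}
#'   \item{M2 (partial pooling)}{as M1, but `(alpha_j, beta_j)` drawn from a
#'     bivariate normal with means `(mu_alpha, mu_beta)`, sds
#'     `(sigma_alpha, sigma_beta)` and correlation `rho`.}
#'   \item{M3 (partial pooling + group-level predictor)}{as M2, but the
#'     bivariate-normal means take a separate value `(mu_alpha[k],
#'     mu_beta[k])` for each habitat k.}
#' }
#' `x` is the 0/1 period indicator, so `alpha_j` is the period-1 plot mean
#' and `beta_j` the between-period change for plot j.
#'
#' @param frame a `model_frame`.
#' @param model `"M1"`, `"M2"` or `"M3"`.
#' @param priors a [prior_config()].
#' @param mcmc an [mcmc_config()].
#' @param quiet suppress JAGS progress output.
#' @return an `eiv_fit`: list with elements `model`, `draws` (matrix, one
#'   column per parameter: `alpha[j]`, `beta[j]`, `sigma_species`, and for
#'   M2/M3 `mu_alpha(\[k\])`, `mu_beta(\[k\])`, `sigma_alpha`, `sigma_beta`,
#'   `rho`), `chain` and `iteration` vectors aligned with the draw rows,
#'   `samples` (the underlying `coda::mcmc.list`), `frame`, `priors`,
#'   `mcmc`, `seed` and `warnings`.
#' @export
fit_model <- function(frame, model = c("M2", "M1", "M3"),
                      priors = prior_config(), mcmc = mcmc_config(),
                      quiet = TRUE) {
  model <- match.arg(model)
  stopifnot(inherits(frame, "model_frame"))
  J <- length(attr(frame, "plot_levels"))
  K <- length(attr(frame, "habitat_levels"))
  if (model == "M3" && K < 2) {
    stop("M3 needs at least 2 habitats; frame has ", K)
  }
  warn <- character(0)
  period_tab <- table(factor(frame$j, levels = 1:J),
                      factor(frame$period, levels = 1:2))
  one_period <- which(rowSums(period_tab > 0) < 2)
  if (length(one_period) && model == "M1") {
    warn <- c(warn, paste0(
      "plot(s) observed in one period only under M1; their missing-period ",
      "parameter is informed only by its prior: ",
      paste(attr(frame, "plot_levels")[one_period], collapse = ", ")))
    warning(warn[length(warn)])
  }

  jd <- list(y = frame$y, x = frame$x, plot = frame$j, n = nrow(frame),
             J = J, loc_prec = 1 / priors$location_sd^2,
             sigma_upper = priors$sigma_upper)
  if (model %in% c("M2", "M3")) {
    jd$rho_lo <- priors$rho_bounds[1]
    jd$rho_hi <- priors$rho_bounds[2]
  }
  if (model == "M3") {
    jd$hab <- attr(frame, "habitat_of_plot")
    jd$K <- K
  }
  base_inits <- jags_inits(frame, model)
  inits <- lapply(seq_len(mcmc$chains), function(ch) {
    c(base_inits,
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = (abs(mcmc$seed) %% 1000003L) * 1000L + ch))
  })
  monitors <- switch(model,
    M1 = c("alpha", "beta", "sigma_species"),
    c("alpha", "beta", "sigma_species", "mu_alpha", "mu_beta",
      "sigma_alpha", "sigma_beta", "rho"))

  n_adapt <- min(mcmc$warmup, 500L)
  n_burn <- mcmc$warmup - n_adapt
  jm <- rjags::jags.model(textConnection(jags_model_string(model)),
                          data = jd, inits = inits,
                          n.chains = mcmc$chains, n.adapt = n_adapt,
                          quiet = quiet)
  if (n_burn > 0) update(jm, n_burn, progress.bar = "none")
  samples <- rjags::coda.samples(jm, monitors, n.iter = mcmc$iter * mcmc$thin,
                                 thin = mcmc$thin, progress.bar = "none")
  draws <- do.call(rbind, lapply(samples, as.matrix))
  per_chain <- nrow(draws) / mcmc$chains
  fit <- structure(list(
    model = model,
    draws = draws,
    chain = rep(seq_len(mcmc$chains), each = per_chain),
    iteration = rep(seq_len(per_chain), times = mcmc$chains),
    samples = samples,
    frame = frame,
    priors = priors,
    mcmc = mcmc,
    seed = mcmc$seed,
    warnings = warn), class = "eiv_fit")
  conv <- tryCatch(check_convergence(fit), error = function(e) NULL)
  if (!is.null(conv) && !attr(conv, "pass")) {
    fit$warnings <- c(fit$warnings, sprintf(
      "convergence check failed (max R-hat %.3f, min ESS %.0f)",
      max(conv$rhat, na.rm = TRUE), min(conv$ess, na.rm = TRUE)))
    warning(fit$warnings[length(fit$warnings)])
  }
  fit$convergence <- conv
  fit
}

#' @export
print.eiv_fit <- function(x, ...) {
  cat(sprintf("eiv_fit: model %s, %d draws (%d chains), %d plots, index %s\n",
              x$model, nrow(x$draws), x$mcmc$chains,
              length(attr(x$frame, "plot_levels")), attr(x$frame, "index")))
  sig <- posterior_summary(x$draws[, "sigma_species"])
  cat(sprintf("  sigma_species: %.3f [%.3f, %.3f]\n",
              sig$mean, sig$lo95, sig$hi95))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

# Column helpers on the draw matrix.
draw_cols <- function(fit, what) {
  cols <- colnames(fit$draws)
  switch(what,
    alpha = fit$draws[, grep("^alpha(\\[|$)", cols), drop = FALSE],
    beta = fit$draws[, grep("^beta(\\[|$)", cols), drop = FALSE],
    mu_alpha = fit$draws[, grep("^mu_alpha(\\[|$)", cols), drop = FALSE],
    mu_beta = fit$draws[, grep("^mu_beta(\\[|$)", cols), drop = FALSE],
    stop("unknown parameter block: ", what))
}

#' Split-chain R-hat and effective sample size
#'
#' Potential scale reduction computed after splitting each chain in half
#' (so within-chain drift inflates R-hat), plus coda's
#' autocorrelation-based effective sample size, for every monitored
#' parameter.
#'
#' @param fit an `eiv_fit` (or a `coda::mcmc.list`) with >= 2 chains.
#' @param rhat_threshold pass threshold for R-hat.
#' @param ess_threshold pass threshold for ESS.
#' @return a `convergence_report` data frame with columns `parameter`,
#'   `rhat`, `ess`; attribute `pass` is TRUE when every parameter meets both
#'   thresholds.
#' @export
check_convergence <- function(fit, rhat_threshold = 1.1,
                              ess_threshold = 100) {
  samples <- if (inherits(fit, "eiv_fit")) fit$samples else fit
  if (!inherits(samples, "mcmc.list")) {
    stop("need an eiv_fit or a coda::mcmc.list")
  }
  if (length(samples) < 2) {
    stop("convergence diagnostics need >= 2 chains; rerun with chains >= 2")
  }
  mats <- lapply(samples, as.matrix)
  params <- colnames(mats[[1]])
  rhat <- vapply(params, function(p) {
    split_rhat(lapply(mats, function(m) m[, p]))
  }, numeric(1))
  ess <- coda::effectiveSize(samples)[params]
  out <- data.frame(parameter = params, rhat = unname(rhat),
                    ess = unname(ess), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "pass") <- all(out$rhat < rhat_threshold, na.rm = TRUE) &&
    all(out$ess >= ess_threshold, na.rm = TRUE)
  attr(out, "thresholds") <- c(rhat = rhat_threshold, ess = ess_threshold)
  class(out) <- c("convergence_report", "data.frame")
  out
}

# Split R-hat (potential scale reduction on half-chains).
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(ch) {
    n <- length(ch) %/% 2
    if (n < 2) return(list(ch))
    list(ch[1:n], ch[(n + 1):(2 * n)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Pointwise log-density matrix
#'
#' Normal log density of each observation under each retained draw:
#' entry (s, i) is `log N(y_i | alpha_j[i]^(s) + beta_j[i]^(s) x_i,
#' sigma_species^(s))`. Row sums give each draw's total log-likelihood;
#' the matrix feeds [dic()].
#'
#' @param fit an `eiv_fit`.
#' @param frame the `model_frame` the fit was computed on (defaults to the
#'   frame stored in the fit).
#' @return numeric matrix, draws x observations.
#' @export
pointwise_log_density <- function(fit, frame = fit$frame) {
  stopifnot(inherits(fit, "eiv_fit"))
  A <- draw_cols(fit, "alpha")
  B <- draw_cols(fit, "beta")
  if (length(attr(frame, "plot_levels")) != ncol(A) ||
      !identical(attr(frame, "plot_levels"),
                 attr(fit$frame, "plot_levels"))) {
    stop("frame does not match the fitted model frame")
  }
  S <- nrow(A)
  n <- nrow(frame)
  jj <- frame$j
  mu <- A[, jj, drop = FALSE] +
    B[, jj, drop = FALSE] * matrix(frame$x, S, n, byrow = TRUE)
  stats::dnorm(matrix(frame$y, S, n, byrow = TRUE), mu,
               matrix(fit$draws[, "sigma_species"], S, n), log = TRUE)
}
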