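#' Parameters for a synthetic resurvey
#'
#' Defines the generative side of the group-level model: per habitat k, the
#' plot intercept/slope pairs `(alpha_j, beta_j)` are drawn from a bivariate
#' normal with means `(mu_alpha[k], mu_beta[k])`, sds
#' `(sigma_alpha, sigma_beta)` and correlation `rho`; species scores are
#' drawn around the plot mean with sd `sigma_species`. Defaults mirror the
#' variance magnitudes typical of indicator-value surveys: within-plot
#' spread much larger than between-plot or between-period spread.
#'
#' @param n_habitats number of habitats K.
#' @param plots_per_habitat plots per habitat (scalar or length-K vector).
#' @param species_per_cell species per (plot, period) cell: a single count
#'   or a `c(min, max)` range sampled uniformly per cell.
#' @param mu_alpha habitat-level mean intercepts (recycled to K).
#' @param mu_beta habitat-level mean changes (recycled to K).
#' @param sigma_alpha between-plot sd of intercepts (within habitat).
#' @param sigma_beta between-plot sd of slopes (within habitat).
#' @param rho intercept-slope correlation.
#' @param sigma_species within-plot sd of species scores.
#' @param ordinal round scores to integers and clip to `bounds`.
#' @param bounds score bounds used when `ordinal = TRUE`.
#' @param index indicator index label attached to emitted frames.
#' @param seed integer seed.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_habitats = 3, plots_per_habitat = 8,
                       species_per_cell = 30,
                       mu_alpha = 5, mu_beta = 0,
                       sigma_alpha = 0.35, sigma_beta = 0.3, rho = 0.3,
                       sigma_species = 1.6,
                       ordinal = FALSE, bounds = c(1, 9), index = "N",
                       seed = 1) {
  stopifnot(n_habitats >= 1, all(plots_per_habitat >= 1),
            all(species_per_cell >= 1),
            sigma_alpha >= 0, sigma_beta >= 0, sigma_species >= 0,
            abs(rho) <= 1, length(bounds) == 2, bounds[1] < bounds[2])
  K <- as.integer(n_habitats)
  structure(list(
    n_habitats = K,
    plots_per_habitat = rep_len(as.integer(plots_per_habitat), K),
    species_per_cell = as.integer(species_per_cell),
    mu_alpha = rep_len(mu_alpha, K),
    mu_beta = rep_len(mu_beta, K),
    sigma_alpha = sigma_alpha, sigma_beta = sigma_beta, rho = rho,
    sigma_species = sigma_species,
    ordinal = ordinal, bounds = bounds, index = index,
    seed = as.integer(seed)), class = "sim_params")
}

#' Studland-like survey preset
#'
#' A preset emulating the shape of the case-study survey: 7 habitats,
#' 74 plots (four habitats of 11 plots, three of 10), two periods, cell
#' species richness drawn uniformly from 10-120, and variance components of
#' the magnitudes seen in real indicator-value resurveys
#' (`sigma_species = 1.6`, `sigma_alpha = 0.35`, `sigma_beta = 0.3`).
#' Habitat mean intercepts spread over the middle of the score scale and
#' habitat mean changes over roughly (-0.45, 0.45): small effect sizes, as
#' expected on an ordinal indicator scale.
#'
#' @param seed integer seed.
#' @return a `sim_params` object.
#' @export
studland_like_preset <- function(seed = 1) {
  sim_params(
    n_habitats = 7,
    plots_per_habitat = c(11, 11, 11, 11, 10, 10, 10),
    species_per_cell = c(10, 120),
    mu_alpha = c(4.0, 4.5, 5.0, 5.5, 6.0, 6.5, 5.0),
    mu_beta = c(-0.45, -0.3, -0.15, 0, 0.15, 0.3, 0.45),
    sigma_alpha = 0.35, sigma_beta = 0.3, rho = 0.3,
    sigma_species = 1.6,
    ordinal = FALSE, bounds = c(1, 9), index = "N",
    seed = seed)
}

#' Simulate a two-period survey with known ground truth
#'
#' Draws plot intercept/slope pairs from the habitat-level bivariate normal
#' and species scores from the data-level normal, assembles a `model_frame`
#' (species are synthetic labels, drawn independently per plot-period cell),
#' and returns the realized plot parameters for recovery tests.
#'
#' @param params a [sim_params()] object.
#' @return list with `frame` (a `model_frame`) and `truth` (list: vectors
#'   `alpha`, `beta` per plot, `habitat_of_plot`, `plot_levels`,
#'   `habitat_levels`, and the `params` used).
#' @export
simulate_survey <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  K <- params$n_habitats
  J <- sum(params$plots_per_habitat)
  hab_of_plot <- rep(seq_len(K), times = params$plots_per_habitat)
  # bivariate normal via the conditional factorization
  alpha <- stats::rnorm(J, params$mu_alpha[hab_of_plot], params$sigma_alpha)
  cond_mean <- params$mu_beta[hab_of_plot] +
    if (params$sigma_alpha > 0) {
      params$rho * (params$sigma_beta / params$sigma_alpha) *
        (alpha - params$mu_alpha[hab_of_plot])
    } else 0
  beta <- stats::rnorm(J, cond_mean,
                       params$sigma_beta * sqrt(1 - params$rho^2))

  plot_ids <- sprintf("plot%03d", seq_len(J))
  hab_ids <- sprintf("hab%02d", seq_len(K))
  rows <- vector("list", 2L * J)
  ridx <- 0L
  for (j in seq_len(J)) {
    for (period in 1:2) {
      nsp <- if (length(params$species_per_cell) == 2L) {
        sample(params$species_per_cell[1]:params$species_per_cell[2], 1L)
      } else params$species_per_cell[1]
      mu <- alpha[j] + (period == 2L) * beta[j]
      y <- stats::rnorm(nsp, mu, params$sigma_species)
      ridx <- ridx + 1L
      rows[[ridx]] <- data.frame(
        y = y, plot = plot_ids[j], period = period,
        habitat = hab_ids[hab_of_plot[j]],
        species = sprintf("sp%05d", seq_len(nsp)),
        stringsAsFactors = FALSE)
    }
  }
  fr <- do.call(rbind, rows)
  if (params$ordinal) {
    y <- round(fr$y)
    clipped <- mean(y < params$bounds[1] | y > params$bounds[2])
    if (clipped > 0.5) {
      warning(sprintf("score bounds clip %.0f%% of generated values",
                      100 * clipped))
    }
    fr$y <- pmin(pmax(y, params$bounds[1]), params$bounds[2])
  }
  fr <- fr[order(fr$plot, fr$period, fr$species), , drop = FALSE]
  frame <- new_model_frame(fr, index = params$index)
  truth <- list(alpha = alpha, beta = beta,
                habitat_of_plot = hab_of_plot,
                plot_levels = plot_ids, habitat_levels = hab_ids,
                params = params)
  list(frame = frame, truth = truth)
}

#' Write the ground truth of a simulated survey to JSON
#'
#' @param truth the `truth` element of [simulate_survey()].
#' @param path output path (`truth.json`).
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  obj <- truth
  obj$params <- unclass(obj$params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
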