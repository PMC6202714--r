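#' Extract the plot design implied by a model frame
#'
#' @param frame a `model_frame`.
#' @return a `plot_design` with one row per plot (plot, habitat).
#' @export
frame_design <- function(frame) {
  as_plot_design(data.frame(
    plot = attr(frame, "plot_levels"),
    habitat = attr(frame, "habitat_levels")[attr(frame, "habitat_of_plot")],
    stringsAsFactors = FALSE))
}

#' Select species-rich plots for the depletion experiment
#'
#' Stratified random selection: one (plot, period) cell with more than
#' `min_species` scored species from each (habitat, period) stratum.
#' Strata without a qualifying plot are skipped with a warning and recorded.
#'
#' @param frame a `model_frame`.
#' @param design a `plot_design` (defaults to the frame's own design).
#' @param min_species richness threshold (strictly greater than).
#' @param fraction fraction of species removed from each selected cell by
#'   [deplete()].
#' @param iterations default iteration count for
#'   [run_depletion_experiment()].
#' @param seed integer seed; selection and per-iteration removals derive
#'   from it.
#' @return a `depletion_plan`: data frame `habitat`, `period`, `plot`,
#'   `n_species`; attributes `fraction`, `iterations`, `seed`,
#'   `skipped_strata`.
#' @export
select_depletion_plots <- function(frame, design = frame_design(frame),
                                   min_species = 50, fraction = 0.9,
                                   iterations = 120, seed = 1) {
  stopifnot(inherits(frame, "model_frame"),
            fraction > 0, fraction < 1, iterations >= 1)
  counts <- stats::aggregate(frame$y,
                             by = list(plot = frame$plot,
                                       period = frame$period),
                             FUN = length)
  names(counts)[3] <- "n_species"
  counts$habitat <- design$habitat[match(counts$plot, design$plot)]
  set.seed(as.integer(seed))
  habs <- sort(unique(design$habitat))
  rows <- list()
  skipped <- character(0)
  for (h in habs) {
    for (p in 1:2) {
      cand <- counts[counts$habitat == h & counts$period == p &
                       counts$n_species > min_species, , drop = FALSE]
      if (nrow(cand) == 0L) {
        skipped <- c(skipped, paste0(h, "/period", p))
        next
      }
      pick <- cand[sample.int(nrow(cand), 1L), , drop = FALSE]
      rows[[length(rows) + 1L]] <-
        data.frame(habitat = h, period = p, plot = pick$plot,
                   n_species = pick$n_species, stringsAsFactors = FALSE)
    }
  }
  if (length(skipped)) {
    warning("stratum(-a) without a plot richer than ", min_species,
            " species skipped: ", paste(skipped, collapse = ", "))
  }
  plan <- if (length(rows)) do.call(rbind, rows) else
    data.frame(habitat = character(0), period = integer(0),
               plot = character(0), n_species = integer(0))
  rownames(plan) <- NULL
  attr(plan, "fraction") <- fraction
  attr(plan, "iterations") <- as.integer(iterations)
  attr(plan, "seed") <- as.integer(seed)
  attr(plan, "skipped_strata") <- skipped
  class(plan) <- c("depletion_plan", "data.frame")
  plan
}

# Deterministic per-iteration seed derived from the plan seed.
iteration_seed <- function(plan_seed, iteration) {
  as.integer((as.numeric(plan_seed) * 7919 + iteration * 104729) %% 2147483629)
}

#' Remove a random share of species from the selected cells
#'
#' For each (plot, period) cell in the plan, keeps
#' `max(1, round(n * (1 - fraction)))` of its species, chosen uniformly at
#' random; all other rows are untouched. The random choice is deterministic
#' given the plan seed and the iteration number.
#'
#' @param frame a `model_frame`.
#' @param plan a `depletion_plan`.
#' @param iteration iteration number (>= 1).
#' @param fraction removal fraction; defaults to the plan's.
#' @return a depleted `model_frame` (same plots, habitats and index).
#' @export
deplete <- function(frame, plan, iteration = 1,
                    fraction = attr(plan, "fraction")) {
  stopifnot(inherits(frame, "model_frame"), fraction >= 0, fraction < 1)
  if (fraction == 0) return(frame)
  set.seed(iteration_seed(attr(plan, "seed"), iteration))
  drop_rows <- integer(0)
  for (r in seq_len(nrow(plan))) {
    cell <- which(frame$plot == plan$plot[r] &
                    frame$period == plan$period[r])
    keep_n <- max(1L, as.integer(round(length(cell) * (1 - fraction))))
    keep <- sample(cell, keep_n)
    drop_rows <- c(drop_rows, setdiff(cell, keep))
  }
  if (!length(drop_rows)) return(frame)
  fr <- as.data.frame(frame)[-drop_rows, , drop = FALSE]
  # rebuild from label columns so indices stay consistent even if a level
  # were emptied (cannot happen here: at least one species is kept per cell)
  out <- new_model_frame(
    fr[, c("y", "plot", "period", "habitat", "species")],
    index = attr(frame, "index"))
  out
}

# Posterior draws of the plot mean of one (plot, period) cell:
# alpha_j for period 1, alpha_j + beta_j for period 2 (draw-wise).
cell_mean_draws <- function(fit, plot, period) {
  j <- match(plot, attr(fit$frame, "plot_levels"))
  if (is.na(j)) stop("plot not in fit: ", plot)
  a <- draw_cols(fit, "alpha")[, j]
  if (period == 2L) a + draw_cols(fit, "beta")[, j] else a
}

#' Run the species-depletion validation experiment
#'
#' Repeatedly removes a random `fraction` of species from the plan's
#' species-rich cells, refits the requested models to the depleted frame,
#' and scores each model's posterior plot-mean estimates for the depleted
#' cells against the full-data raw mean of the same cell (the "true mean").
#'
#' @param frame the full `model_frame`.
#' @param plan a `depletion_plan`; its fraction/iterations/seed drive the
#'   experiment unless overridden.
#' @param models character vector among `"M1"`, `"M2"`, `"M3"`.
#' @param iterations number of depletion iterations.
#' @param priors a [prior_config()].
#' @param mcmc an [mcmc_config()]; the per-fit seed is derived from it and
#'   the iteration number.
#' @param quiet suppress per-iteration progress messages.
#' @return a `depletion_result`: list with `metrics` (per model: mean 50%
#'   and 95% interval widths, mean precision = average over cells of
#'   1/variance of the point estimates across iterations, hit proportions
#'   at 50% and 95%, mean absolute distance from the true mean), `raw`
#'   (per-iteration estimates: iteration, plot, period, model, point, lo50,
#'   hi50, lo95, hi95, true_mean) and `failures` (count of failed fits).
#' @export
run_depletion_experiment <- function(frame, plan,
                                     models = c("M1", "M2", "M3"),
                                     iterations = attr(plan, "iterations"),
                                     priors = prior_config(),
                                     mcmc = mcmc_config(),
                                     quiet = TRUE) {
  models <- match.arg(models, c("M1", "M2", "M3"), several.ok = TRUE)
  stopifnot(nrow(plan) >= 1, iterations >= 1)
  raw_full <- plot_raw_means(frame)
  true_mean <- vapply(seq_len(nrow(plan)), function(r) {
    raw_full$mean[raw_full$plot == plan$plot[r] &
                    raw_full$period == plan$period[r]]
  }, numeric(1))

  rows <- list()
  failures <- 0L
  for (it in seq_len(iterations)) {
    dep <- deplete(frame, plan, iteration = it)
    for (m in models) {
      fit <- tryCatch(
        suppressWarnings(fit_model(
          dep, model = m, priors = priors,
          mcmc = mcmc_config(chains = mcmc$chains, warmup = mcmc$warmup,
                             iter = mcmc$iter, thin = mcmc$thin,
                             seed = iteration_seed(mcmc$seed, it)))),
        error = function(e) NULL)
      if (is.null(fit)) {
        failures <- failures + 1L
        next
      }
      for (r in seq_len(nrow(plan))) {
        d <- cell_mean_draws(fit, plan$plot[r], plan$period[r])
        s <- posterior_summary(d)
        rows[[length(rows) + 1L]] <- data.frame(
          iteration = it, plot = plan$plot[r], period = plan$period[r],
          model = m, point = s$mean, lo50 = s$lo50, hi50 = s$hi50,
          lo95 = s$lo95, hi95 = s$hi95, true_mean = true_mean[r],
          stringsAsFactors = FALSE)
      }
    }
    if (!quiet) message("depletion iteration ", it, "/", iterations)
  }
  raw <- do.call(rbind, rows)
  rownames(raw) <- NULL
  structure(list(metrics = depletion_metrics(raw), raw = raw,
                 failures = failures, plan = plan),
            class = "depletion_result")
}

#' Aggregate depletion metrics from per-iteration estimates
#'
#' Recomputes the summary table from the raw per-iteration estimates, so
#' results are reproducible from the persisted raw table alone.
#'
#' @param raw the `raw` data frame of a `depletion_result`.
#' @return a `depletion_metrics` data frame, one row per model:
#'   `mean_width50`, `mean_width95`, `mean_precision`, `hits50`, `hits95`,
#'   `mean_abs_dist`.
#' @export
depletion_metrics <- function(raw) {
  out <- do.call(rbind, lapply(split(raw, raw$model), function(d) {
    cell <- paste(d$plot, d$period)
    prec <- vapply(split(d$point, cell), function(p) {
      if (length(p) < 2) NA_real_ else 1 / stats::var(p)
    }, numeric(1))
    data.frame(
      model = d$model[1],
      mean_width50 = mean(d$hi50 - d$lo50),
      mean_width95 = mean(d$hi95 - d$lo95),
      mean_precision = mean(prec, na.rm = TRUE),
      hits50 = mean(d$true_mean >= d$lo50 & d$true_mean <= d$hi50),
      hits95 = mean(d$true_mean >= d$lo95 & d$true_mean <= d$hi95),
      mean_abs_dist = mean(abs(d$point - d$true_mean)),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("depletion_metrics", "data.frame")
  out
}

#' @export
print.depletion_result <- function(x, ...) {
  cat(sprintf("depletion_result: %d cells, %d iterations, %d failed fit(s)\n",
              nrow(x$plan), max(x$raw$iteration), x$failures))
  print(x$metrics)
  invisible(x)
}
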