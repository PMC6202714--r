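# Shared fixtures: small synthetic surveys and memoized MCMC fits reused
# across test files (fits are the expensive part of the suite).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

test_mcmc <- function(seed, chains = 2, warmup = 500, iter = 500) {
  mcmc_config(chains = chains, warmup = warmup, iter = iter, seed = seed)
}

# 20-plot survey: 2 habitats x 10 plots, 30 species per cell
survey20 <- function() cached("survey20", function() {
  simulate_survey(sim_params(
    n_habitats = 2, plots_per_habitat = 10, species_per_cell = 30,
    mu_alpha = c(4.5, 5.5), mu_beta = c(-0.3, 0.3), seed = 201))
})

fit_m1_20 <- function() cached("fit_m1_20", function() {
  suppressWarnings(fit_model(survey20()$frame, "M1",
                             mcmc = test_mcmc(11)))
})

# low between-plot spread: strong shrinkage regime (24 plots)
survey_shrink <- function() cached("survey_shrink", function() {
  simulate_survey(sim_params(
    n_habitats = 2, plots_per_habitat = 12, species_per_cell = 30,
    mu_alpha = 5, mu_beta = 0, sigma_alpha = 0.15, sigma_beta = 0.1,
    seed = 202))
})

fit_m2_shrink <- function() cached("fit_m2_shrink", function() {
  suppressWarnings(fit_model(survey_shrink()$frame, "M2",
                             mcmc = test_mcmc(12)))
})

# habitat-structured survey: 3 habitats x 8 plots, 30 species per cell
survey_hab <- function() cached("survey_hab", function() {
  simulate_survey(sim_params(
    n_habitats = 3, plots_per_habitat = 8, species_per_cell = 30,
    mu_alpha = c(4, 5, 6), mu_beta = c(-0.5, 0, 0.5), seed = 203))
})

fit_m1_hab <- function() cached("fit_m1_hab", function() {
  suppressWarnings(fit_model(survey_hab()$frame, "M1",
                             mcmc = test_mcmc(13)))
})
fit_m2_hab <- function() cached("fit_m2_hab", function() {
  suppressWarnings(fit_model(survey_hab()$frame, "M2",
                             mcmc = test_mcmc(13)))
})
fit_m3_hab <- function() cached("fit_m3_hab", function() {
  suppressWarnings(fit_model(survey_hab()$frame, "M3",
                             mcmc = test_mcmc(13)))
})

# Construct a model frame directly from vectors (bypasses file I/O).
make_frame <- function(y, plot, period, habitat = "H1", species = NULL) {
  n <- length(y)
  if (is.null(species)) species <- sprintf("sp%04d", seq_len(n))
  df <- data.frame(y = as.numeric(y), plot = as.character(plot),
                   period = as.integer(period),
                   habitat = rep_len(as.character(habitat), n),
                   species = species, stringsAsFactors = FALSE)
  eivpool:::new_model_frame(df, index = "N")
}

# Hand-built fit object with known draws, for exact metric oracles.
# alpha/beta: S x J matrices; mu_alpha/mu_beta: S-vector (M2) or S x K (M3).
make_fake_fit <- function(frame, alpha, beta, sigma_species,
                          model = "M1", mu_alpha = NULL, mu_beta = NULL,
                          sigma_alpha = NULL, sigma_beta = NULL,
                          rho = NULL) {
  alpha <- as.matrix(alpha); beta <- as.matrix(beta)
  J <- ncol(alpha)
  draws <- cbind(alpha, beta, sigma_species)
  colnames(draws) <- c(sprintf("alpha[%d]", 1:J), sprintf("beta[%d]", 1:J),
                       "sigma_species")
  add <- function(draws, x, name) {
    x <- as.matrix(x)
    colnames(x) <- if (ncol(x) == 1) name else
      sprintf("%s[%d]", name, seq_len(ncol(x)))
    cbind(draws, x)
  }
  if (model %in% c("M2", "M3")) {
    draws <- add(draws, mu_alpha, "mu_alpha")
    draws <- add(draws, mu_beta, "mu_beta")
    if (!is.null(sigma_alpha)) draws <- add(draws, sigma_alpha, "sigma_alpha")
    if (!is.null(sigma_beta)) draws <- add(draws, sigma_beta, "sigma_beta")
    if (!is.null(rho)) draws <- add(draws, rho, "rho")
  }
  structure(list(model = model, draws = draws,
                 chain = rep(1L, nrow(draws)),
                 iteration = seq_len(nrow(draws)),
                 samples = NULL, frame = frame,
                 priors = prior_config(), mcmc = NULL, seed = NA,
                 warnings = character(0)),
            class = "eiv_fit")
}

# Write a tiny EIV / occurrence / design CSV trio into dir; returns paths.
write_fixture_csvs <- function(dir) {
  eiv <- file.path(dir, "eiv.csv")
  occ <- file.path(dir, "occ.csv")
  des <- file.path(dir, "design.csv")
  writeLines(c("species,F,L,N,R,S",
               "Carex arenaria,6,8,2,5,1",
               "Calluna vulgaris,6,7,1,2,0",
               "Erica tetralix,8,8,1,2,0",
               "Ulex europaeus,5,8,3,5,0",
               "Molinia caerulea,7,7,2,3,0"), eiv)
  grid <- expand.grid(plot = c("p1", "p2"), period = 1:2,
                      species = c("Carex arenaria", "Calluna vulgaris",
                                  "Erica tetralix", "Ulex europaeus",
                                  "Molinia caerulea"),
                      stringsAsFactors = FALSE)
  utils::write.csv(grid[order(grid$plot, grid$period), ], occ,
                   row.names = FALSE)
  writeLines(c("plot,habitat,area_m2", "p1,heath,1000", "p2,dune,2000"), des)
  list(eiv = eiv, occ = occ, design = des)
}
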