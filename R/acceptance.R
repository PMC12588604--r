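# Canned evaluation scenarios used by the acceptance suite and
# scripts/acceptance.R: a strong-signal niche-recovery benchmark and the
# hierarchical driver-regression convergence benchmark.

#' Niche-model benchmark: strong-signal synthetic species
#'
#' Generates a modern-scenario environment on the desk-scale grid, defines a
#' species with Gaussian suitability in annual temperature and precipitation
#' (breadths 10% of each layer's range, optima at the layer medians), samples
#' `n_presence` presence cells proportional to suitability and
#' `n_background` uniform background cells (seeded), and evaluates the
#' maximum-entropy-style model with the published bootstrap protocol
#' (20 replicates, 75/25 split).
#'
#' @param seed_world Seed for the environment + sampling.
#' @param seed_eval Seed for the bootstrap evaluation.
#' @param n_presence,n_background Sample sizes (defaults 500 / 10000).
#' @param n_boot,train_frac Evaluation protocol (defaults 20, 0.75).
#' @return The `AUCSummary`.
#' @export
benchmark_niche_auc <- function(seed_world, seed_eval, n_presence = 500L,
                                n_background = 10000L, n_boot = 20L,
                                train_frac = 0.75) {
  gs <- grid_spec(0, 60, 60, 140, dlat = 3, dlon = 8 / 3)
  env <- generate_environment("modern", seed_world, gs)
  ann <- env_annual_layers(env)
  E <- cbind(temperature = as.vector(ann$temperature),
             precipitation = as.vector(ann$precipitation))
  sp <- list(t_opt = median(E[, 1]),
             t_breadth = 0.1 * diff(range(E[, 1])),
             p_opt = median(E[, 2]),
             p_breadth = 0.1 * diff(range(E[, 2])))
  suit <- suitability(sp, E[, 1], E[, 2])
  with_seed(seed_world, {
    pres <- E[sample.int(nrow(E), n_presence, replace = TRUE, prob = suit), ]
    bg <- E[sample.int(nrow(E), n_background, replace = TRUE), ]
    evaluate_auc(pres, bg, n_boot = n_boot, train_frac = train_frac,
                 seed = seed_eval)
  })
}

#' Driver-regression benchmark: synthetic recovery table
#'
#' Generates the standard recovery table (400 segments across 10 species,
#' standardised drivers, true temperature coefficient 0.5, all other
#' coefficients 0, residual sd 0.3) and fits the hierarchical Bayesian model
#' with species intercepts.
#'
#' @param seed_table Seed for the synthetic table.
#' @param seed_fit Seed for the sampler.
#' @param n,n_species,beta_temperature,sigma Table parameters.
#' @param chains,tune,draws Sampler size (defaults 4, 3000, 3000).
#' @return The `PosteriorSummary`.
#' @export
benchmark_driver_fit <- function(seed_table, seed_fit, n = 400L,
                                 n_species = 10L, beta_temperature = 0.5,
                                 sigma = 0.3, chains = 4L, tune = 3000L,
                                 draws = 3000L) {
  tab <- with_seed(seed_table, {
    X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, DRIVER_COLS))
    X <- scale(X)
    tab <- data.table::as.data.table(as.matrix(X))
    tab[, azimuth := beta_temperature * temperature + rnorm(n, 0, sigma)]
    tab[, species := sample(sprintf("S%02d", seq_len(n_species)), n,
                            replace = TRUE)]
    tab
  })
  fit_bayes(tab, hierarchical = TRUE, seed = seed_fit, chains = chains,
            tune = tune, draws = draws, standardize = TRUE)
}
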