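# Shared fixtures and independent oracles.  Oracles here deliberately avoid
# the package's prediction/fitting code paths: curves are evaluated with
# inline arithmetic and optima are located by brute-force grid search.

design_days <- c(0, 1, 3, 5, 10, 15, 21, 22, 24, 26, 31, 36, 42)

default_schedule <- function() exposure_schedule(C_I0 = 2)

# inline single-phase curve (oracle; independent of .onecomp)
oracle_curve <- function(t, c0, ce, kA, kE) {
  c0 * exp(-kE * t) + ce * kA / kE - ce * kA / kE * exp(-kE * t)
}

# brute-force RSS minimiser over a (kA, kE) grid
grid_search <- function(y, t, c0, ce, kA_grid, kE_grid) {
  best <- list(rss = Inf)
  for (kE in kE_grid) {
    E <- exp(-kE * t)
    base <- c0 * E
    gain <- ce / kE * (1 - E)
    for (kA in kA_grid) {
      rss <- sum((y - base - kA * gain)^2)
      if (rss < best$rss) best <- list(kA = kA, kE = kE, rss = rss)
    }
  }
  best
}

# noise-free observations on the design days from a single (pooled) truth
noise_free_data <- function(kA1, kE1, kA2, kE2,
                            schedule = default_schedule(),
                            days = design_days, per_day = 4) {
  tr <- list(contamination = kinetic_params(kA1, kE1, quiet = TRUE),
             decontamination = kinetic_params(kA2, kE2, quiet = TRUE))
  cfg <- simulation_config(schedule = schedule,
                           truth = list(forest = tr, city = tr),
                           time_points = days,
                           colonies_per_cell = ceiling(per_day / 4),
                           noise_sd_contamination = 0,
                           noise_sd_decontamination = 0,
                           exceedance_prob = 0, seed = 1)
  generate_dataset(cfg)$observations
}

# pooled-truth config at the study design (both habitats share parameters)
pooled_truth_config <- function(seed,
                                kA1 = 0.871, kE1 = 1.119,
                                kA2 = 4.075, kE2 = 0.33,
                                exceedance_prob = 0, ...) {
  tr <- list(contamination = kinetic_params(kA1, kE1, quiet = TRUE),
             decontamination = kinetic_params(kA2, kE2, quiet = TRUE))
  simulation_config(truth = list(forest = tr, city = tr),
                    exceedance_prob = exceedance_prob, seed = seed, ...)
}

# balanced 2x2 endpoint table with specified cell means
endpoint_data <- function(mu, n_per_cell = 4, sd = 0, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(rep = seq_len(n_per_cell),
                      habitat = c("city", "forest"),
                      time_days = c(0, 42), stringsAsFactors = FALSE)
  key <- paste(grid$time_days, grid$habitat)
  mu_row <- mu[key]
  data.frame(colony_id = sprintf("c%02d", seq_len(nrow(grid))),
             habitat = grid$habitat, region = "paris",
             time_days = grid$time_days,
             concentration = mu_row + stats::rnorm(nrow(grid), 0, sd),
             stringsAsFactors = FALSE)
}
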