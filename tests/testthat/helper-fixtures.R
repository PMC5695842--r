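# Small fixtures built in code.

# 4 samples x 3 taxa, one location, both treatments, two occasions.
toy_counts <- function() {
  counts <- matrix(c(1, 2, 3,
                     4, 5, 6,
                     7, 8, 9,
                     0, 1, 2),
                   nrow = 4, byrow = TRUE,
                   dimnames = list(NULL, c("acari", "collembola", "diptera")))
  meta <- data.frame(
    sample_id = paste0("s", 1:4),
    location = "loc01",
    treatment = c("treated", "control", "treated", "control"),
    habitat = "lawn",
    occasion = c("pre", "pre", "post1", "post1"),
    sample_type = "bulk"
  )
  taxon_counts(counts, meta)
}

# Two-location, one-habitat BACI toy: before T=4, C=2; after T=2, C=6 at
# both locations. Replicate effect = (2-6)-(4-2) = -6 everywhere.
# Second taxon is 10x the first.
baci_toy <- function() {
  cells <- expand.grid(location = c("loc01", "loc02"),
                       treatment = c("treated", "control"),
                       occasion = c("pre", "post1"),
                       stringsAsFactors = FALSE)
  base <- ifelse(cells$occasion == "pre",
                 ifelse(cells$treatment == "treated", 4, 2),
                 ifelse(cells$treatment == "treated", 2, 6))
  counts <- cbind(taxon_a = base, taxon_b = 10 * base)
  meta <- data.frame(
    sample_id = sprintf("s%02d", seq_len(nrow(cells))),
    location = cells$location,
    treatment = cells$treatment,
    habitat = "lawn",
    occasion = cells$occasion,
    sample_type = "bulk"
  )
  taxon_counts(counts, meta)
}

# Reduced synthetic design for fast model/power tests: fewer taxa and
# locations, no subsampling noise, no losses.
mini_config <- function(seed = 1L, treatment_multiplier = 1, ...) {
  args <- list(
    n_locations = 8, n_taxa = 6,
    intercept = log(c(120, 40, 8, 4, 2, 1)),
    habitat_effect = rep(c(0.5, -0.5), 3),
    treatment_multiplier = treatment_multiplier,
    dispersion = rep(1, 6),
    subsample_fraction = NULL,
    pitfall_locations = 4, pitfall_extra_locations = 2,
    n_lost_bulk = 0, n_lost_pitfall = 0,
    seed = seed
  )
  args <- utils::modifyList(args, list(...))
  do.call(synthetic_config, args)
}

mini_bulk <- function(seed = 1L, treatment_multiplier = 1, ...) {
  sim <- simulate_dataset(mini_config(seed, treatment_multiplier, ...))
  occasion_subset(sim$pooled, "bulk", c("pre", "post1"))
}

alt_terms <- c("period", "habitat", "location", "treatment")

# Independent oracle: direct numerical maximization of the NB log-likelihood
# over (beta, log theta), multiple starts, sharing no code with the fitter.
oracle_nb_ml <- function(y, X) {
  negll <- function(par) {
    beta <- par[seq_len(ncol(X))]
    theta <- exp(par[length(par)])
    mu <- exp(drop(X %*% beta))
    -sum(dnbinom(y, size = theta, mu = mu, log = TRUE))
  }
  starts <- list(c(rep(0.1, ncol(X)), 0), c(log(mean(y) + 0.5),
                                            rep(0, ncol(X) - 1), 1))
  best <- NULL
  for (s in starts) {
    o <- optim(s, negll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  # polish with alternating restarts until stationary
  for (k in 1:6) {
    o1 <- optim(best$par, negll, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-15))
    if (o1$value < best$value) best <- o1
    o2 <- optim(best$par, negll, method = "BFGS",
                control = list(maxit = 2000, reltol = 1e-15))
    improved <- best$value - o2$value
    if (o2$value < best$value) best <- o2
    if (improved < 1e-10) break
  }
  list(loglik = -best$value,
       coefficients = best$par[seq_len(ncol(X))],
       theta = exp(best$par[length(best$par)]))
}
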