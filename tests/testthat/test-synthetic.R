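test_that("the same seed reproduces the dataset exactly", {
  s1 <- simulate_dataset(mini_config(seed = 42))
  s2 <- simulate_dataset(mini_config(seed = 42))
  expect_identical(s1$raw, s2$raw)
  expect_identical(s1$pooled, s2$pooled)
  s3 <- simulate_dataset(mini_config(seed = 43))
  expect_false(identical(s1$raw$counts, s3$raw$counts))
})

test_that("the default design reproduces the study sample inventory", {
  sim <- simulate_dataset(synthetic_config(seed = 11))
  expect_equal(table(sim$raw$meta$sample_type)[["bulk"]], 467)
  expect_equal(table(sim$raw$meta$sample_type)[["pitfall"]], 129)
  expect_equal(table(sim$pooled$meta$sample_type)[["bulk"]], 156)
  expect_equal(table(sim$pooled$meta$sample_type)[["pitfall"]], 68)
  # dominant taxa flagged as extrapolated, counts strongly skewed
  expect_length(sim$pooled$extrapolated_taxa, 2)
  tot <- sort(colSums(sim$pooled$counts), decreasing = TRUE)
  expect_true(tot[2] > 10 * median(tot))
})

test_that("simulated counts are overdispersed and dispersion_check sees it", {
  sim <- simulate_dataset(synthetic_config(seed = 5))
  b <- occasion_subset(sim$pooled, "bulk", c("pre", "post1"))
  ratios <- dispersion_check(b)
  expect_true(mean(ratios > 1, na.rm = TRUE) > 0.8)
})

test_that("variance/mean ratio matches the NB closed form", {
  # Var = mu + mu^2/Phi, so Var/mean = 1 + mu/Phi
  n <- 5e4
  meta <- data.frame(sample_id = sprintf("s%05d", 1:n), location = "loc01",
                     treatment = "control", habitat = "lawn",
                     occasion = "pre", sample_type = "bulk")
  withr::with_seed(99, {
    y_nb <- rnbinom(n, size = 1, mu = 10)      # expect ratio ~ 11
    y_pois <- rnbinom(n, size = 1e8, mu = 10)  # Poisson limit, ratio ~ 1
  })
  m <- taxon_counts(cbind(nb = y_nb, pois = y_pois, flat = rep(2, n)), meta)
  r <- dispersion_check(m)
  expect_equal(unname(r["nb"]), 11, tolerance = 0.05)
  expect_equal(unname(r["pois"]), 1, tolerance = 0.05)
  expect_true(is.na(r["flat"]))
  expect_error(dispersion_check(subset_samples(m, 1)), "2 samples")
})

test_that("marginal means of raw counts match the linear predictor", {
  # strip known occasion/habitat effects and the component split, then the
  # remaining mean must equal exp(intercept); > 1e5 draws per taxon
  cfg <- synthetic_config(
    n_locations = 3200, n_taxa = 2, intercept = log(c(8, 2)),
    habitat_effect = c(0.4, -0.3), sigma_location = 0,
    dispersion = c(1, 2), subsample_fraction = NULL,
    pitfall_locations = 0, pitfall_extra_locations = 0,
    n_lost_bulk = 0, n_lost_pitfall = 0, seed = 21)
  sim <- simulate_dataset(cfg)
  raw <- sim$raw
  occ_eff <- c(pre = 0, cfg$occasion_effect)
  scale <- exp(-occ_eff[as.character(raw$meta$occasion)]) *
    ifelse(raw$meta$component == "lawn_core", 2, 4)
  expect_gt(nrow(raw$counts), 1e5)
  for (j in 1:2) {
    hab <- exp(ifelse(raw$meta$habitat == "forest", cfg$habitat_effect[j], 0))
    adj <- raw$counts[, j] * scale / hab
    expect_equal(mean(adj), exp(cfg$intercept[j]), tolerance = 0.01)
  }
})

test_that("the treatment multiplier scales treated-after cell means", {
  cfg <- mini_config(seed = 8, treatment_multiplier = 0.5,
                     n_locations = 200, sigma_location = 0)
  sim <- simulate_dataset(cfg)
  b <- sim$pooled
  after <- b$meta$period == "after" & b$meta$sample_type == "bulk"
  trt <- b$meta$treatment == "treated"
  ratio <- mean(b$counts[after & trt, 1]) / mean(b$counts[after & !trt, 1])
  expect_equal(ratio, 0.5, tolerance = 0.15)
  # before treatment the two arms are exchangeable
  before <- b$meta$period == "before" & b$meta$sample_type == "bulk"
  ratio0 <- mean(b$counts[before & trt, 1]) / mean(b$counts[before & !trt, 1])
  expect_equal(ratio0, 1, tolerance = 0.15)
})

test_that("model fits recover the generating coefficients", {
  # under a null treatment effect the alternative model contains the truth;
  # at 200 locations the generating values lie within 3 SEs
  cfg <- mini_config(seed = 31, n_locations = 200)
  sim <- simulate_dataset(cfg)
  b <- occasion_subset(sim$pooled, "bulk", c("pre", "post1"))
  fit <- fit_many_glm(b, model_spec(alt_terms))
  rn <- rownames(fit$coefficients)
  for (jj in 1:2) {
    se <- sqrt(diag(fit$vcov[[jj]]))
    est <- fit$coefficients[, jj]
    truth <- c(
      # the reference cell carries the reference location's effect
      "(Intercept)" = cfg$intercept[jj] + unname(sim$location_effect["loc01"]),
      "periodafter" = unname(cfg$occasion_effect["post1"]),
      "habitatforest" = cfg$habitat_effect[jj],
      "treatmentcontrol" = 0
    )
    for (nm in names(truth)) {
      k <- which(rn == nm)
      expect_lt(abs(est[k] - truth[nm]), 3 * se[k] + 1e-8,
                label = paste("coef", nm, "taxon", jj))
    }
  }
  # location contrasts recover the simulated location effects (attenuated
  # by estimation noise at ~12 rows per location)
  loc_cols <- grep("^location", rn)
  est_loc <- fit$coefficients[loc_cols, 1]
  lev <- sub("^location", "", rn[loc_cols])
  true_loc <- sim$location_effect[lev] - sim$location_effect["loc01"]
  expect_gt(cor(est_loc, true_loc), 0.85)
  # pooled samples sum 2 (lawn) or 4 (forest) components of dispersion 1,
  # so the pooled-scale dispersion sits between those component counts
  expect_gt(unname(fit$theta[1]), 1.2)
  expect_lt(unname(fit$theta[1]), 6)
})

test_that("design arithmetic helpers", {
  expect_equal(treated_area_m2(), 832)
  expect_equal(treated_area_m2(1, 8), 64)
})
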