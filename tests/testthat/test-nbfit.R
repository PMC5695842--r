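test_that("intercept-only fit equals the sample mean exactly", {
  y <- c(2, 2, 2, 2)
  X <- matrix(1, 4, 1, dimnames = list(NULL, "(Intercept)"))
  f <- fit_nb_glm(y, X)
  expect_equal(unname(f$coefficients), log(2), tolerance = 1e-8)
  expect_equal(unname(f$fitted), rep(2, 4), tolerance = 1e-7)
})

test_that("fitted optimum matches a brute-force optimizer on small instances", {
  for (seed in 1:3) {
    withr::with_seed(seed, {
      x <- rnorm(10)
      X <- cbind("(Intercept)" = 1, x = x)
      y <- rnbinom(10, size = 1.5, mu = exp(1 + 0.5 * x))
    })
    if (all(y == 0)) next
    f <- fit_nb_glm(y, X)
    o <- oracle_nb_ml(y, X)
    expect_equal(f$loglik, o$loglik, tolerance = 1e-6)
    expect_gte(f$loglik, o$loglik - 1e-6)
  }
})

test_that("compiled and reference engines agree", {
  b <- mini_bulk(seed = 2)
  X <- fit_many_glm(b, model_spec())$X
  for (j in seq_along(b$taxa)) {
    y <- b$counts[, j]
    if (all(y == 0)) next
    fc <- fit_nb_glm(y, X, engine = "cpp")
    fr <- fit_nb_glm(y, X, engine = "r")
    expect_equal(fc$loglik, fr$loglik, tolerance = 1e-7)
    expect_equal(fc$coefficients, fr$coefficients, tolerance = 1e-5)
  }
})

test_that("fits agree with an established NB GLM implementation", {
  skip_if_not_installed("MASS")
  b <- mini_bulk(seed = 4)
  fit <- fit_many_glm(b, model_spec(alt_terms))
  for (j in seq_along(b$taxa)) {
    y <- b$counts[, j]
    if (all(y == 0)) next
    gm <- tryCatch(
      suppressWarnings(MASS::glm.nb(
        y ~ period + habitat + location + treatment, data = b$meta,
        control = glm.control(maxit = 200))),
      error = function(e) NULL)
    # only converged, interior-theta MASS fits are comparable
    if (is.null(gm) || !gm$converged || gm$theta > 1e6) next
    expect_equal(fit$loglik_taxon[[j]], as.numeric(logLik(gm)),
                 tolerance = 1e-6)
    expect_equal(unname(fit$coefficients[, j]), unname(coef(gm)),
                 tolerance = 1e-4)
    expect_equal(unname(fit$theta[j]), gm$theta, tolerance = 1e-3)
  }
})

test_that("log-likelihood equals the direct NB log-pmf sum", {
  b <- mini_bulk(seed = 6)
  fit <- fit_many_glm(b, model_spec())
  for (j in seq_along(b$taxa)) {
    direct <- sum(dnbinom(b$counts[, j], size = fit$theta[j],
                          mu = pmax(fit$fitted[, j], 1e-8), log = TRUE))
    expect_equal(fit$loglik_taxon[[j]], direct, tolerance = 1e-8)
  }
})

test_that("near the Poisson limit NB coefficients match a Poisson GLM", {
  withr::with_seed(11, {
    meta <- mini_bulk(seed = 1)$meta
    mu <- exp(2 + 0.5 * (meta$habitat == "forest"))
    y <- rpois(nrow(meta), mu)
  })
  X <- model.matrix(~habitat, meta)
  f <- fit_nb_glm(y, X)
  pg <- glm(y ~ habitat, data = meta, family = poisson())
  expect_equal(unname(f$coefficients), unname(coef(pg)), tolerance = 1e-4)
  expect_gt(f$theta, 1e4)  # dispersion driven to the Poisson boundary
})

test_that("AIC identity and parameter accounting hold", {
  b <- mini_bulk(seed = 8)
  f <- fit_many_glm(b, model_spec())
  p <- ncol(f$X)
  expect_equal(f$df, length(b$taxa) * (p + 1))
  expect_equal(f$aic, -2 * f$loglik + 2 * f$df)
  expect_equal(AIC(f), f$aic)
  # one-taxon matrix reduces to the univariate fit
  m1 <- taxon_counts(b$counts[, 1, drop = FALSE], b$meta)
  f1 <- fit_many_glm(m1, model_spec())
  u <- fit_nb_glm(b$counts[, 1], f1$X)
  expect_equal(f1$aic, -2 * u$loglik + 2 * (p + 1))
  # duplicating a taxon doubles the total log-likelihood and parameters
  m2 <- taxon_counts(cbind(a_tax = b$counts[, 1], b_tax = b$counts[, 1]),
                     b$meta)
  f2 <- fit_many_glm(m2, model_spec())
  expect_equal(f2$loglik, 2 * u$loglik, tolerance = 1e-6)
  expect_equal(f2$df, 2 * (p + 1))
})

test_that("an all-zero taxon is flagged degenerate and kept out of the LR", {
  b <- mini_bulk(seed = 9)
  m <- taxon_counts(cbind(b$counts[, 1:2], none = 0), b$meta)
  f0 <- fit_many_glm(m, model_spec())
  expect_true(f0$degenerate[["none"]])
  expect_false(any(f0$degenerate[c("taxon_01", "taxon_02")]))
  f1 <- fit_many_glm(m, model_spec(alt_terms))
  lr_all <- bacinb:::lr_stat(f0, f1)
  # the degenerate taxon contributes nothing to the statistic
  m2 <- taxon_counts(b$counts[, 1:2], b$meta)
  lr_two <- bacinb:::lr_stat(fit_many_glm(m2, model_spec()),
                             fit_many_glm(m2, model_spec(alt_terms)))
  expect_equal(lr_all, lr_two, tolerance = 1e-6)
})

test_that("unidentifiable designs raise errors naming the factor", {
  b <- mini_bulk(seed = 3)
  one_loc <- subset_samples(b, b$meta$location == "loc01")
  expect_error(fit_many_glm(one_loc, model_spec()), "location")
  expect_error(model_spec(c("period", "frobnication")), "unknown model term")
  expect_error(model_spec(c("period", "period")), "duplicated")
})

test_that("AIC comparison honors nesting, ties, and bookkeeping", {
  b <- mini_bulk(seed = 5)
  expect_error(
    compare_models_aic(b, model_spec(c("period", "treatment")),
                       model_spec(c("period", "habitat"))),
    "nested")
  tie <- compare_models_aic(b, model_spec(c("period", "habitat")),
                            model_spec(c("period", "habitat")))
  expect_equal(tie$delta_aic, 0)
  expect_equal(tie$preferred, "null")
  expect_equal(tie$lr, 0, tolerance = 1e-6)
  # adding a k-level factor adds (k-1) * n_taxa parameters
  cmp <- compare_models_aic(b, model_spec(c("period", "habitat")),
                            model_spec(c("period", "habitat", "treatment")))
  expect_equal(cmp$fit_alt$df - cmp$fit_null$df, 1 * length(b$taxa))
  expect_gte(cmp$lr, -1e-6)
})

test_that("LR statistic is seed-stable and resampling p-values are valid", {
  b <- mini_bulk(seed = 12)
  cmp <- compare_models_aic(b, n_resamples = 99, seed = 7)
  expect_true(cmp$p_value >= 1 / 100 && cmp$p_value <= 1)
  cmp2 <- compare_models_aic(b, n_resamples = 99, seed = 7)
  expect_identical(cmp$p_value, cmp2$p_value)
  expect_error(compare_models_aic(b, n_resamples = 50, seed = 1), ">= 99")
})
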