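# Multivariate negative binomial GLMs: independent per-taxon fits sharing a
# design matrix, combined by summed log-likelihood; AIC model comparison and
# analysis of deviance with whole-row (PIT) resampling.

.model_terms <- c("period", "habitat", "location", "treatment")
.theta_range <- c(1e-4, 1e7)
.mu_floor <- 1e-8

#' Specify a log-linear abundance model
#'
#' A model is an ordered list of design factors drawn from `period`
#' (before/after treatment), `habitat`, `location`, and `treatment`.
#' The canonical null model is `period + habitat + location`; the
#' alternative adds `treatment`. Factors use treatment-contrast
#' (reference-level) coding.
#'
#' @param terms character vector of factor names, in testing order.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(terms = c("period", "habitat", "location")) {
  bad <- setdiff(terms, .model_terms)
  if (length(bad)) {
    stop("unknown model term(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(.model_terms, collapse = ", "), ")")
  }
  if (anyDuplicated(terms)) stop("duplicated model terms")
  structure(list(terms = as.character(terms)), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("abundance ~", if (length(x$terms)) paste(x$terms, collapse = " + ")
      else "1", "\n")
  invisible(x)
}

#' @export
format.model_spec <- function(x, ...) {
  paste("abundance ~", if (length(x$terms)) paste(x$terms, collapse = " + ")
        else "1")
}

# Is `a` nested in `b`?
spec_nested <- function(a, b) all(a$terms %in% b$terms)

# Design matrix for a spec over a metadata frame; errors when a factor is
# unidentifiable (single level present, or introduces rank deficiency).
spec_design <- function(spec, meta) {
  for (tm in spec$terms) {
    lev <- unique(as.character(meta[[tm]]))
    if (length(lev) < 2) {
      stop("factor '", tm, "' has a single level in the data; ",
           "model is unidentifiable")
    }
  }
  fml <- stats::as.formula(paste("~", if (length(spec$terms))
    paste(spec$terms, collapse = " + ") else "1"))
  meta2 <- meta
  for (tm in spec$terms) meta2[[tm]] <- droplevels(factor(meta2[[tm]]))
  X <- stats::model.matrix(fml, data = meta2)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design for model ", format(spec),
         "; check factor crossings")
  }
  X
}

# NB log-likelihood in the (mu, Phi=size) convention.
nb_loglik <- function(y, mu, theta) {
  sum(stats::dnbinom(y, size = theta, mu = pmax(mu, .mu_floor), log = TRUE))
}

# Profile-ML dispersion at fixed means. Newton steps on theta (score and
# observed information of the profile likelihood), falling back to a 1-D
# search over log(theta) when Newton stalls or leaves the allowed range.
ml_theta <- function(y, mu, theta0 = NULL) {
  mu <- pmax(mu, .mu_floor)
  score <- function(th) {
    sum(digamma(th + y) - digamma(th) + log(th) + 1 - log(th + mu) -
          (y + th) / (mu + th))
  }
  info <- function(th) {
    sum(-trigamma(th + y) + trigamma(th) - 1 / th + 2 / (mu + th) -
          (y + th) / (mu + th)^2)
  }
  m <- mean(y); v <- stats::var(y)
  th <- theta0 %||% if (is.finite(v) && v > m) m^2 / (v - m) else 10
  th <- min(max(th, .theta_range[1]), .theta_range[2])
  ok <- FALSE
  for (it in seq_len(30)) {
    i <- info(th)
    if (!is.finite(i) || i <= 0) break
    delta <- score(th) / i
    th_new <- th + delta
    if (!is.finite(th_new) || th_new <= .theta_range[1] ||
        th_new >= .theta_range[2]) break
    if (abs(delta) < 1e-8 * (th + 1)) {
      th <- th_new
      ok <- TRUE
      break
    }
    th <- th_new
  }
  if (!ok) {
    f <- function(lt) -nb_loglik(y, mu, exp(lt))
    th <- exp(stats::optimize(f, log(.theta_range), tol = 1e-8)$minimum)
  }
  th
}

# IRLS for NB with log link at fixed theta; weighted normal equations
# solved directly (designs here are small).
irls_beta <- function(y, X, theta, beta) {
  for (it in seq_len(50)) {
    eta <- drop(X %*% beta)
    eta[eta > 30] <- 30
    eta[eta < -30] <- -30
    mu <- exp(eta)
    w <- mu / (1 + mu / theta)
    z <- eta + (y - mu) / mu
    A <- crossprod(X, X * w)
    rhs <- crossprod(X, w * z)
    new_beta <- tryCatch(drop(solve(A, rhs)), error = function(e) {
      # near-singular weighted system: tiny ridge, relative to scale
      drop(solve(A + diag(1e-8 * max(diag(A)), ncol(A)), rhs))
    })
    if (max(abs(new_beta - beta)) < 1e-10 * (1 + max(abs(beta)))) {
      beta <- new_beta
      break
    }
    beta <- new_beta
  }
  beta
}

#' Fit a univariate negative binomial GLM with log link
#'
#' Maximum-likelihood fit of NB(mu, Phi) with log mu = X beta, alternating
#' iteratively reweighted least squares for the coefficients at fixed
#' dispersion with profile-likelihood updates of the dispersion, until the
#' log-likelihood stabilizes. The NB convention is mean `mu`, size `Phi`,
#' variance `mu + mu^2 / Phi`.
#'
#' @param y non-negative integer counts.
#' @param X design matrix (including intercept column).
#' @param max_iter maximum outer (beta, Phi) alternations.
#' @param tol relative log-likelihood convergence tolerance.
#' @param engine `"cpp"` (compiled, default) or `"r"`; both implement the
#'   same algorithm and agree to numerical tolerance.
#' @return list with `coefficients`, `theta` (the dispersion Phi),
#'   `loglik`, `fitted` (means mu), `df` (number of free parameters,
#'   coefficients + dispersion), `converged`, `degenerate` (all-zero
#'   response handled at a mean floor), `vcov` (approximate covariance of
#'   the coefficients at fixed Phi).
#' @export
fit_nb_glm <- function(y, X, max_iter = 200, tol = 1e-8,
                       engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (!is.matrix(X)) X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)")
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8)) {
    stop("y must be non-negative integer counts")
  }
  y <- round(y)
  p <- ncol(X)
  if (all(y == 0)) {
    beta <- c(log(.mu_floor), rep(0, p - 1))
    names(beta) <- colnames(X)
    mu <- rep(.mu_floor, length(y))
    theta <- .theta_range[2]
    return(list(coefficients = beta, theta = theta,
                loglik = nb_loglik(y, mu, theta), fitted = mu,
                df = p + 1, converged = TRUE, degenerate = TRUE,
                vcov = matrix(NA_real_, p, p)))
  }
  if (engine == "cpp") {
    core <- .fit_nb_core(y, X, max_iter, tol)
    beta <- drop(core$coefficients)
    names(beta) <- colnames(X)
    return(list(coefficients = beta, theta = core$theta,
                loglik = core$loglik, fitted = drop(core$fitted),
                df = p + 1, converged = core$converged, degenerate = FALSE,
                vcov = core$vcov))
  }
  # R reference engine
  beta <- qr.coef(qr(X), log(y + 0.5))
  if (any(is.na(beta))) beta <- c(log(mean(y) + 0.5), rep(0, p - 1))
  mu <- exp(pmin(pmax(drop(X %*% beta), -30), 30))
  m <- mean(y); v <- stats::var(y)
  theta <- if (is.finite(v) && v > m) m^2 / (v - m) else 100
  theta <- min(max(theta, .theta_range[1]), .theta_range[2])
  ll <- nb_loglik(y, mu, theta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    beta <- irls_beta(y, X, theta, beta)
    mu <- exp(pmin(pmax(drop(X %*% beta), -30), 30))
    theta <- ml_theta(y, mu, theta)
    ll_new <- nb_loglik(y, mu, theta)
    if (abs(ll_new - ll) < tol * (abs(ll) + 1)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  w <- mu / (1 + mu / theta)
  xtwx <- crossprod(X * sqrt(w))
  vc <- tryCatch(solve(xtwx), error = function(e) matrix(NA_real_, p, p))
  names(beta) <- colnames(X)
  list(coefficients = beta, theta = theta, loglik = ll, fitted = mu,
       df = p + 1, converged = converged, degenerate = FALSE, vcov = vc)
}

#' Fit independent NB GLMs to every taxon of a count matrix
#'
#' The multivariate fit is the collection of per-taxon NB GLMs sharing one
#' design matrix; taxa are modeled independently and the model
#' log-likelihood is the sum over taxa. AIC = -2 * total log-likelihood +
#' 2 * total parameter count, counting each taxon's dispersion as a free
#' parameter. All-zero taxa are fit at a mean floor, flagged `degenerate`,
#' and excluded from likelihood-ratio statistics (but kept in the output).
#'
#' @param m `taxon_counts` object.
#' @param spec a [model_spec()].
#' @return object of class `nbfit`: per-taxon coefficients (matrix),
#'   dispersions, log-likelihoods, fitted means, convergence and degeneracy
#'   flags, plus totals `loglik`, `df`, `aic`, the design matrix, and the
#'   data it was fit to.
#' @export
fit_many_glm <- function(m, spec = model_spec()) {
  stopifnot(inherits(m, "taxon_counts"), inherits(spec, "model_spec"))
  X <- spec_design(spec, m$meta)
  J <- length(m$taxa)
  fits <- lapply(seq_len(J), function(j) fit_nb_glm(m$counts[, j], X))
  coefs <- vapply(fits, `[[`, numeric(ncol(X)), "coefficients")
  coefs <- matrix(coefs, nrow = ncol(X),
                  dimnames = list(colnames(X), m$taxa))
  out <- list(
    spec = spec,
    taxa = m$taxa,
    coefficients = coefs,
    theta = stats::setNames(vapply(fits, `[[`, numeric(1), "theta"), m$taxa),
    loglik_taxon = stats::setNames(vapply(fits, `[[`, numeric(1), "loglik"),
                                   m$taxa),
    fitted = matrix(vapply(fits, `[[`, numeric(nrow(X)), "fitted"),
                    nrow = nrow(X), dimnames = list(m$meta$sample_id, m$taxa)),
    converged = stats::setNames(vapply(fits, `[[`, logical(1), "converged"),
                                m$taxa),
    degenerate = stats::setNames(vapply(fits, `[[`, logical(1),
                                        "degenerate"), m$taxa),
    vcov = lapply(fits, `[[`, "vcov"),
    n_obs = nrow(X),
    X = X,
    data = m
  )
  out$df <- sum(vapply(fits, `[[`, numeric(1), "df"))
  out$loglik <- sum(out$loglik_taxon)
  out$aic <- -2 * out$loglik + 2 * out$df
  class(out) <- "nbfit"
  out
}

#' @export
print.nbfit <- function(x, ...) {
  cat("Multivariate NB fit:", format(x$spec), "\n")
  cat(length(x$taxa), "taxa,", x$n_obs, "samples\n")
  cat("logLik =", format(x$loglik, digits = 6), " df =", x$df,
      " AIC =", format(x$aic, digits = 6), "\n")
  if (any(!x$converged)) {
    cat("NOT CONVERGED:", paste(x$taxa[!x$converged], collapse = ", "),
        "(AIC approximate)\n")
  }
  if (any(x$degenerate)) {
    cat("degenerate (all-zero) taxa:",
        paste(x$taxa[x$degenerate], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
logLik.nbfit <- function(object, ...) {
  structure(object$loglik, df = object$df, class = "logLik")
}

#' @export
AIC.nbfit <- function(object, ..., k = 2) {
  -2 * object$loglik + k * object$df
}

# Sum of per-taxon LR over non-degenerate-in-either-fit taxa.
lr_stat <- function(fit_null, fit_alt) {
  keep <- !(fit_null$degenerate | fit_alt$degenerate)
  2 * sum(fit_alt$loglik_taxon[keep] - fit_null$loglik_taxon[keep])
}

# LR statistic from raw pieces, skipping all-zero (degenerate) taxa;
# identical to lr_stat(fit_many_glm(.)) but without container overhead,
# for resampling loops where the design matrices are fixed.
lr_core <- function(counts, X0, X1) {
  lr <- 0
  for (j in seq_len(ncol(counts))) {
    y <- counts[, j]
    if (!any(y > 0)) next
    f1 <- .fit_nb_core(y, X1, 200L, 1e-8)
    f0 <- .fit_nb_core(y, X0, 200L, 1e-8)
    lr <- lr + 2 * (f1$loglik - f0$loglik)
  }
  lr
}

# PIT residual rows under a fit, uniform on the discrete NB mass intervals.
pit_residuals <- function(fit) {
  y <- fit$data$counts
  mu <- pmax(fit$fitted, .mu_floor)
  theta <- rep(fit$theta, each = nrow(y))
  lo <- stats::pnbinom(y - 1, size = theta, mu = mu)
  up <- stats::pnbinom(y, size = theta, mu = mu)
  u <- lo + matrix(stats::runif(length(y)), nrow(y)) * (up - lo)
  pmin(pmax(u, 1e-10), 1 - 1e-10)
}

# One PIT-trap resample: permute whole residual rows (preserving cross-taxon
# correlation), then map back through each observation's null fitted NB.
pit_resample_counts <- function(fit, perm, u) {
  mu <- pmax(fit$fitted, .mu_floor)
  theta <- rep(fit$theta, each = nrow(mu))
  q <- stats::qnbinom(u[perm, , drop = FALSE], size = theta, mu = mu)
  dimnames(q) <- dimnames(fit$data$counts)
  q
}

#' Compare nested abundance models by AIC
#'
#' Fits the null and alternative models to the same samples and reports
#' their AICs, the delta AIC (alternative minus null), the likelihood-ratio
#' statistic, and which model is preferred: the alternative if and only if
#' its AIC is strictly lower (ties favor the null, by parsimony). An
#' optional row-resampling p-value for the LR statistic is computed by
#' refitting both models to datasets regenerated from the null fit with
#' whole rows of probability-integral-transform residuals permuted, which
#' preserves cross-taxon correlation.
#'
#' @param m `taxon_counts` object.
#' @param null_spec,alt_spec nested [model_spec()]s.
#' @param n_resamples number of resampling iterations for the p-value
#'   (0 = no p-value).
#' @param seed integer seed used when `n_resamples > 0`.
#' @return object of class `model_comparison`: `aic_null`, `aic_alt`,
#'   `delta_aic`, `lr`, `p_value`, `n_resamples`, `preferred`, and both
#'   `nbfit` objects.
#' @export
compare_models_aic <- function(m, null_spec = model_spec(),
                               alt_spec = model_spec(c("period", "habitat",
                                                       "location",
                                                       "treatment")),
                               n_resamples = 0, seed = NULL) {
  stopifnot(inherits(m, "taxon_counts"))
  if (!spec_nested(null_spec, alt_spec)) {
    stop("null model must be nested in the alternative model")
  }
  fit0 <- fit_many_glm(m, null_spec)
  fit1 <- fit_many_glm(m, alt_spec)
  lr <- lr_stat(fit0, fit1)
  delta <- fit1$aic - fit0$aic
  p <- NA_real_
  if (n_resamples > 0) {
    if (n_resamples < 99) stop("n_resamples must be >= 99 (or 0)")
    if (is.null(seed)) stop("seed required when resampling")
    p <- with_seed(seed, {
      u <- pit_residuals(fit0)
      n <- fit0$n_obs
      X0 <- fit0$X
      X1 <- fit1$X
      exceed <- 0L
      for (r in seq_len(n_resamples)) {
        ystar <- pit_resample_counts(fit0, sample.int(n), u)
        if (lr_core(ystar, X0, X1) >= lr) exceed <- exceed + 1L
      }
      (1 + exceed) / (1 + n_resamples)
    })
  }
  structure(
    list(aic_null = fit0$aic, aic_alt = fit1$aic, delta_aic = delta,
         lr = lr, p_value = p, n_resamples = n_resamples,
         preferred = if (delta < -1e-9) "alternative" else "null",
         fit_null = fit0, fit_alt = fit1),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  tab <- data.frame(
    model = c(format(x$fit_null$spec), format(x$fit_alt$spec)),
    res_df = x$fit_null$n_obs -
      c(ncol(x$fit_null$X), ncol(x$fit_alt$X)),
    LR = c(NA, x$lr),
    P = c(NA, x$p_value),
    AIC = c(x$aic_null, x$aic_alt),
    delta_AIC = c(0, x$delta_aic)
  )
  print(tab, row.names = FALSE, digits = 5)
  cat("preferred:", x$preferred, "\n")
  invisible(x)
}

#' Analysis of deviance with row-resampling p-values
#'
#' Sequential (type I) tests of each model term: term k is tested by the
#' likelihood-ratio (default) or Wald statistic between the models with
#' terms 1..k-1 and 1..k. P-values come from resampling: datasets are
#' regenerated from the smaller model's fit with whole rows of PIT
#' residuals permuted (preserving cross-taxon correlation), both models are
#' refit, and p = (1 + #\{resampled stat >= observed\}) / (1 + n_resamples).
#'
#' @param m `taxon_counts` object.
#' @param spec [model_spec()] whose terms are tested in order.
#' @param n_resamples resampling iterations per term (>= 99).
#' @param seed integer seed.
#' @param statistic `"LR"` (likelihood ratio, default) or `"wald"`.
#' @return data.frame of class `anova_deviance` with one row per term:
#'   `term`, `df` (coefficients added, per taxon count), `stat`, `p_value`.
#' @export
anova_deviance <- function(m, spec = model_spec(), n_resamples = 199,
                           seed = 1L, statistic = c("LR", "wald")) {
  stopifnot(inherits(m, "taxon_counts"), inherits(spec, "model_spec"))
  statistic <- match.arg(statistic)
  if (n_resamples < 99) stop("n_resamples must be >= 99")
  terms <- spec$terms
  if (!length(terms)) stop("no terms to test")
  res <- data.frame(term = terms, df = NA_real_, stat = NA_real_,
                    p_value = NA_real_)
  for (k in seq_along(terms)) {
    spec0 <- model_spec(terms[seq_len(k - 1)])
    spec1 <- model_spec(terms[seq_len(k)])
    fit0 <- fit_many_glm(m, spec0)
    fit1 <- fit_many_glm(m, spec1)
    obs <- if (statistic == "LR") lr_stat(fit0, fit1)
           else wald_stat(fit1, terms[k])
    res$df[k] <- ncol(fit1$X) - ncol(fit0$X)
    res$stat[k] <- obs
    res$p_value[k] <- with_seed(seed + k, {
      u <- pit_residuals(fit0)
      n <- fit0$n_obs
      exceed <- 0L
      for (r in seq_len(n_resamples)) {
        ystar <- pit_resample_counts(fit0, sample.int(n), u)
        st <- if (statistic == "LR") {
          lr_core(ystar, fit0$X, fit1$X)
        } else {
          mstar <- taxon_counts(ystar, m$meta, m$extrapolated_taxa)
          wald_stat(fit_many_glm(mstar, spec1), terms[k])
        }
        if (st >= obs) exceed <- exceed + 1L
      }
      (1 + exceed) / (1 + n_resamples)
    })
  }
  attr(res, "statistic") <- statistic
  attr(res, "n_resamples") <- n_resamples
  class(res) <- c("anova_deviance", "data.frame")
  res
}

# Multivariate Wald statistic for one term: sum over (non-degenerate) taxa
# of beta_k' V_k^{-1} beta_k over the term's design columns.
wald_stat <- function(fit, term) {
  cols <- grep(paste0("^", term), colnames(fit$X))
  if (!length(cols)) stop("term '", term, "' not in design")
  total <- 0
  for (j in seq_along(fit$taxa)) {
    if (fit$degenerate[j]) next
    b <- fit$coefficients[cols, j]
    V <- fit$vcov[[j]][cols, cols, drop = FALSE]
    w <- tryCatch(drop(t(b) %*% solve(V, b)), error = function(e) NA_real_)
    if (is.finite(w)) total <- total + w
  }
  total
}
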