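# Bootstrap power analyses built on the AIC decision rule: resample whole
# pooled-sample rows with replacement (preserving cross-taxon correlation),
# impose a multiplicative reduction on treated post-treatment counts, refit
# the null and treatment models, and score whether the treatment model wins
# on AIC.

# Fast AIC-delta (alternative minus null) for a resampled count matrix.
# Equivalent to fitting both models with fit_many_glm and differencing the
# AICs: all-zero taxa are degenerate under both models (identical floor
# likelihood), so they contribute only the parameter-count difference.
aic_delta_core <- function(counts, X1, null_cols) {
  X0 <- X1[, null_cols, drop = FALSE]
  J <- ncol(counts)
  lldiff <- 0
  for (j in seq_len(J)) {
    y <- counts[, j]
    if (!any(y > 0)) next
    f1 <- .fit_nb_core(y, X1, 200L, 1e-8)
    f0 <- .fit_nb_core(y, X0, 200L, 1e-8)
    lldiff <- lldiff + (f1$loglik - f0$loglik)
  }
  2 * (ncol(X1) - ncol(X0)) * J - 2 * lldiff
}

# One bootstrap cell: n_reps resamples at a given reduction factor and
# sample-size multiplier. Returns wins, redraw count.
power_cell <- function(m, factor, multiplier, n_reps, null_spec, alt_spec,
                       reduce_rows = "treated_after", max_redraw = 100) {
  n <- nrow(m$counts)
  n_draw <- n * multiplier
  wins <- 0L
  redraws <- 0L
  needed <- unique(c(null_spec$terms, alt_spec$terms))
  for (r in seq_len(n_reps)) {
    delta <- NULL
    for (attempt in seq_len(max_redraw + 1)) {
      idx <- sample.int(n, n_draw, replace = TRUE)
      meta <- m$meta[idx, , drop = FALSE]
      ok <- all(vapply(needed, function(tm)
        length(unique(as.character(meta[[tm]]))) >= 2, logical(1)))
      X1 <- NULL
      if (ok) {
        X1 <- tryCatch(spec_design(alt_spec, meta), error = function(e) NULL)
        ok <- !is.null(X1)
      }
      if (ok) {
        counts <- m$counts[idx, , drop = FALSE]
        hit <- if (reduce_rows == "all") rep(TRUE, n_draw)
               else meta$treatment == "treated" & meta$period == "after"
        counts[hit, ] <- round_half_up(counts[hit, , drop = FALSE] * factor)
        null_pos <- c(0L, match(null_spec$terms, alt_spec$terms))
        null_cols <- attr(X1, "assign") %in% null_pos
        delta <- tryCatch(aic_delta_core(counts, X1, null_cols),
                          error = function(e) NULL)
        if (!is.null(delta)) break
      }
      redraws <- redraws + 1L
    }
    if (is.null(delta)) stop("could not fit a non-degenerate resample ",
                             "after ", max_redraw, " attempts")
    if (delta < -1e-9) wins <- wins + 1L
  }
  c(wins = wins, redraws = redraws)
}

power_grid_core <- function(m, factors, multipliers, n_reps, seed,
                            null_spec, alt_spec, reduce_rows, mode) {
  grid <- expand.grid(factor = factors, multiplier = multipliers)
  grid <- grid[order(grid$factor, grid$multiplier), , drop = FALSE]
  res <- with_seed(seed, {
    t(apply(grid, 1, function(g) {
      power_cell(m, g[["factor"]], g[["multiplier"]], n_reps,
                 null_spec, alt_spec, reduce_rows)
    }))
  })
  out <- data.frame(
    factor = grid$factor,
    reduction = 1 - grid$factor,
    multiplier = grid$multiplier,
    n_reps = n_reps,
    n_wins = res[, "wins"],
    power = res[, "wins"] / n_reps,
    mc_se = sqrt((res[, "wins"] / n_reps) * (1 - res[, "wins"] / n_reps) /
                   n_reps),
    n_redraws = res[, "redraws"],
    row.names = NULL
  )
  attr(out, "seed") <- seed
  attr(out, "mode") <- mode
  attr(out, "null_spec") <- null_spec
  attr(out, "alt_spec") <- alt_spec
  attr(out, "stratified") <- FALSE
  class(out) <- c("power_grid", "data.frame")
  out
}

#' Retrospective bootstrap power analysis
#'
#' Estimates the power of the realized design to detect a multiplicative
#' reduction in treated post-treatment abundance. Each bootstrap run draws
#' pooled samples (whole rows, metadata attached) with replacement from the
#' observed set, multiplies counts of treated-after rows by the reduction
#' factor (rounding half-up to keep integer counts), fits the null and
#' treatment models, and scores a detection when the treatment model has the
#' lower AIC. Power at a factor is the detection fraction over `n_reps`
#' runs. Resamples in which a model factor loses all contrast are redrawn
#' (and counted).
#'
#' @param m `taxon_counts` restricted to one sample type and occasion pair
#'   (see [occasion_subset()]).
#' @param factors grid of reduction factors (retained proportion of
#'   abundance); the study grid is 0.1 to 0.9 in steps of 0.05.
#' @param n_reps bootstrap runs per factor (the study used 10,000; smaller
#'   values give Monte-Carlo SE sqrt(p(1-p)/n_reps)).
#' @param seed integer seed.
#' @param null_spec,alt_spec the nested models of the AIC decision rule.
#' @param reduce_rows `"treated_after"` (the design's impact cell) or
#'   `"all"` (a negative control: reduction applied to every row leaves no
#'   treatment contrast, so "power" collapses to the false-selection rate).
#' @return `power_grid` data.frame: one row per factor with `power`,
#'   `mc_se`, `n_wins`, `n_redraws`.
#' @export
retrospective_power <- function(m, factors = seq(0.1, 0.9, by = 0.05),
                                n_reps = 500, seed = 1L,
                                null_spec = model_spec(),
                                alt_spec = model_spec(c("period", "habitat",
                                                        "location",
                                                        "treatment")),
                                reduce_rows = c("treated_after", "all")) {
  stopifnot(inherits(m, "taxon_counts"), all(factors > 0 & factors <= 1),
            n_reps >= 1)
  reduce_rows <- match.arg(reduce_rows)
  power_grid_core(m, factors, 1L, n_reps, seed, null_spec, alt_spec,
                  reduce_rows, "retrospective")
}

#' Prospective bootstrap power analysis
#'
#' As [retrospective_power()], but each run draws `multiplier x n` rows with
#' replacement, simulating a future study with an enlarged sample size under
#' the observed abundance distribution. With `multipliers = 1` this is the
#' retrospective analysis.
#'
#' @inheritParams retrospective_power
#' @param reductions abundance reductions to detect as retained fractions
#'   (default `c(0.75, 0.5)`: a 25% and a 50% reduction).
#' @param multipliers integer sample-size multipliers (the study used 1-20
#'   for bulk samples, 10-100 by 10 for pitfall samples).
#' @return `power_grid` data.frame with one row per (reduction factor,
#'   multiplier) cell.
#' @export
prospective_power <- function(m, reductions = c(0.75, 0.5),
                              multipliers = 1:20, n_reps = 200, seed = 1L,
                              null_spec = model_spec(),
                              alt_spec = model_spec(c("period", "habitat",
                                                      "location",
                                                      "treatment")),
                              reduce_rows = c("treated_after", "all")) {
  stopifnot(inherits(m, "taxon_counts"),
            all(reductions > 0 & reductions <= 1),
            all(multipliers == round(multipliers) & multipliers >= 1))
  reduce_rows <- match.arg(reduce_rows)
  power_grid_core(m, reductions, as.integer(multipliers), n_reps, seed,
                  null_spec, alt_spec, reduce_rows, "prospective")
}

#' Smallest detectable reduction at a power threshold
#'
#' From a retrospective `power_grid`, the smallest abundance reduction
#' (1 - factor) whose estimated power meets the threshold.
#'
#' @param grid `power_grid` from [retrospective_power()].
#' @param threshold required power (the study's decision rule is 0.80).
#' @return smallest reduction (proportion) with power >= threshold, or `NA`
#'   if none on the grid.
#' @export
detectable_reduction <- function(grid, threshold = 0.8) {
  stopifnot(inherits(grid, "power_grid"))
  ok <- grid$power >= threshold
  if (!any(ok)) return(NA_real_)
  min(grid$reduction[ok])
}

#' Smallest sample-size multiplier reaching a power threshold
#'
#' From a prospective `power_grid`, per reduction factor, the smallest
#' multiplier whose estimated power meets the threshold.
#'
#' @param grid `power_grid` from [prospective_power()].
#' @param threshold required power.
#' @return data.frame with `factor`, `reduction`, `multiplier` (NA when the
#'   threshold is not reached on the grid).
#' @export
required_multiplier <- function(grid, threshold = 0.8) {
  stopifnot(inherits(grid, "power_grid"))
  out <- lapply(split(grid, grid$factor), function(g) {
    ok <- g$power >= threshold
    data.frame(factor = g$factor[1], reduction = g$reduction[1],
               multiplier = if (any(ok)) min(g$multiplier[ok]) else NA_real_)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' @export
print.power_grid <- function(x, ...) {
  cat("Bootstrap power grid (", attr(x, "mode"), "), seed ",
      attr(x, "seed"), ":\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
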