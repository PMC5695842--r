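# Synthetic data emulating the paired-plot BACI field design:
# 13 locations x 2 plots (treated vs control) x 2 habitats; bulk samples at
# 3 occasions; pitfall samples at a 7-location subset (2 occasions) plus a
# 3-location late occasion; ~20 orders with two dominant taxa; NB counts.

#' Configuration for the synthetic BACI dataset generator
#'
#' Defaults reproduce the geometry and abundance structure of the field
#' study the package's analyses are designed for: 13 locations each with a
#' treated and a control plot spanning lawn and forest; bulk samples
#' (2 lawn cores; 2 forest soil + 2 forest litter per plot) at a
#' pre-treatment and two post-treatment occasions; paired pitfall traps at 7
#' locations for pre/post1 and at 3 of those locations for a late post2
#' occasion; 20 taxa with two numerically dominant taxa counted by 15%
#' subsampling and extrapolation; strongly overdispersed counts; one lost
#' bulk litter sample and 7 unsortable pitfall samples.
#'
#' @param n_locations number of experimental locations (paired plots).
#' @param n_taxa number of taxa (arthropod orders).
#' @param intercept per-taxon log baseline mean count of a pooled bulk
#'   sample (reference cell: lawn, pre-treatment, average location). Default
#'   gives two dominant taxa (means ~570 and ~170) and 18 minor taxa with
#'   means between 0.5 and 8, mirroring strongly skewed order abundances.
#' @param habitat_effect per-taxon log-scale effect of forest vs. lawn.
#' @param occasion_effect named log-scale shifts for `post1` and `post2`
#'   occasions relative to `pre`, common to all taxa (seasonal drift).
#' @param sigma_location SD of the Normal(0, sigma) location effects, shared
#'   by the paired plots at a location and by all taxa.
#' @param treatment_multiplier multiplicative effect applied to mean counts
#'   of treated plots after treatment; 1 means no effect; may be a scalar or
#'   a per-taxon vector.
#' @param dispersion per-taxon NB dispersion (size) Phi; variance is
#'   mu + mu^2/Phi, so smaller Phi means stronger overdispersion.
#' @param pitfall_scale multiplier on mean counts for pitfall samples, which
#'   catch far fewer individuals than bulk extraction.
#' @param subsample_fraction fraction of each bulk sample counted for the
#'   dominant taxa (their totals are extrapolated); set `NULL` to disable.
#' @param n_dominant number of dominant (subsampled) taxa.
#' @param pitfall_locations number of locations with pitfall sampling at
#'   pre/post1.
#' @param pitfall_extra_locations number of those locations with the extra
#'   late (post2) pitfall occasion.
#' @param n_lost_bulk,n_lost_pitfall raw samples lost (bulk forest litter)
#'   or too dirty to sort (pitfall), removed at random without emptying any
#'   pooled cell.
#' @param seed integer seed making the dataset reproducible.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_locations = 13,
                             n_taxa = 20,
                             intercept = NULL,
                             habitat_effect = NULL,
                             occasion_effect = c(post1 = -0.2, post2 = -0.4),
                             sigma_location = 0.5,
                             treatment_multiplier = 1,
                             dispersion = rep(1, n_taxa),
                             pitfall_scale = 0.05,
                             subsample_fraction = 0.15,
                             n_dominant = 2,
                             pitfall_locations = 7,
                             pitfall_extra_locations = 3,
                             n_lost_bulk = 1,
                             n_lost_pitfall = 7,
                             seed = 1L) {
  if (is.null(intercept)) {
    minor <- seq(log(0.5), log(8), length.out = n_taxa - n_dominant)
    intercept <- c(log(570), log(170), rep(log(20), max(0, n_dominant - 2)),
                   minor)[seq_len(n_taxa)]
  }
  if (is.null(habitat_effect)) {
    habitat_effect <- rep(c(0.6, -0.6), length.out = n_taxa)
  }
  dispersion <- rep_len(dispersion, n_taxa)
  treatment_multiplier <- rep_len(treatment_multiplier, n_taxa)
  if (any(dispersion <= 0)) stop("dispersion must be > 0")
  if (any(treatment_multiplier < 0)) {
    stop("treatment_multiplier must be >= 0")
  }
  if (pitfall_locations > n_locations ||
      pitfall_extra_locations > pitfall_locations) {
    stop("pitfall location counts inconsistent with n_locations")
  }
  taxa <- sprintf("taxon_%02d", seq_len(n_taxa))
  structure(
    list(n_locations = n_locations, n_taxa = n_taxa, taxa = taxa,
         intercept = intercept, habitat_effect = habitat_effect,
         occasion_effect = occasion_effect,
         sigma_location = sigma_location,
         treatment_multiplier = treatment_multiplier,
         dispersion = dispersion, pitfall_scale = pitfall_scale,
         subsample_fraction = subsample_fraction,
         n_dominant = n_dominant,
         pitfall_locations = pitfall_locations,
         pitfall_extra_locations = pitfall_extra_locations,
         n_lost_bulk = n_lost_bulk, n_lost_pitfall = n_lost_pitfall,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Evaluate an expression with a local, restored RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# Raw-sample metadata for the full design, before losses: one row per raw
# component sample, with the pooled-cell id and expected components per cell.
design_raw_meta <- function(cfg) {
  loc <- sprintf("loc%02d", seq_len(cfg$n_locations))
  plots <- expand.grid(location = loc, treatment = .treatment_levels,
                       stringsAsFactors = FALSE)
  bulk_cells <- merge(merge(plots, data.frame(habitat = .habitat_levels)),
                      data.frame(occasion = .occasion_levels))
  bulk_cells$sample_type <- "bulk"
  pit_loc <- loc[seq_len(cfg$pitfall_locations)]
  pit_extra <- loc[seq_len(cfg$pitfall_extra_locations)]
  pit_cells <- rbind(
    merge(merge(plots[plots$location %in% pit_loc, ],
                data.frame(habitat = .habitat_levels)),
          data.frame(occasion = c("pre", "post1"))),
    merge(merge(plots[plots$location %in% pit_extra, ],
                data.frame(habitat = .habitat_levels)),
          data.frame(occasion = "post2"))
  )
  pit_cells$sample_type <- rep("pitfall", nrow(pit_cells))
  cells <- rbind(bulk_cells, pit_cells)

  expand_cell <- function(cell) {
    comps <- if (cell$sample_type == "pitfall") {
      rep("pitfall", 2)
    } else if (cell$habitat == "lawn") {
      rep("lawn_core", 2)
    } else {
      c("forest_soil", "forest_soil", "forest_litter", "forest_litter")
    }
    k <- length(comps)
    data.frame(cell[rep(1, k), , drop = FALSE],
               component = comps,
               stratum = rep(c("edge", "interior"), length.out = k),
               n_components = k,
               row.names = NULL)
  }
  raw <- do.call(rbind, lapply(seq_len(nrow(cells)),
                               function(i) expand_cell(cells[i, ])))
  raw$cell_id <- with(raw, paste(location, treatment, habitat, occasion,
                                 sample_type, sep = "_"))
  raw$sample_id <- paste(raw$cell_id,
                         ave(seq_len(nrow(raw)), raw$cell_id,
                             FUN = seq_along),
                         sep = "_")
  raw
}

# Drop lost bulk-litter and unsortable pitfall raw samples at random,
# never emptying a pooled cell.
apply_losses <- function(raw, cfg) {
  drop <- integer()
  pick <- function(candidates, n) {
    chosen <- integer()
    for (k in seq_len(n)) {
      cand <- setdiff(candidates, chosen)
      # keep at least one raw sample per pooled cell
      ok <- vapply(cand, function(i) {
        sum(raw$cell_id == raw$cell_id[i] &
              !(seq_len(nrow(raw)) %in% c(chosen, i))) >= 1
      }, logical(1))
      cand <- cand[ok]
      if (!length(cand)) break
      chosen <- c(chosen, if (length(cand) == 1) cand else sample(cand, 1))
    }
    chosen
  }
  drop <- c(drop, pick(which(raw$component == "forest_litter"),
                       cfg$n_lost_bulk))
  drop <- c(drop, pick(which(raw$component == "pitfall"),
                       cfg$n_lost_pitfall))
  if (length(drop)) raw[-drop, , drop = FALSE] else raw
}

#' Simulate a raw and pooled BACI count dataset
#'
#' Draws negative binomial counts for every raw component sample under the
#' log-linear abundance model (taxon intercept + occasion + habitat +
#' shared location effect + log treatment multiplier for treated plots
#' after treatment), applies the subsample-count-then-extrapolate protocol
#' to the dominant taxa in bulk samples, removes lost samples, and pools
#' via [pool_samples()]. Reproducible: the same config (including its seed)
#' yields byte-identical output.
#'
#' @param cfg a [synthetic_config()].
#' @return list with elements `raw` and `pooled` (both [taxon_counts()]),
#'   `config`, and `location_effect` (the simulated per-location effects).
#' @export
simulate_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    raw <- design_raw_meta(cfg)
    loc_eff <- stats::rnorm(cfg$n_locations, 0, cfg$sigma_location)
    names(loc_eff) <- sprintf("loc%02d", seq_len(cfg$n_locations))
    raw <- apply_losses(raw, cfg)
    n <- nrow(raw)
    eta_base <- loc_eff[raw$location] +
      ifelse(raw$occasion == "pre", 0,
             cfg$occasion_effect[raw$occasion]) +
      log(ifelse(raw$sample_type == "pitfall", cfg$pitfall_scale, 1)) -
      log(raw$n_components)
    treated_after <- raw$treatment == "treated" & raw$occasion != "pre"
    counts <- matrix(0, n, cfg$n_taxa,
                     dimnames = list(raw$sample_id, cfg$taxa))
    for (j in seq_len(cfg$n_taxa)) {
      eta <- eta_base + cfg$intercept[j] +
        ifelse(raw$habitat == "forest", cfg$habitat_effect[j], 0) +
        ifelse(treated_after, log(cfg$treatment_multiplier[j]), 0)
      y <- stats::rnbinom(n, size = cfg$dispersion[j], mu = exp(eta))
      counts[, j] <- y
    }
    dominant <- cfg$taxa[seq_len(cfg$n_dominant)]
    if (!is.null(cfg$subsample_fraction) && cfg$n_dominant > 0) {
      f <- cfg$subsample_fraction
      bulk <- raw$sample_type == "bulk"
      for (j in dominant) {
        sub <- stats::rbinom(sum(bulk), size = counts[bulk, j], prob = f)
        counts[bulk, j] <- extrapolate_subsample(sub, f)
      }
    }
    meta_cols <- c("sample_id", "location", "treatment", "habitat",
                   "occasion", "sample_type", "stratum", "component")
    raw_tc <- taxon_counts(counts, raw[meta_cols],
                           extrapolated_taxa = if (!is.null(cfg$subsample_fraction)) dominant else character())
    pooled <- suppressWarnings(pool_samples(raw_tc))
    list(raw = raw_tc, pooled = pooled, config = cfg,
         location_effect = loc_eff)
  })
}

#' Total treated area of the experimental design
#'
#' Design arithmetic: one square treated plot per location.
#'
#' @param n_locations number of locations (each with one treated plot).
#' @param plot_side_m side length of a treated plot in meters.
#' @return total treated area in square meters (832 for the default
#'   13-location, 8 m design).
#' @export
treated_area_m2 <- function(n_locations = 13, plot_side_m = 8) {
  stopifnot(n_locations >= 0, plot_side_m >= 0)
  n_locations * plot_side_m^2
}

#' Per-taxon variance-to-mean ratios
#'
#' A quick overdispersion diagnostic: under the package's NB convention
#' (variance mu + mu^2/Phi) the ratio is 1 + mu/Phi, so values well above 1
#' indicate overdispersion relative to Poisson.
#'
#' @param m `taxon_counts` object with at least two samples.
#' @return named numeric vector of variance/mean ratios; `NA` for constant
#'   (including all-zero) taxa, for which the ratio carries no information.
#' @export
dispersion_check <- function(m) {
  stopifnot(inherits(m, "taxon_counts"))
  if (nrow(m$counts) < 2) stop("need at least 2 samples")
  mu <- colMeans(m$counts)
  v <- apply(m$counts, 2, stats::var)
  ratio <- ifelse(mu > 0 & v > 0, v / mu, NA_real_)
  names(ratio) <- m$taxa
  ratio
}
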