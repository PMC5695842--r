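# Orchestration: pool -> model comparison -> analysis of deviance -> BACI
# -> power, from a single configuration, with seeded determinism and a
# machine-readable run log.

#' Build an analysis configuration
#'
#' Describes a full BACI analysis run: the data source (CSV paths for raw
#' or pooled counts, or a synthetic-data configuration), the per-analysis
#' model comparisons, and optional power-analysis settings. The default
#' analyses mirror the standard four: bulk and pitfall samples, each
#' compared pre vs. first post-treatment occasion and pre vs. second
#' post-treatment occasion; the late pitfall comparison omits location
#' (few locations carry the late occasion).
#'
#' @param input either a list with `raw_csv` or `pooled_csv` path, or a
#'   [synthetic_config()] (default: synthetic data with the design
#'   defaults).
#' @param analyses list of analysis descriptors, each a list with
#'   `sample_type`, `occasion_pair`, `null_terms`, `alt_terms`.
#' @param anova_resamples resampling iterations for analysis of deviance
#'   (0 disables the deviance tables).
#' @param power list or NULL; when a list, fields `mode`
#'   (`"retrospective"`, `"prospective"` or both), `factors`, `reductions`,
#'   `multipliers`, `n_reps`, `sample_type`, `occasion_pair`.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(input = synthetic_config(),
                            analyses = default_analyses(),
                            anova_resamples = 0,
                            power = NULL,
                            seed = 1L) {
  for (a in analyses) {
    stopifnot(is.list(a), a$sample_type %in% .sample_type_levels,
              length(a$occasion_pair) == 2)
    bad <- setdiff(a$occasion_pair, .occasion_levels)
    if (length(bad)) {
      stop("unknown occasion(s) in analysis config: ",
           paste(bad, collapse = ", "))
    }
    model_spec(a$null_terms)
    model_spec(a$alt_terms)
  }
  structure(list(input = input, analyses = analyses,
                 anova_resamples = anova_resamples, power = power,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' The standard four BACI model comparisons
#'
#' Bulk samples pre vs. each of two post occasions with the full null model
#' (period + habitat + location); pitfall samples pre vs. first post with
#' the full null; pitfall pre vs. the late occasion with period + habitat
#' only (the late occasion runs at a small location subset, leaving
#' location poorly identified).
#'
#' @return list of analysis descriptors for [analysis_config()].
#' @export
default_analyses <- function() {
  full_null <- c("period", "habitat", "location")
  list(
    list(sample_type = "bulk", occasion_pair = c("pre", "post1"),
         null_terms = full_null, alt_terms = c(full_null, "treatment")),
    list(sample_type = "bulk", occasion_pair = c("pre", "post2"),
         null_terms = full_null, alt_terms = c(full_null, "treatment")),
    list(sample_type = "pitfall", occasion_pair = c("pre", "post1"),
         null_terms = full_null, alt_terms = c(full_null, "treatment")),
    list(sample_type = "pitfall", occasion_pair = c("pre", "post2"),
         null_terms = c("period", "habitat"),
         alt_terms = c("period", "habitat", "treatment"))
  )
}

#' Read an analysis configuration from YAML
#'
#' The YAML mirrors [analysis_config()]: top-level keys `input` (either
#' `raw_csv`/`pooled_csv` paths or `synthetic: {...}` fields passed to
#' [synthetic_config()]), `analyses`, `anova_resamples`, `power`, `seed`.
#'
#' @param path YAML file path.
#' @return `analysis_config` object.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  input <- if (!is.null(y$input$synthetic)) {
    do.call(synthetic_config, y$input$synthetic)
  } else if (!is.null(y$input)) {
    y$input
  } else {
    synthetic_config()
  }
  analyses <- if (is.null(y$analyses)) default_analyses() else
    lapply(y$analyses, function(a) {
      a$occasion_pair <- unlist(a$occasion_pair)
      a$null_terms <- unlist(a$null_terms)
      a$alt_terms <- unlist(a$alt_terms)
      a
    })
  analysis_config(input = input, analyses = analyses,
                  anova_resamples = y$anova_resamples %||% 0,
                  power = y$power,
                  seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Load or simulate the pooled dataset named by a config.
resolve_input <- function(cfg) {
  input <- cfg$input
  if (inherits(input, "synthetic_config")) {
    sim <- simulate_dataset(input)
    list(pooled = sim$pooled, raw = sim$raw, source = "synthetic")
  } else if (!is.null(input$pooled_csv)) {
    list(pooled = read_count_table(input$pooled_csv, input$schema),
         raw = NULL, source = input$pooled_csv)
  } else if (!is.null(input$raw_csv)) {
    raw <- read_count_table(input$raw_csv, input$schema)
    list(pooled = pool_samples(raw), raw = raw, source = input$raw_csv)
  } else {
    stop("config input must be a synthetic_config or name raw_csv/pooled_csv")
  }
}

#' Run the full BACI analysis pipeline
#'
#' Resolves the input data (reading CSVs and pooling, or simulating), then
#' for each configured analysis runs the AIC model comparison, the analysis
#' of deviance (optional), the BACI effects, and the category summaries;
#' then any configured power analyses. Every stochastic stage uses a seed
#' derived from the master seed, so reruns with the same config are
#' identical. When `outdir` is given, writes per-analysis CSVs (model
#' comparison, deviance, BACI, category means), power grids, and a JSON run
#' log of seeds, rep counts, and warnings.
#'
#' @param cfg [analysis_config()].
#' @param outdir optional output directory (created if needed).
#' @return list of class `baci_report`: `data` (pooled `taxon_counts`),
#'   `analyses` (per-analysis results), `power`, `log`.
#' @export
run_baci_analysis <- function(cfg = analysis_config(), outdir = NULL) {
  stopifnot(inherits(cfg, "analysis_config"))
  run_log <- list(seed = cfg$seed, warnings = list())
  note <- function(stage, msg) {
    run_log$warnings[[length(run_log$warnings) + 1]] <<-
      list(stage = stage, message = msg)
  }
  dat <- withCallingHandlers(
    resolve_input(cfg),
    warning = function(w) {
      note("input", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  pooled <- dat$pooled
  run_log$source <- dat$source
  run_log$n_pooled_samples <- nrow(pooled$counts)
  run_log$n_taxa <- length(pooled$taxa)

  analyses <- vector("list", length(cfg$analyses))
  for (i in seq_along(cfg$analyses)) {
    a <- cfg$analyses[[i]]
    label <- paste0(a$sample_type, "_",
                    paste(a$occasion_pair, collapse = "_"))
    sub <- tryCatch(
      occasion_subset(pooled, a$sample_type, a$occasion_pair),
      error = function(e) {
        stop("analysis stage '", label, "': ", conditionMessage(e))
      })
    cmp <- compare_models_aic(sub, model_spec(a$null_terms),
                              model_spec(a$alt_terms))
    dev <- NULL
    if (cfg$anova_resamples > 0) {
      dev <- anova_deviance(sub, model_spec(a$null_terms),
                            n_resamples = cfg$anova_resamples,
                            seed = cfg$seed + 100L + i)
    }
    baci <- withCallingHandlers(
      baci_effect(sub, a$occasion_pair),
      warning = function(w) {
        note(label, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    analyses[[i]] <- list(label = label, sample_type = a$sample_type,
                          occasion_pair = a$occasion_pair,
                          comparison = cmp, deviance = dev, baci = baci,
                          categories = category_summary(sub))
    if (any(!cmp$fit_null$converged) || any(!cmp$fit_alt$converged)) {
      note(label, "non-converged taxa; AIC approximate")
    }
  }
  names(analyses) <- vapply(analyses, `[[`, character(1), "label")

  power_res <- NULL
  if (!is.null(cfg$power)) {
    p <- cfg$power
    sub <- occasion_subset(pooled, p$sample_type %||% "bulk",
                           p$occasion_pair %||% c("pre", "post1"))
    null_spec <- model_spec(p$null_terms %||%
                              c("period", "habitat", "location"))
    alt_spec <- model_spec(p$alt_terms %||%
                             c(null_spec$terms, "treatment"))
    power_res <- list()
    modes <- p$mode %||% "retrospective"
    if ("retrospective" %in% modes) {
      power_res$retrospective <- retrospective_power(
        sub, factors = p$factors %||% seq(0.1, 0.9, by = 0.05),
        n_reps = p$n_reps %||% 500, seed = cfg$seed + 1000L,
        null_spec = null_spec, alt_spec = alt_spec)
      power_res$detectable_reduction <-
        detectable_reduction(power_res$retrospective)
    }
    if ("prospective" %in% modes) {
      power_res$prospective <- prospective_power(
        sub, reductions = p$reductions %||% c(0.75, 0.5),
        multipliers = p$multipliers %||% 1:20,
        n_reps = p$n_reps %||% 200, seed = cfg$seed + 2000L,
        null_spec = null_spec, alt_spec = alt_spec)
      power_res$required_multiplier <-
        required_multiplier(power_res$prospective)
    }
  }

  report <- structure(list(data = pooled, analyses = analyses,
                           power = power_res, log = run_log),
                      class = "baci_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

# Serialize a report bundle as CSV/JSON files.
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  comparison_rows <- list()
  for (a in report$analyses) {
    cmp <- a$comparison
    comparison_rows[[a$label]] <- data.frame(
      analysis = a$label,
      model = c(format(cmp$fit_null$spec), format(cmp$fit_alt$spec)),
      res_df = cmp$fit_null$n_obs - c(ncol(cmp$fit_null$X),
                                      ncol(cmp$fit_alt$X)),
      lr = c(NA, cmp$lr), p_value = c(NA, cmp$p_value),
      aic = c(cmp$aic_null, cmp$aic_alt),
      delta_aic = c(0, cmp$delta_aic),
      preferred = cmp$preferred
    )
    if (!is.null(a$deviance)) {
      utils::write.csv(a$deviance,
                       file.path(outdir, paste0("deviance_", a$label,
                                                ".csv")),
                       row.names = FALSE)
    }
    utils::write.csv(a$baci$effects,
                     file.path(outdir, paste0("baci_", a$label, ".csv")),
                     row.names = FALSE)
    utils::write.csv(a$categories$by_occasion,
                     file.path(outdir, paste0("categories_", a$label,
                                              ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(do.call(rbind, c(comparison_rows,
                                    list(make.row.names = FALSE))),
                   file.path(outdir, "model_comparisons.csv"),
                   row.names = FALSE)
  if (!is.null(report$power)) {
    for (mode in intersect(c("retrospective", "prospective"),
                           names(report$power))) {
      utils::write.csv(as.data.frame(report$power[[mode]]),
                       file.path(outdir, paste0("power_", mode, ".csv")),
                       row.names = FALSE)
    }
    summ <- list()
    if (!is.null(report$power$detectable_reduction)) {
      summ$detectable_reduction_80pct <- report$power$detectable_reduction
    }
    if (!is.null(report$power$required_multiplier)) {
      summ$required_multiplier_80pct <- report$power$required_multiplier
    }
    jsonlite::write_json(summ, file.path(outdir, "power_summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  jsonlite::write_json(report$log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(outdir)
}

#' @export
print.baci_report <- function(x, ...) {
  cat("BACI analysis report (seed ", x$log$seed, ", source: ",
      x$log$source, ")\n", sep = "")
  cat(x$log$n_pooled_samples, "pooled samples,", x$log$n_taxa, "taxa\n\n")
  for (a in x$analyses) {
    cat("--", a$label, "--\n")
    print(a$comparison)
    cat("\n")
  }
  if (!is.null(x$power$detectable_reduction)) {
    cat("smallest reduction detectable at 80% power:",
        x$power$detectable_reduction, "\n")
  }
  invisible(x)
}
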