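# Before-After-Control-Impact effects on mean counts, with standard errors
# taken over the (location, habitat) replicate set.

#' Inverse hyperbolic sine scale
#'
#' `asinh(x) = log(x + sqrt(x^2 + 1))`: a signed log-like transform that is
#' defined at and antisymmetric around zero, used for plotting BACI effects
#' spanning several orders of magnitude in either direction.
#'
#' @param x numeric vector.
#' @return `asinh(x)`.
#' @export
asinh_scale <- function(x) asinh(x)

#' Before-After-Control-Impact effect per taxon
#'
#' For each (location, habitat) replicate, mean counts are formed in the
#' four cells treatment x period, and the replicate BACI value is
#' (treated_after - control_after) - (treated_before - control_before).
#' The per-taxon effect is the mean of the replicate values and its
#' standard error is their sample SD divided by sqrt(number of replicates).
#' Replicates missing any of the four cells are dropped with a warning.
#'
#' @param m `taxon_counts` object (pooled samples).
#' @param occasion_pair the before/after occasions, e.g. `c("pre", "post1")`.
#' @param sample_type optional sample type to restrict to first.
#' @return object of class `baci_result`: data.frame `effects` (taxon,
#'   mean_abundance, effect, se, n_replicates), matrix `replicates`
#'   (replicate x taxon BACI values), and the comparison label.
#' @export
baci_effect <- function(m, occasion_pair = c("pre", "post1"),
                        sample_type = NULL) {
  stopifnot(inherits(m, "taxon_counts"), length(occasion_pair) == 2)
  if (!is.null(sample_type)) {
    m <- subset_samples(m, m$meta$sample_type == sample_type)
  }
  m <- subset_samples(m, m$meta$occasion %in% occasion_pair)
  meta <- m$meta
  rep_key <- paste(meta$location, meta$habitat, sep = ":")
  cell_of <- function(trt, per) meta$treatment == trt & meta$period == per
  reps <- sort(unique(rep_key))
  rep_rows <- lapply(reps, function(rk) {
    idx <- which(rep_key == rk)
    cells <- list(ta = idx[cell_of("treated", "after")[idx]],
                  ca = idx[cell_of("control", "after")[idx]],
                  tb = idx[cell_of("treated", "before")[idx]],
                  cb = idx[cell_of("control", "before")[idx]])
    if (any(lengths(cells) == 0)) NULL else cells
  })
  complete <- !vapply(rep_rows, is.null, logical(1))
  if (any(!complete)) {
    warning(sum(!complete), " incomplete (location, habitat) replicate(s) ",
            "dropped: ", paste(reps[!complete], collapse = ", "))
  }
  reps <- reps[complete]
  rep_rows <- rep_rows[complete]
  if (!length(reps)) stop("no complete replicates for the BACI contrast")
  cmean <- function(idx) colMeans(m$counts[idx, , drop = FALSE])
  repvals <- t(vapply(rep_rows, function(cl) {
    (cmean(cl$ta) - cmean(cl$ca)) - (cmean(cl$tb) - cmean(cl$cb))
  }, numeric(length(m$taxa))))
  rownames(repvals) <- reps
  colnames(repvals) <- m$taxa
  n_rep <- length(reps)
  eff <- colMeans(repvals)
  se <- if (n_rep >= 2) apply(repvals, 2, stats::sd) / sqrt(n_rep)
        else rep(NA_real_, length(m$taxa))
  out <- list(
    effects = data.frame(taxon = m$taxa,
                         mean_abundance = colMeans(m$counts),
                         effect = eff, se = se, n_replicates = n_rep,
                         row.names = NULL),
    replicates = repvals,
    occasion_pair = occasion_pair,
    sample_type = if (is.null(sample_type))
      paste(sort(unique(as.character(meta$sample_type))), collapse = "+")
    else sample_type
  )
  class(out) <- "baci_result"
  out
}

#' @export
print.baci_result <- function(x, ...) {
  cat("BACI effects (", x$sample_type, ", ",
      paste(x$occasion_pair, collapse = " vs "), "), ",
      x$effects$n_replicates[1], " replicates:\n", sep = "")
  print(x$effects, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Mean and standard error of abundance per design category
#'
#' Per-taxon mean abundance and SE over pooled samples within each
#' (period, treatment) and each (occasion, treatment) category — the
#' summaries behind abundance-trajectory figures and BACI tables.
#'
#' @param m `taxon_counts` object.
#' @return list of two data.frames, `by_period` and `by_occasion`, in long
#'   format: taxon, category columns, `n`, `mean`, `se` (`NA` when a
#'   category has a single sample).
#' @export
category_summary <- function(m) {
  stopifnot(inherits(m, "taxon_counts"))
  summarize_by <- function(keys) {
    key <- do.call(paste, c(lapply(m$meta[keys], as.character), sep = "|"))
    groups <- split(seq_len(nrow(m$counts)), key)
    do.call(rbind, lapply(names(groups), function(g) {
      idx <- groups[[g]]
      lab <- strsplit(g, "|", fixed = TRUE)[[1]]
      mu <- colMeans(m$counts[idx, , drop = FALSE])
      se <- if (length(idx) >= 2) {
        apply(m$counts[idx, , drop = FALSE], 2, stats::sd) /
          sqrt(length(idx))
      } else rep(NA_real_, length(m$taxa))
      out <- data.frame(taxon = m$taxa, n = length(idx), mean = mu, se = se,
                        row.names = NULL)
      for (i in seq_along(keys)) out[[keys[i]]] <- lab[i]
      out[c("taxon", keys, "n", "mean", "se")]
    }))
  }
  list(by_period = summarize_by(c("period", "treatment")),
       by_occasion = summarize_by(c("occasion", "treatment")))
}

#' Plot BACI effects on an inverse hyperbolic sine scale
#'
#' Point-and-error-bar plot of per-taxon BACI effects with +/- 1 SE ranges,
#' on the asinh scale (signed, log-like, defined at zero). Requires
#' ggplot2.
#'
#' @param x `baci_result` from [baci_effect()].
#' @return a ggplot object.
#' @export
plot_baci <- function(x) {
  stopifnot(inherits(x, "baci_result"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_baci requires the ggplot2 package")
  }
  df <- x$effects
  df$lo <- asinh_scale(df$effect - df$se)
  df$hi <- asinh_scale(df$effect + df$se)
  df$mid <- asinh_scale(df$effect)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$taxon, y = .data$mid)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo,
                                          ymax = .data$hi)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "BACI effect (asinh scale)",
                  title = paste0(x$sample_type, ": ",
                                 paste(x$occasion_pair,
                                       collapse = " vs "))) +
    ggplot2::theme_minimal()
}
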