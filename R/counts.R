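#' @keywords internal
#' @useDynLib bacinb, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Canonical factor levels for the BACI design metadata.
.treatment_levels <- c("treated", "control")
.habitat_levels <- c("lawn", "forest")
.occasion_levels <- c("pre", "post1", "post2")
.sample_type_levels <- c("bulk", "pitfall")
.component_levels <- c("lawn_core", "forest_soil", "forest_litter", "pitfall")
.meta_required <- c("sample_id", "location", "treatment", "habitat",
                    "occasion", "sample_type")
.meta_optional <- c("stratum", "component")

#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going away from zero, the
#' convention used when integerizing extrapolated or reduction-scaled counts
#' before negative binomial fitting (counts are non-negative, so this is
#' round half-up).
#'
#' @param x numeric vector.
#' @return numeric vector of integers (as doubles).
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Derive period (before/after) from sampling occasion
#'
#' The design has one pre-treatment occasion and up to two post-treatment
#' occasions; `period` is `"before"` exactly for the pre-treatment occasion.
#'
#' @param occasion character or factor of occasion labels (`pre`, `post1`,
#'   `post2`).
#' @return factor with levels `before`, `after`.
#' @export
period_from_occasion <- function(occasion) {
  factor(ifelse(as.character(occasion) == "pre", "before", "after"),
         levels = c("before", "after"))
}

#' Construct a taxon count matrix with sample metadata
#'
#' The central container of the package: a samples-by-taxa matrix of
#' non-negative counts together with one row of design metadata per sample.
#' Metadata carry the BACI design factors (location, treatment, habitat,
#' occasion, derived period, sample type) plus optional stratum and raw
#' component labels.
#'
#' @param counts numeric matrix (samples x taxa) of non-negative counts, or a
#'   data.frame coercible to one. Column names are taxon labels.
#' @param meta data.frame with one row per sample; required columns
#'   `sample_id`, `location`, `treatment`, `habitat`, `occasion`,
#'   `sample_type`; optional `stratum`, `component`. A `period` column is
#'   derived from `occasion` and need not be supplied.
#' @param extrapolated_taxa character vector naming taxa whose counts were
#'   scaled up from counted subsamples.
#' @return object of class `taxon_counts`: a list with elements `counts`,
#'   `taxa`, `meta`, `extrapolated_taxa`.
#' @export
taxon_counts <- function(counts, meta, extrapolated_taxa = character()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.meta_required, names(meta))
  if (length(missing_cols)) {
    stop("missing metadata column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(counts) != nrow(meta)) {
    stop("counts has ", nrow(counts), " rows but meta has ", nrow(meta))
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicated sample_id in metadata")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  if (is.null(colnames(counts))) {
    stop("counts must have taxon column names")
  }
  check_level <- function(x, levels, what) {
    bad <- setdiff(unique(as.character(x)), levels)
    if (length(bad)) {
      stop("unknown ", what, " level(s): ", paste(bad, collapse = ", "))
    }
    factor(as.character(x), levels = levels)
  }
  meta$sample_id <- as.character(meta$sample_id)
  meta$location <- factor(as.character(meta$location))
  meta$treatment <- check_level(meta$treatment, .treatment_levels, "treatment")
  meta$habitat <- check_level(meta$habitat, .habitat_levels, "habitat")
  meta$occasion <- check_level(meta$occasion, .occasion_levels, "occasion")
  meta$sample_type <- check_level(meta$sample_type, .sample_type_levels,
                                  "sample_type")
  if (!is.null(meta$component) && !all(is.na(meta$component))) {
    meta$component <- check_level(meta$component, .component_levels,
                                  "component")
  }
  meta$period <- period_from_occasion(meta$occasion)
  extrapolated_taxa <- as.character(extrapolated_taxa)
  bad_taxa <- setdiff(extrapolated_taxa, colnames(counts))
  if (length(bad_taxa)) {
    stop("extrapolated taxa not in matrix: ", paste(bad_taxa, collapse = ", "))
  }
  ord_taxa <- order(colnames(counts))
  counts <- counts[, ord_taxa, drop = FALSE]
  ord <- order(meta$location, meta$treatment, meta$habitat, meta$occasion,
               meta$sample_id)
  counts <- counts[ord, , drop = FALSE]
  meta <- meta[ord, , drop = FALSE]
  rownames(counts) <- meta$sample_id
  rownames(meta) <- NULL
  structure(
    list(counts = counts, taxa = colnames(counts), meta = meta,
         extrapolated_taxa = sort(extrapolated_taxa)),
    class = "taxon_counts"
  )
}

#' @export
print.taxon_counts <- function(x, ...) {
  cat("taxon_counts: ", nrow(x$counts), " samples x ", length(x$taxa),
      " taxa\n", sep = "")
  cat("sample types:",
      paste(names(table(x$meta$sample_type)), table(x$meta$sample_type),
            sep = "=", collapse = ", "), "\n")
  cat("occasions:",
      paste(names(table(x$meta$occasion)), table(x$meta$occasion),
            sep = "=", collapse = ", "), "\n")
  if (length(x$extrapolated_taxa)) {
    cat("extrapolated taxa:", paste(x$extrapolated_taxa, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.taxon_counts <- function(x) dim(x$counts)

#' Subset a taxon count matrix by sample
#'
#' @param m `taxon_counts` object.
#' @param keep logical or integer index over samples (rows).
#' @return `taxon_counts` restricted to the selected samples.
#' @export
subset_samples <- function(m, keep) {
  stopifnot(inherits(m, "taxon_counts"))
  taxon_counts(m$counts[keep, , drop = FALSE], m$meta[keep, , drop = FALSE],
               m$extrapolated_taxa)
}

#' Restrict to one sample type and a pair of occasions
#'
#' Convenience wrapper for the four per-analysis data subsets (bulk or
#' pitfall crossed with pre vs. first or second post-treatment occasion).
#'
#' @param m `taxon_counts` object.
#' @param sample_type `"bulk"` or `"pitfall"`.
#' @param occasion_pair character vector of length 2, e.g. `c("pre", "post1")`.
#' @return `taxon_counts` restricted to matching samples.
#' @export
occasion_subset <- function(m, sample_type, occasion_pair) {
  stopifnot(inherits(m, "taxon_counts"), length(occasion_pair) == 2)
  keep <- m$meta$sample_type == sample_type &
    m$meta$occasion %in% occasion_pair
  if (!any(keep)) {
    stop("no samples of type ", sample_type, " at occasions ",
         paste(occasion_pair, collapse = "/"))
  }
  subset_samples(m, keep)
}

#' Extrapolate a taxon total from a counted subsample
#'
#' When only a fraction of a sample is counted for very abundant taxa, the
#' sample total is estimated as `count / fraction`; with the 15% subsampling
#' fraction this is the (100 / 15) x count rule.
#'
#' @param subcount non-negative numeric vector of subsample counts.
#' @param fraction counted fraction of the sample, in (0, 1].
#' @return estimated totals, `subcount / fraction` (not rounded; counts are
#'   integerized later, at pooling).
#' @export
extrapolate_subsample <- function(subcount, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      !is.finite(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be a single number in (0, 1]")
  }
  if (any(!is.finite(subcount)) || any(subcount < 0)) {
    stop("subcount must be finite and non-negative")
  }
  subcount / fraction
}

#' Describe how raw samples pool into analysis samples
#'
#' A pooling plan names the grouping keys and, per habitat/sample-type, the
#' raw components expected in each pooled group. Groups missing some
#' components (lost or unsortable samples) are still pooled from whatever is
#' present; the shortfall is recorded in the pooling log.
#'
#' @param keys metadata columns defining a pooled group.
#' @param expected named list: expected number of raw component samples per
#'   pooled group, by `"bulk.lawn"`, `"bulk.forest"`, `"pitfall"`.
#' @return object of class `pooling_plan`.
#' @export
pooling_plan <- function(keys = c("location", "treatment", "habitat",
                                  "occasion", "sample_type"),
                         expected = list(bulk.lawn = 2L, bulk.forest = 4L,
                                         pitfall = 2L)) {
  structure(list(keys = keys, expected = expected), class = "pooling_plan")
}

#' Pool raw component samples into analysis samples
#'
#' Sums counts over all raw samples sharing the grouping keys (by default
#' location, treatment, habitat, occasion, sample type), giving one pooled
#' sample per plot x habitat x occasion cell. Counts are rounded half-up to
#' integers afterwards so that extrapolated (fractional) totals are valid
#' negative binomial responses. Groups with fewer raw components than the
#' plan expects are pooled from what exists and listed, with a warning, in
#' the `pooling_log` attribute of the result.
#'
#' @param raw `taxon_counts` of raw component samples.
#' @param plan a [pooling_plan()].
#' @return `taxon_counts` of pooled samples (one row per group), with
#'   attribute `pooling_log` (data.frame of incomplete groups).
#' @export
pool_samples <- function(raw, plan = pooling_plan()) {
  stopifnot(inherits(raw, "taxon_counts"), inherits(plan, "pooling_plan"))
  meta <- raw$meta
  key_df <- meta[plan$keys]
  key <- do.call(paste, c(lapply(key_df, as.character), sep = "|"))
  groups <- split(seq_len(nrow(meta)), key)
  pooled_counts <- t(vapply(groups, function(idx) {
    colSums(raw$counts[idx, , drop = FALSE])
  }, numeric(length(raw$taxa))))
  colnames(pooled_counts) <- raw$taxa
  first_idx <- vapply(groups, `[`, integer(1), 1L)
  pooled_meta <- meta[first_idx, setdiff(names(meta), "component"),
                      drop = FALSE]
  pooled_meta$sample_id <- gsub("\\|", "_", names(groups))
  pooled_meta$stratum <- NULL
  pooled_counts <- round_half_up(pooled_counts)

  n_comp <- lengths(groups)
  expect_key <- ifelse(pooled_meta$sample_type == "pitfall", "pitfall",
                       paste("bulk", pooled_meta$habitat, sep = "."))
  n_expected <- unlist(plan$expected)[expect_key]
  short <- which(!is.na(n_expected) & n_comp < n_expected)
  log <- data.frame(sample_id = pooled_meta$sample_id[short],
                    n_components = n_comp[short],
                    n_expected = n_expected[short],
                    row.names = NULL)
  if (nrow(log)) {
    warning(nrow(log), " pooled group(s) have fewer raw components than ",
            "expected; pooled from what is present")
  }
  out <- taxon_counts(pooled_counts, pooled_meta, raw$extrapolated_taxa)
  attr(out, "pooling_log") <- log
  out
}

#' Read a count table with design metadata from CSV
#'
#' Accepts a wide layout (one row per sample, one column per taxon, metadata
#' columns first) or a long layout (one row per sample-taxon pair with
#' `taxon` and `count` columns). Extrapolated taxa are recorded in a
#' `# extrapolated_taxa:` comment line (wide) or an `extrapolated` flag
#' column (long), as written by [write_count_table()].
#'
#' @param path CSV file path.
#' @param schema optional named character vector mapping file column names to
#'   the canonical metadata names (e.g. `c(plot_treatment = "treatment")`).
#' @return `taxon_counts` object.
#' @export
read_count_table <- function(path, schema = NULL) {
  header <- readLines(path, n = 5L)
  extrap <- character()
  cm <- grep("^# *extrapolated_taxa:", header, value = TRUE)
  if (length(cm)) {
    val <- trimws(sub("^# *extrapolated_taxa:", "", cm[1]))
    if (nzchar(val)) extrap <- strsplit(val, ";")[[1]]
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        check.names = FALSE)
  if (!is.null(schema)) {
    hit <- names(df) %in% names(schema)
    names(df)[hit] <- schema[names(df)[hit]]
  }
  missing_cols <- setdiff(.meta_required, names(df))
  if (length(missing_cols)) {
    stop("missing metadata column(s): ", paste(missing_cols, collapse = ", "))
  }
  meta_cols <- intersect(c(.meta_required, .meta_optional), names(df))
  if (all(c("taxon", "count") %in% names(df))) {
    # long layout
    if (anyDuplicated(df[c("sample_id", "taxon")])) {
      stop("duplicated (sample_id, taxon) rows in long layout")
    }
    if ("extrapolated" %in% names(df)) {
      extrap <- union(extrap, unique(df$taxon[as.logical(df$extrapolated)]))
    }
    taxa <- sort(unique(df$taxon))
    samples <- unique(df$sample_id)
    counts <- matrix(0, length(samples), length(taxa),
                     dimnames = list(samples, taxa))
    counts[cbind(match(df$sample_id, samples), match(df$taxon, taxa))] <-
      df$count
    meta <- df[!duplicated(df$sample_id), meta_cols, drop = FALSE]
    taxon_counts(counts, meta, extrap)
  } else {
    taxon_cols <- setdiff(names(df), c(meta_cols, "period"))
    counts <- as.matrix(df[taxon_cols])
    if (!is.numeric(counts)) stop("non-numeric taxon count column")
    rownames(counts) <- df$sample_id
    taxon_counts(counts, df[meta_cols], extrap)
  }
}

#' Write a count table to CSV
#'
#' Writes the wide layout by default (metadata columns then one column per
#' taxon, rows ordered by design keys and sample id, taxa alphabetical), or
#' the long layout with `taxon`, `count` and an `extrapolated` flag column.
#' Output is read back identically by [read_count_table()].
#'
#' @param m `taxon_counts` object.
#' @param path output CSV path.
#' @param layout `"wide"` or `"long"`.
#' @return invisibly, `path`.
#' @export
write_count_table <- function(m, path, layout = c("wide", "long")) {
  stopifnot(inherits(m, "taxon_counts"))
  layout <- match.arg(layout)
  meta_cols <- intersect(c(.meta_required, .meta_optional), names(m$meta))
  meta <- m$meta[meta_cols]
  if (layout == "wide") {
    con <- file(path, "w")
    on.exit(close(con))
    if (length(m$extrapolated_taxa)) {
      writeLines(paste0("# extrapolated_taxa: ",
                        paste(m$extrapolated_taxa, collapse = ";")), con)
    }
    utils::write.csv(cbind(meta, as.data.frame(m$counts)), con,
                     row.names = FALSE, quote = FALSE)
  } else {
    long <- data.frame(
      meta[rep(seq_len(nrow(meta)), times = length(m$taxa)), , drop = FALSE],
      taxon = rep(m$taxa, each = nrow(meta)),
      count = as.vector(m$counts),
      row.names = NULL
    )
    long$extrapolated <- long$taxon %in% m$extrapolated_taxa
    long <- long[order(long$sample_id, long$taxon), ]
    utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
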