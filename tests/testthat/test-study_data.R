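test_that("subsample extrapolation follows the count/fraction rule", {
  expect_equal(extrapolate_subsample(15, 0.15), 100)
  expect_equal(extrapolate_subsample(0, 0.15), 0)
  expect_equal(extrapolate_subsample(13, 0.15), 100 / 15 * 13)
  expect_equal(round_half_up(extrapolate_subsample(13, 0.15)), 87)
  # vectorized and linear
  a <- c(3, 7, 11)
  b <- c(1, 0, 4)
  expect_equal(extrapolate_subsample(a + b, 0.2),
               extrapolate_subsample(a, 0.2) + extrapolate_subsample(b, 0.2))
  expect_error(extrapolate_subsample(5, 0), "fraction")
  expect_error(extrapolate_subsample(5, 1.2), "fraction")
  expect_error(extrapolate_subsample(-1, 0.5), "non-negative")
})

test_that("round_half_up rounds ties upward for counts", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.4, 2.6, 86.6667)),
               c(1, 2, 2, 3, 87))
})

test_that("taxon_counts validates metadata and counts", {
  m <- toy_counts()
  expect_s3_class(m, "taxon_counts")
  expect_equal(dim(m), c(4, 3))
  expect_equal(as.character(m$meta$period),
               ifelse(m$meta$occasion == "pre", "before", "after"))
  meta <- m$meta
  bad <- meta
  bad$treatment <- "sprayed"
  expect_error(taxon_counts(m$counts, bad), "unknown treatment")
  expect_error(taxon_counts(m$counts, meta[, -1]), "sample_id")
  neg <- m$counts
  neg[1, 1] <- -2
  expect_error(taxon_counts(neg, meta), "non-negative")
  dup <- meta
  dup$sample_id <- rep("s1", 4)
  expect_error(taxon_counts(m$counts, dup), "duplicated sample_id")
})

test_that("wide and long CSV round-trips preserve the object", {
  m <- taxon_counts(toy_counts()$counts, toy_counts()$meta,
                    extrapolated_taxa = c("acari", "collembola"))
  for (layout in c("wide", "long")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_count_table(m, path, layout = layout)
    m2 <- read_count_table(path)
    expect_equal(m2$counts, m$counts)
    expect_equal(m2$taxa, m$taxa)
    expect_equal(m2$extrapolated_taxa, m$extrapolated_taxa)
    expect_equal(m2$meta[c("sample_id", "location", "treatment", "habitat",
                           "occasion", "sample_type", "period")],
                 m$meta[c("sample_id", "location", "treatment", "habitat",
                          "occasion", "sample_type", "period")])
  }
})

test_that("empty matrix writes a header-only CSV", {
  m <- toy_counts()
  empty <- subset_samples(m, integer(0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_count_table(empty, path)
  expect_length(readLines(path), 1L)
})

test_that("malformed CSVs are rejected", {
  m <- toy_counts()
  path <- withr::local_tempfile(fileext = ".csv")
  write_count_table(m, path, layout = "long")
  long <- read.csv(path)
  long2 <- rbind(long, long[1, ])
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(long2, path2, row.names = FALSE)
  expect_error(read_count_table(path2), "duplicated")

  path <- withr::local_tempfile(fileext = ".csv")
  write_count_table(m, path)
  wide <- read.csv(path)
  wide$treatment <- NULL
  path3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(wide, path3, row.names = FALSE)
  expect_error(read_count_table(path3), "treatment")
})

test_that("schema mapping renames file columns to canonical names", {
  m <- toy_counts()
  path <- withr::local_tempfile(fileext = ".csv")
  write_count_table(m, path)
  df <- read.csv(path)
  names(df)[names(df) == "treatment"] <- "plot_treatment"
  write.csv(df, path, row.names = FALSE)
  m2 <- read_count_table(path, schema = c(plot_treatment = "treatment"))
  expect_equal(m2$counts, m$counts)
})

test_that("pooling the full study inventory gives 156 bulk and 68 pitfall rows", {
  sim <- simulate_dataset(synthetic_config(seed = 7))
  raw <- sim$raw
  expect_equal(sum(raw$meta$sample_type == "bulk"), 467)
  expect_equal(sum(raw$meta$sample_type == "pitfall"), 129)
  pooled <- suppressWarnings(pool_samples(raw))
  expect_equal(sum(pooled$meta$sample_type == "bulk"), 156)
  expect_equal(sum(pooled$meta$sample_type == "pitfall"), 68)
  # the lost litter + dirty pitfalls are logged as incomplete groups
  expect_warning(pool_samples(raw), "fewer raw components")
  log <- attr(pooled, "pooling_log")
  expect_true(nrow(log) >= 1)
})

test_that("pooling conserves taxon totals up to the rounding rule", {
  sim <- simulate_dataset(synthetic_config(seed = 3))
  raw_tot <- colSums(sim$raw$counts)
  pooled_tot <- colSums(sim$pooled$counts)
  n_groups <- nrow(sim$pooled$counts)
  expect_true(all(abs(raw_tot - pooled_tot) <= 0.5 * n_groups))
  # non-extrapolated taxa have integer raw counts: conservation is exact
  plain <- setdiff(sim$pooled$taxa, sim$pooled$extrapolated_taxa)
  expect_equal(pooled_tot[plain], raw_tot[plain])
})

test_that("a single-sample group pools to itself", {
  m <- toy_counts()
  pooled <- pool_samples(m, pooling_plan(expected = list()))
  expect_equal(nrow(pooled$counts), 4L)
  expect_equal(unname(colSums(pooled$counts)), unname(colSums(m$counts)))
})
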