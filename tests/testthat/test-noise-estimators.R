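test_that("size correction is a no-op when counts ignore size, exact for
           constants, and scale-invariant", {
  set.seed(14)
  counts <- rpois(500, 5)
  sizes <- runif(500, 7, 14)
  fe <- size_corrected_fano(counts, sizes, n_boot = 500, seed = 1)
  expect_equal(fe$fano, fe$raw_fano, tolerance = 0.05)
  expect_true(fe$ci[1] <= fe$fano && fe$fano <= fe$ci[2])
  # constant counts: zero variance, zero Fano
  fe0 <- size_corrected_fano(rep(4, 100), runif(100, 7, 14), n_boot = 0)
  expect_equal(fe0$fano, 0)
  # invariant to rescaling sizes (length vs volume proxy)
  fe_mm <- size_corrected_fano(counts, sizes * 1e3, n_boot = 0)
  expect_equal(fe_mm$fano, size_corrected_fano(counts, sizes,
                                               n_boot = 0)$fano,
               tolerance = 1e-12)
  # the residual-variance formulation is the same estimator
  fe_res <- size_corrected_fano(counts, sizes, n_boot = 0,
                                variant = "residual")
  expect_equal(fe_res$fano, fe_mm$fano, tolerance = 1e-12)
})

test_that("size-scaled Poisson counts are raw super-Poissonian but
           corrected back to 1", {
  set.seed(15)
  n <- 3000
  sizes <- runif(n, 7, 14)
  counts <- rpois(n, 2 * sizes)            # mean proportional to size
  fe <- size_corrected_fano(counts, sizes, n_boot = 1000, seed = 2)
  expect_gt(fe$raw_fano, 1.5)              # size effect inflates raw Fano
  expect_lt(abs(fe$fano - 1), 3 * fe$se)   # correction recovers Poisson
})

test_that("degenerate size variance falls back to the raw Fano", {
  expect_warning(
    fe <- size_corrected_fano(rpois(50, 5), rep(10, 50), n_boot = 0),
    "degenerate")
  expect_equal(fe$fano, fe$raw_fano)
})

test_that("sliding-window retention enforces the per-stratum thresholds", {
  # disjoint windows: clusters of cells at integer lengths, window 0.5,
  # step 1.0, so window k holds exactly cluster k
  mk <- function(sizes_per_cluster) {
    lengths <- rep(seq_along(sizes_per_cluster), sizes_per_cluster)
    counts <- rpois(length(lengths), 5)
    list(counts = counts, lengths = lengths)
  }
  set.seed(16)
  # 44 full windows of 50 cells, one mid-run window with 49
  sizes <- rep(50, 45); sizes[23] <- 49
  d <- mk(sizes)
  prof <- sliding_window_fano(d$counts, d$lengths, window = 0.5, step = 1,
                              population = "pooled", nucleation = "all")
  all_w <- attr(prof, "all_windows")
  expect_equal(nrow(all_w), 44)
  expect_false(any(prof$n_cells == 49))          # the 49-cell window drops
  expect_equal(nrow(prof), 43)                   # flanking runs both >= 20
  # the same table passes the single-replicate threshold (40) everywhere
  prof_rep <- sliding_window_fano(d$counts, d$lengths, window = 0.5,
                                  step = 1, population = "replicate")
  expect_equal(nrow(prof_rep), 44)
  # runs shorter than 20 consecutive windows yield an empty profile
  d2 <- mk(rep(50, 15))
  prof2 <- sliding_window_fano(d2$counts, d2$lengths, window = 0.5,
                               step = 1)
  expect_equal(nrow(prof2), 0)
  # binucleated stratum only needs 30 cells for 6 consecutive windows
  d3 <- mk(rep(30, 8))
  prof3 <- sliding_window_fano(d3$counts, d3$lengths, window = 0.5,
                               step = 1, nucleation = "bi")
  expect_equal(nrow(prof3), 7)
})

test_that("sliding-window Fano of size-scaled Poisson data stays near 1", {
  set.seed(17)
  n <- 4000
  lengths <- runif(n, 7, 14)
  counts <- rpois(n, 1.5 * lengths)
  prof <- sliding_window_fano(counts, lengths)
  expect_gt(nrow(prof), 20)
  expect_lt(max(abs(prof$fano - 1)), 0.35)
  expect_lt(abs(mean(prof$fano) - 1), 0.08)
})

test_that("nuclear-cytoplasmic covariance estimator behaves on known inputs", {
  set.seed(18)
  # independent Poisson pairs: covariance ~ 0, CI covers 0
  n <- 2000
  a <- rpois(n, 3); b <- rpois(n, 4)
  cv <- nuc_cyto_covariance(a, b, n_boot = 1000, seed = 3)
  expect_lt(cv$ci[1], 0); expect_gt(cv$ci[2], 0)
  # duplicated vector: covariance equals the variance
  cv2 <- nuc_cyto_covariance(a, a, n_boot = 200, seed = 3)
  expect_equal(cv2$covariance, var(a))
  # sub-Poissonian model population: negative covariance
  ps <- sample_population(model_spec(3, 3, 10, 10, 5), 5000, seed = 19)
  cv3 <- nuc_cyto_covariance(ps$nuclear, ps$cytoplasmic, n_boot = 1000,
                             seed = 4)
  expect_lt(cv3$covariance, 0)
  expect_lt(cv3$ci[2], 0)
  # size-partialled variant strips a shared linear size trend
  sizes <- runif(n, 7, 14)
  an <- a + round(2 * sizes); bn <- b + round(3 * sizes)
  cv4 <- nuc_cyto_covariance(an, bn, sizes = sizes, n_boot = 1000, seed = 5)
  expect_gt(cv4$covariance, 5)                  # raw: size-driven positive
  expect_lt(abs(cv4$covariance_partial), abs(cv4$covariance) / 4)
  # small samples are flagged
  expect_warning(nuc_cyto_covariance(a[1:10], b[1:10], n_boot = 50),
                 "low-precision")
})

test_that("noise_summary assembles the per-compartment table with covariance", {
  ps <- sample_population(model_spec(3, 3, 10, 10, 5), 800, seed = 20)
  sizes <- runif(800, 7, 14)
  counts <- dplyr::bind_rows(
    tibble::tibble(cell_id = seq_len(800), compartment = "nuclear",
                   count = ps$nuclear, size = sizes),
    tibble::tibble(cell_id = seq_len(800), compartment = "cytoplasmic",
                   count = ps$cytoplasmic, size = sizes))
  ns <- noise_summary(counts, condition = "synthetic", n_boot = 400)
  expect_equal(nrow(ns), 2)
  expect_true(all(ns$fano_lo <= ns$size_corrected_fano &
                    ns$size_corrected_fano <= ns$fano_hi))
  expect_s3_class(attr(ns, "covariance"), "covariance_estimate")
  expect_lt(attr(ns, "covariance")$covariance, 0)
})
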