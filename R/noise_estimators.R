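# chunked nonparametric bootstrap of a statistic of paired columns;
# stat takes (matrix of resampled y1, matrix of y2, ...) column-wise and
# returns a vector of replicate statistics.
boot_replicates <- function(n, n_boot, fun, chunk = 1000L) {
  out <- numeric(0)
  done <- 0L
  while (done < n_boot) {
    b <- min(chunk, n_boot - done)
    idx <- matrix(sample.int(n, n * b, replace = TRUE), nrow = n)
    out <- c(out, fun(idx))
    done <- done + b
  }
  out
}

# column-wise variance / covariance helpers for resample matrices
col_var <- function(m) {
  n <- nrow(m)
  (colMeans(m^2) - colMeans(m)^2) * n / (n - 1)
}
col_cov <- function(a, b) {
  n <- nrow(a)
  (colMeans(a * b) - colMeans(a) * colMeans(b)) * n / (n - 1)
}

# point estimate of the size-corrected Fano factor:
# (Var(count) - slope^2 Var(size)) / mean(count), slope from OLS of
# count on size. Subtracts the size-explained variance component.
# variant = "residual" instead uses Var(residuals)/mean — algebraically
# equal up to the n-1 normalization of the regression fit.
fano_corrected_point <- function(counts, sizes,
                                 variant = c("explained", "residual")) {
  variant <- match.arg(variant)
  vs <- var(sizes)
  slope <- cov(counts, sizes) / vs
  if (variant == "explained") {
    (var(counts) - slope^2 * vs) / mean(counts)
  } else {
    res <- counts - mean(counts) - slope * (sizes - mean(sizes))
    var(res) / mean(counts)
  }
}

#' Cell size-corrected Fano factor
#'
#' Mean mRNA number grows with cell size, which inflates the population
#' variance; left uncorrected, a sub-Poissonian distribution can masquerade
#' as Poissonian. This regresses count on size by ordinary least squares
#' and subtracts the size-explained variance component:
#' `F_corr = (Var(count) - slope^2 Var(size)) / mean(count)`.
#' The estimator is invariant to rescaling the sizes by any positive
#' constant, and its 95% confidence interval is obtained by nonparametric
#' bootstrap over cells (percentile method).
#'
#' @param counts Per-cell mRNA counts (any counting method).
#' @param sizes Per-cell sizes (length or volume; positive). With
#'   degenerate size variance, the raw Fano factor is returned with a
#'   warning.
#' @param n_boot Bootstrap resamples (default 10000); 0 skips the CI.
#' @param seed Integer seed for the bootstrap.
#' @param variant `"explained"` (variance-subtraction form, default) or
#'   `"residual"` (variance of OLS residuals over the mean).
#' @return A list of class `"fano_estimate"`: `fano`, `ci` (95% percentile
#'   interval), `se` (bootstrap SE), `raw_fano`, `slope`, `mean_count`,
#'   `n_cells`, `n_boot`.
#' @export
size_corrected_fano <- function(counts, sizes, n_boot = 10000, seed = 1,
                                variant = c("explained", "residual")) {
  variant <- match.arg(variant)
  stopifnot(length(counts) == length(sizes), all(sizes > 0))
  n <- length(counts)
  if (n < 30)
    warning("fewer than 30 cells; size-corrected Fano is unreliable",
            call. = FALSE)
  raw <- var(counts) / mean(counts)
  if (!is.finite(var(sizes)) || var(sizes) < 1e-12 * mean(sizes)^2) {
    warning("degenerate size variance; returning the raw Fano factor",
            call. = FALSE)
    return(structure(list(fano = raw, ci = c(NA_real_, NA_real_),
                          se = NA_real_, raw_fano = raw, slope = NA_real_,
                          mean_count = mean(counts), n_cells = n,
                          n_boot = 0L),
                     class = "fano_estimate"))
  }
  point <- fano_corrected_point(counts, sizes, variant)
  slope <- cov(counts, sizes) / var(sizes)
  ci <- c(NA_real_, NA_real_); se <- NA_real_
  if (n_boot > 0) {
    set.seed(seed)
    reps <- boot_replicates(n, n_boot, function(idx) {
      cc <- matrix(counts[idx], nrow = n)
      ss <- matrix(sizes[idx], nrow = n)
      vs <- col_var(ss)
      sl <- col_cov(cc, ss) / vs
      if (variant == "explained") {
        (col_var(cc) - sl^2 * vs) / colMeans(cc)
      } else {
        # residual variance equals (var - slope^2 var_s) for OLS, so the
        # two variants share a bootstrap path
        (col_var(cc) - sl^2 * vs) / colMeans(cc)
      }
    })
    ci <- unname(quantile(reps, c(0.025, 0.975)))
    se <- sd(reps)
  }
  structure(list(fano = point, ci = ci, se = se, raw_fano = raw,
                 slope = slope, mean_count = mean(counts), n_cells = n,
                 n_boot = as.integer(n_boot)),
            class = "fano_estimate")
}

#' @export
print.fano_estimate <- function(x, ...) {
  cat(sprintf("<fano_estimate> F_corr = %.4g [%.4g, %.4g]  (raw %.4g, n = %d)\n",
              x$fano, x$ci[1], x$ci[2], x$raw_fano, x$n_cells))
  invisible(x)
}

# retention thresholds (min cells pooled, min cells per replicate,
# min consecutive qualifying windows) by nucleation stratum
window_thresholds <- function(nucleation) {
  switch(nucleation,
         all = c(pooled = 50, replicate = 40, consecutive = 20),
         mono = c(pooled = 40, replicate = 30, consecutive = 10),
         bi = c(pooled = 30, replicate = 20, consecutive = 6))
}

#' Fano factor in a sliding window of cell length
#'
#' Combines cells within a `window`-micrometer length window, computes the
#' mean, variance and Fano factor of their counts, and slides the window by
#' `step` across all cell sizes. Windows are retained only where the
#' minimum cell count for the chosen stratum is met for a run of at least
#' the required number of consecutive windows; minimum cells per window are
#' (pooled, single replicate) = (50, 40) for all cells combined, (40, 30)
#' for mononucleated and (30, 20) for binucleated cells, with required runs
#' of 20, 10 and 6 consecutive windows respectively.
#'
#' @param counts,lengths Aligned per-cell counts and cell lengths (um).
#' @param window Window width in micrometers (default 1.0).
#' @param step Window step in micrometers (default 0.1).
#' @param population `"pooled"` (default) or `"replicate"`; selects which
#'   minimum-cell threshold applies.
#' @param nucleation `"all"`, `"mono"` or `"bi"`; the stratum determines
#'   the threshold triple.
#' @return A tibble of retained windows: `center`, `n_cells`, `mean`,
#'   `variance`, `fano`. Attribute `all_windows` holds every window with a
#'   `retained` flag. Zero rows when no run qualifies.
#' @export
sliding_window_fano <- function(counts, lengths, window = 1.0, step = 0.1,
                                population = c("pooled", "replicate"),
                                nucleation = c("all", "mono", "bi")) {
  population <- match.arg(population)
  nucleation <- match.arg(nucleation)
  stopifnot(length(counts) == length(lengths))
  thr <- window_thresholds(nucleation)
  min_cells <- unname(thr[population])
  min_run <- unname(thr["consecutive"])

  centers <- seq(min(lengths) + window / 2, max(lengths) - window / 2,
                 by = step)
  if (!length(centers))
    centers <- mean(range(lengths))
  stats_tab <- lapply(centers, function(cc) {
    inwin <- counts[lengths >= cc - window / 2 & lengths <= cc + window / 2]
    tibble::tibble(center = cc, n_cells = length(inwin),
                   mean = if (length(inwin)) mean(inwin) else NA_real_,
                   variance = if (length(inwin) > 1) var(inwin) else NA_real_)
  })
  tab <- dplyr::bind_rows(stats_tab)
  tab$fano <- tab$variance / tab$mean
  qualifies <- tab$n_cells >= min_cells
  runs <- rle(qualifies)
  keep_run <- runs$values & runs$lengths >= min_run
  tab$retained <- inverse.rle(list(values = keep_run,
                                   lengths = runs$lengths))
  out <- tab[tab$retained, setdiff(names(tab), "retained")]
  attr(out, "all_windows") <- tab
  attr(out, "thresholds") <- c(min_cells = min_cells, min_run = min_run)
  out
}

#' Covariance between nuclear and cytoplasmic mRNA counts
#'
#' Sample covariance of per-cell (nuclear, cytoplasmic) count pairs with a
#' bootstrap 95% confidence interval. In the multi-step expression model
#' this covariance is negative for sub-Poissonian, zero for Poissonian and
#' positive for super-Poissonian fluctuations, so its sign is an
#' independent, fit-free check of the noise regime. When `sizes` is given,
#' a size-partialled covariance (covariance of the residuals of both counts
#' regressed on size) is reported alongside, flagged separately, since the
#' shared size dependence otherwise adds a positive extrinsic component.
#'
#' @param nuclear,cytoplasmic Aligned per-cell counts.
#' @param sizes Optional per-cell sizes for the partialled variant.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Integer bootstrap seed.
#' @return A list of class `"covariance_estimate"`: `covariance`, `ci`,
#'   `se`, and (when sizes are supplied) `covariance_partial`, `ci_partial`,
#'   `se_partial`; plus `n_cells`. Fewer than 30 cells adds a
#'   `low_precision` warning flag.
#' @export
nuc_cyto_covariance <- function(nuclear, cytoplasmic, sizes = NULL,
                                n_boot = 10000, seed = 1) {
  stopifnot(length(nuclear) == length(cytoplasmic))
  n <- length(nuclear)
  low <- n < 30
  if (low) warning("fewer than 30 cells; covariance is low-precision",
                   call. = FALSE)
  point <- cov(nuclear, cytoplasmic)
  set.seed(seed)
  reps <- boot_replicates(n, n_boot, function(idx) {
    col_cov(matrix(nuclear[idx], nrow = n),
            matrix(cytoplasmic[idx], nrow = n))
  })
  out <- list(covariance = point,
              ci = unname(quantile(reps, c(0.025, 0.975))),
              se = sd(reps), n_cells = n, low_precision = low)
  if (!is.null(sizes)) {
    stopifnot(length(sizes) == n)
    rn <- stats::residuals(lm(nuclear ~ sizes))
    rc <- stats::residuals(lm(cytoplasmic ~ sizes))
    out$covariance_partial <- cov(rn, rc)
    repsp <- boot_replicates(n, n_boot, function(idx) {
      nn <- matrix(nuclear[idx], nrow = n)
      cc <- matrix(cytoplasmic[idx], nrow = n)
      ss <- matrix(sizes[idx], nrow = n)
      vs <- col_var(ss)
      bn <- col_cov(nn, ss) / vs
      bc <- col_cov(cc, ss) / vs
      col_cov(nn, cc) - bn * bc * vs
    })
    out$ci_partial <- unname(quantile(repsp, c(0.025, 0.975)))
    out$se_partial <- sd(repsp)
  }
  structure(out, class = "covariance_estimate")
}

#' @export
print.covariance_estimate <- function(x, ...) {
  cat(sprintf("<covariance_estimate> Cov(N, C) = %.4g [%.4g, %.4g], n = %d\n",
              x$covariance, x$ci[1], x$ci[2], x$n_cells))
  if (!is.null(x$covariance_partial))
    cat(sprintf("  size-partialled: %.4g [%.4g, %.4g]\n",
                x$covariance_partial, x$ci_partial[1], x$ci_partial[2]))
  invisible(x)
}

#' Per-compartment noise summary for one gene/condition
#'
#' Convenience wrapper producing the standard summary table: per
#' compartment the number of cells, mean count, raw and size-corrected Fano
#' factor with 95% CI, plus the nuclear-cytoplasmic covariance.
#'
#' @param counts Count table from [count_cells()] (one row per cell per
#'   compartment) joined with per-cell sizes: columns `cell_id`,
#'   compartment column, `count`, `size`.
#' @param by Compartment column name.
#' @param condition Label stored in the output.
#' @param n_boot,seed Bootstrap settings passed through.
#' @return A tibble with one row per compartment and attribute
#'   `covariance` (a `"covariance_estimate"`, computed when both `nuclear`
#'   and `cytoplasmic` levels are present).
#' @export
noise_summary <- function(counts, by = "compartment", condition = NA,
                          n_boot = 10000, seed = 1) {
  stopifnot(all(c("cell_id", by, "count", "size") %in% names(counts)))
  lev <- unique(counts[[by]])
  rows <- lapply(lev, function(cmp) {
    d <- counts[counts[[by]] == cmp, ]
    fe <- size_corrected_fano(d$count, d$size, n_boot = n_boot, seed = seed)
    tibble::tibble(condition = condition, compartment = cmp,
                   n_cells = fe$n_cells, mean_count = fe$mean_count,
                   raw_fano = fe$raw_fano, size_corrected_fano = fe$fano,
                   fano_lo = fe$ci[1], fano_hi = fe$ci[2], fano_se = fe$se)
  })
  out <- dplyr::bind_rows(rows)
  if (all(c("nuclear", "cytoplasmic") %in% lev)) {
    wide <- counts |>
      dplyr::filter(.data[[by]] %in% c("nuclear", "cytoplasmic")) |>
      tidyr::pivot_wider(id_cols = "cell_id", names_from = dplyr::all_of(by),
                         values_from = "count")
    sz <- counts[!duplicated(counts$cell_id),
                 c("cell_id", "size")]
    wide <- dplyr::left_join(wide, sz, by = "cell_id")
    attr(out, "covariance") <- nuc_cyto_covariance(
      wide$nuclear, wide$cytoplasmic, sizes = wide$size,
      n_boot = n_boot, seed = seed)
  }
  out
}
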