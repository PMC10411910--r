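#' Normalize spot intensities to the single-molecule scale
#'
#' Divides the PSF amplitude of each spot by the median amplitude of the
#' cytoplasmic spots in the same image, so a typical single-mRNA spot gets a
#' normalized intensity of 1. Each image is normalized independently, which
#' removes image-to-image gain differences. Images without any cytoplasmic
#' spot cannot be normalized and are dropped with a warning.
#'
#' @param spots Spot table with at least `image_id`, `compartment`
#'   (`"nuclear"`/`"cytoplasmic"`) and `intensity_amplitude` (> 0).
#' @return The spot table with a `normalized_intensity` column added; the
#'   per-image median of cytoplasmic normalized intensities is exactly 1.
#' @export
normalize_intensities <- function(spots) {
  stopifnot(all(c("image_id", "compartment", "intensity_amplitude") %in%
                  names(spots)))
  if (any(spots$intensity_amplitude <= 0))
    stop("intensity amplitudes must be > 0", call. = FALSE)
  med <- spots |>
    dplyr::filter(.data$compartment == "cytoplasmic") |>
    dplyr::group_by(.data$image_id) |>
    dplyr::summarise(.img_median = median(.data$intensity_amplitude),
                     .groups = "drop")
  bad <- setdiff(unique(spots$image_id), med$image_id)
  if (length(bad)) {
    warning(length(bad), " image(s) without cytoplasmic spots excluded: ",
            paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    spots <- dplyr::filter(spots, !(.data$image_id %in% bad))
  }
  spots |>
    dplyr::left_join(med, by = "image_id") |>
    dplyr::mutate(normalized_intensity =
                    .data$intensity_amplitude / .data$.img_median) |>
    dplyr::select(-".img_median")
}

#' Per-cell mRNA counts from a spot table
#'
#' Three counting methods:
#' * `"spot"`: the number of spots, ignoring intensity. Accurate when nearly
#'   all spots hold a single molecule; undercounts multi-mRNA spots such as
#'   transcription sites.
#' * `"intensity"`: the sum of normalized intensities, which counts
#'   multi-mRNA spots correctly but sums the technical intensity variation
#'   of every single-molecule spot into the count.
#' * `"hybrid"` (default): spots with normalized intensity below the 95th
#'   percentile of the *cytoplasmic* spots in the same sample count as one
#'   molecule; brighter spots contribute their normalized intensity. This
#'   keeps technical intensity noise out of single-molecule spots while
#'   still counting multi-mRNA spots as several molecules, and is therefore
#'   always >= the spot count.
#'
#' @param spots Spot table; for `"intensity"`/`"hybrid"` it must carry
#'   `normalized_intensity` (see [normalize_intensities()]).
#' @param cells Optional cell table (`image_id`, `cell_id`); when given,
#'   cells without spots in a compartment appear with count 0 (required for
#'   unbiased means and Fano factors).
#' @param method `"hybrid"`, `"spot"` or `"intensity"`.
#' @param percentile_threshold Percentile (of cytoplasmic normalized
#'   intensities, per sample) above which a spot is treated as multi-mRNA in
#'   the hybrid method. Default 95.
#' @param by Column holding the compartment grouping (default
#'   `"compartment"`; pass `"spot_class"` after [classify_nascent()]).
#' @param sample_col Column identifying the sample/replicate within which
#'   the hybrid percentile is computed (default `"replicate_id"`; if
#'   absent, the whole table is one sample).
#' @return A tibble with one row per cell per compartment level:
#'   `image_id`, `cell_id`, compartment column, `count`. Spot counts are
#'   integer; hybrid and intensity counts are real.
#' @export
count_cells <- function(spots, cells = NULL,
                        method = c("hybrid", "spot", "intensity"),
                        percentile_threshold = 95, by = "compartment",
                        sample_col = "replicate_id") {
  method <- match.arg(method)
  stopifnot(all(c("image_id", "cell_id", by) %in% names(spots)))
  if (method != "spot" && !"normalized_intensity" %in% names(spots))
    stop("run normalize_intensities() before method = \"", method, "\"",
         call. = FALSE)

  spots$.cmp <- spots[[by]]
  if (method == "spot") {
    spots$.mol <- 1
  } else if (method == "intensity") {
    spots$.mol <- spots$normalized_intensity
  } else {
    if (sample_col %in% names(spots)) {
      spots$.sample <- spots[[sample_col]]
    } else {
      spots$.sample <- "all"
    }
    thr <- spots |>
      dplyr::filter(.data$compartment == "cytoplasmic") |>
      dplyr::group_by(.data$.sample) |>
      dplyr::summarise(
        # empirical (type 1) percentile: the threshold is an observed
        # cytoplasmic intensity, and spots at or below it count as one
        # molecule, so at least `percentile_threshold`% of the
        # single-molecule reference spots are counted as singletons
        .thr = quantile(.data$normalized_intensity,
                        percentile_threshold / 100, names = FALSE,
                        type = 1),
        .groups = "drop")
    spots <- dplyr::left_join(spots, thr, by = ".sample")
    if (any(is.na(spots$.thr)))
      stop("a sample has no cytoplasmic spots; cannot set the hybrid ",
           "threshold", call. = FALSE)
    spots$.mol <- ifelse(spots$normalized_intensity <= spots$.thr,
                         1, spots$normalized_intensity)
  }

  counts <- spots |>
    dplyr::group_by(.data$image_id, .data$cell_id, .data$.cmp) |>
    dplyr::summarise(count = sum(.data$.mol), .groups = "drop")
  if (method == "spot") counts$count <- as.integer(counts$count)

  levels_cmp <- sort(unique(spots$.cmp))
  if (!is.null(cells)) {
    grid <- tidyr::expand_grid(
      dplyr::distinct(cells, .data$image_id, .data$cell_id),
      .cmp = levels_cmp)
    counts <- grid |>
      dplyr::left_join(counts, by = c("image_id", "cell_id", ".cmp")) |>
      dplyr::mutate(count = dplyr::coalesce(
        .data$count, if (method == "spot") 0L else 0))
  }
  names(counts)[names(counts) == ".cmp"] <- by
  counts
}

# Otsu-style 1D two-class threshold: minimizes within-class variance over
# candidate splits of the sorted values.
otsu_threshold <- function(v) {
  v <- sort(v)
  n <- length(v)
  cs <- cumsum(v); css <- cumsum(v^2)
  k <- seq_len(n - 1)
  m1 <- cs[k] / k
  m2 <- (cs[n] - cs[k]) / (n - k)
  ss1 <- css[k] - k * m1^2
  ss2 <- (css[n] - css[k]) - (n - k) * m2^2
  within <- ss1 + ss2
  i <- which.min(within)
  (v[i] + v[i + 1]) / 2
}

# Minimum of a kernel density estimate between its two largest modes;
# NA when the KDE has fewer than two modes (unimodal distribution).
kde_minimum <- function(v) {
  d <- density(v)
  y <- d$y
  up <- diff(y) > 0
  peaks <- which(!up[-1] & up[-length(up)]) + 1
  if (length(peaks) < 2) return(NA_real_)
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  valley <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1
  d$x[valley]
}

# Number of *prominent* modes of the KDE of v: two peaks only count as
# separate modes when the valley between them dips below 70% of the lower
# peak (small KDE wiggles on a unimodal sample are not modes).
kde_modes <- function(v, prominence = 0.7) {
  d <- density(v)
  y <- d$y
  up <- diff(y) > 0
  peaks <- which(!up[-1] & up[-length(up)]) + 1
  if (length(peaks) < 2) return(1L)
  peaks <- peaks[order(y[peaks], decreasing = TRUE)]
  n_modes <- 1L
  kept <- peaks[1]
  for (p in peaks[-1]) {
    seps <- vapply(kept, function(q) {
      rng <- sort(c(p, q))
      min(y[rng[1]:rng[2]]) < prominence * min(y[p], y[q])
    }, logical(1))
    if (all(seps)) {
      kept <- c(kept, p)
      n_modes <- n_modes + 1L
    }
  }
  n_modes
}

#' Classify spots as nascent, mature nuclear, or cytoplasmic
#'
#' Computes the 3D distance of every FISH spot to its nearest labeled
#' transcription-site (TS) spot in the same cell. The distribution of these
#' distances among nuclear spots is bimodal when nascent transcripts are
#' present; a per-image cutoff at the gap between the two modes separates
#' nascent (near) from mature nuclear (far) spots. Cytoplasmic spots keep
#' their label, except for TSs that fell just outside the nuclear mask (see
#' `mask_mode`).
#'
#' The cutoff backend is either an Otsu-style two-class split minimizing
#' within-class variance on log-distances (default) or the minimum of a
#' kernel density estimate between the two largest modes. If the per-image
#' distance distribution is unimodal (fewer than two KDE modes, or too few
#' nuclear spots), the configured fixed `fallback_cutoff` is used with a
#' warning.
#'
#' @param spots Spot table with `image_id`, `cell_id`, `compartment`,
#'   `x`, `y`, `z` (micrometers).
#' @param ts_spots TS spot table with `image_id`, `cell_id`, `x`, `y`, `z`
#'   (one row per labeled TS; typically one per nucleus).
#' @param method `"otsu"` or `"kde"`.
#' @param fallback_cutoff Fixed cutoff in micrometers used when the
#'   distance distribution is unimodal.
#' @param mask_mode How to treat spots labeled cytoplasmic that lie within
#'   the nascent cutoff of a TS (the signature of a TS just outside the
#'   nuclear mask): `"expand"` relabels them nascent (isotropic nuclear
#'   expansion); `"filter"` marks the whole cell excluded (recorded in the
#'   `excluded_cells` attribute).
#' @return `spots` with columns `ts_distance` and
#'   `spot_class` (`"nascent"`, `"mature_nuclear"`, `"cytoplasmic"`) added.
#'   Attributes: `cutoffs` (tibble of per-image cutoff and backend used) and
#'   `excluded_cells` (tibble, only for `mask_mode = "filter"`).
#' @export
classify_nascent <- function(spots, ts_spots, method = c("otsu", "kde"),
                             fallback_cutoff = 0.6,
                             mask_mode = c("expand", "filter")) {
  method <- match.arg(method)
  mask_mode <- match.arg(mask_mode)
  stopifnot(all(c("image_id", "cell_id", "compartment", "x", "y", "z") %in%
                  names(spots)),
            all(c("image_id", "cell_id", "x", "y", "z") %in%
                  names(ts_spots)))
  # nearest-TS distance within each cell
  ts_by_cell <- split(ts_spots[, c("x", "y", "z")],
                      paste(ts_spots$image_id, ts_spots$cell_id, sep = "\r"))
  key <- paste(spots$image_id, spots$cell_id, sep = "\r")
  dist <- rep(NA_real_, nrow(spots))
  for (k in unique(key)) {
    ts <- ts_by_cell[[k]]
    if (is.null(ts)) next
    sel <- which(key == k)
    dx <- outer(spots$x[sel], ts$x, "-")
    dy <- outer(spots$y[sel], ts$y, "-")
    dz <- outer(spots$z[sel], ts$z, "-")
    dist[sel] <- sqrt(apply(dx^2 + dy^2 + dz^2, 1, min))
  }
  spots$ts_distance <- dist

  cutoffs <- lapply(unique(spots$image_id), function(img) {
    d <- spots$ts_distance[spots$image_id == img &
                             spots$compartment == "nuclear"]
    d <- d[is.finite(d) & d > 0]
    if (length(d) >= 10 && kde_modes(log(d)) >= 2) {
      cut <- switch(method,
                    otsu = exp(otsu_threshold(log(d))),
                    kde = exp(kde_minimum(log(d))))
      if (is.finite(cut))
        return(tibble::tibble(image_id = img, cutoff = cut,
                              backend = method))
    }
    tibble::tibble(image_id = img, cutoff = fallback_cutoff,
                   backend = "fallback")
  })
  cutoffs <- dplyr::bind_rows(cutoffs)
  if (any(cutoffs$backend == "fallback"))
    warning(sum(cutoffs$backend == "fallback"),
            " image(s) had a unimodal TS-distance distribution; ",
            "using the fixed fallback cutoff", call. = FALSE)

  spots <- dplyr::left_join(spots, cutoffs[, c("image_id", "cutoff")],
                            by = "image_id")
  near <- is.finite(spots$ts_distance) & spots$ts_distance < spots$cutoff
  spots$spot_class <- ifelse(
    spots$compartment == "nuclear",
    ifelse(near, "nascent", "mature_nuclear"),
    "cytoplasmic")

  excluded <- NULL
  stray <- near & spots$compartment == "cytoplasmic"
  if (any(stray)) {
    if (mask_mode == "expand") {
      spots$spot_class[stray] <- "nascent"
    } else {
      excluded <- dplyr::distinct(spots[stray, c("image_id", "cell_id")])
      drop <- paste(spots$image_id, spots$cell_id, sep = "\r") %in%
        paste(excluded$image_id, excluded$cell_id, sep = "\r")
      spots <- spots[!drop, ]
    }
  }
  spots$cutoff <- NULL
  attr(spots, "cutoffs") <- cutoffs
  if (!is.null(excluded)) attr(spots, "excluded_cells") <- excluded
  spots
}
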