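#' Configure cell-level quality filters
#'
#' The filter set used before noise estimation:
#' * `length_sd`: remove cells whose length is more than this many standard
#'   deviations from the sample mean (applied once, not iterated; default 4).
#' * `width_range`: keep only widths inside this range in micrometers
#'   (`c(1.5, 4)` for reanalysis-style filtering; `NULL` disables).
#' * `length_max`: exclude cells longer than this (16 um for
#'   reanalysis-style filtering; `NULL` disables).
#' * `ts_qc`: for TS-labeling experiments, exclude cells without a GFP spot
#'   or with more than two GFP spots per nucleus, and cells with a
#'   cytoplasmic GFP spot.
#'
#' @param length_sd Numeric or `NULL`.
#' @param width_range Length-2 numeric or `NULL`.
#' @param length_max Numeric or `NULL`.
#' @param ts_qc Logical.
#' @return A list of class `"filter_config"`.
#' @export
filter_config <- function(length_sd = 4, width_range = NULL,
                          length_max = NULL, ts_qc = FALSE) {
  structure(list(length_sd = length_sd, width_range = width_range,
                 length_max = length_max, ts_qc = ts_qc),
            class = "filter_config")
}

#' Apply cell filters with an exclusion log
#'
#' Deterministically filters a cell table by the active rules in a
#' [filter_config()]. Every excluded cell is logged together with the rule
#' that triggered it. The length-SD rule uses the mean and SD of the sample
#' (per `replicate_id` when present) computed once on the input table.
#'
#' @param cells Cell table with `image_id`, `cell_id`, `length`, `width`,
#'   `n_nuclei`; for `ts_qc`, also `n_gfp_spots` (max per nucleus) and
#'   `cytoplasmic_gfp` (logical).
#' @param rules A [filter_config()].
#' @return The filtered cell table, with attribute `exclusion_log`: a
#'   tibble with `image_id`, `cell_id`, `rule`, `value`.
#' @export
filter_cells <- function(cells, rules = filter_config()) {
  stopifnot(inherits(rules, "filter_config"),
            all(c("image_id", "cell_id", "length", "width") %in%
                  names(cells)))
  log_rows <- list()
  note <- function(bad, rule, value) {
    if (any(bad))
      log_rows[[length(log_rows) + 1L]] <<- tibble::tibble(
        image_id = cells$image_id[bad], cell_id = cells$cell_id[bad],
        rule = rule, value = value[bad])
  }
  drop <- rep(FALSE, nrow(cells))

  if (!is.null(rules$length_sd)) {
    grp <- if ("replicate_id" %in% names(cells)) cells$replicate_id else 1
    mu <- stats::ave(cells$length, grp)
    sdv <- stats::ave(cells$length, grp, FUN = sd)
    z <- abs(cells$length - mu) / sdv
    bad <- is.finite(z) & z > rules$length_sd
    note(bad, sprintf("length_%gSD", rules$length_sd), cells$length)
    drop <- drop | bad
  }
  if (!is.null(rules$width_range)) {
    bad <- cells$width < rules$width_range[1] |
      cells$width > rules$width_range[2]
    note(bad, "width_range", cells$width)
    drop <- drop | bad
  }
  if (!is.null(rules$length_max)) {
    bad <- cells$length > rules$length_max
    note(bad, "length_max", cells$length)
    drop <- drop | bad
  }
  if (isTRUE(rules$ts_qc)) {
    stopifnot(all(c("n_gfp_spots", "cytoplasmic_gfp") %in% names(cells)))
    bad <- cells$n_gfp_spots < 1 | cells$n_gfp_spots > 2
    note(bad, "gfp_spots_per_nucleus", as.numeric(cells$n_gfp_spots))
    drop <- drop | bad
    bad <- as.logical(cells$cytoplasmic_gfp)
    note(bad, "cytoplasmic_gfp", as.numeric(cells$cytoplasmic_gfp))
    drop <- drop | bad
  }

  out <- cells[!drop, , drop = FALSE]
  attr(out, "exclusion_log") <-
    if (length(log_rows)) dplyr::bind_rows(log_rows) else
      tibble::tibble(image_id = character(), cell_id = character(),
                     rule = character(), value = numeric())
  out
}

#' Cell volume for a cylinder with hemispherical caps
#'
#' Fission yeast cells are modeled as a cylinder of the cell width capped by
#' two hemispheres: `V = pi (w/2)^2 (L - w) + 4/3 pi (w/2)^3`. For
#' `L = w` this degenerates to a sphere.
#'
#' @param length,width Cell length and width in micrometers
#'   (`length >= width > 0`).
#' @return Volume in cubic micrometers.
#' @examples
#' cell_volume(10, 4)  # 24*pi + 32*pi/3
#' @export
cell_volume <- function(length, width) {
  if (any(width <= 0)) stop("width must be > 0", call. = FALSE)
  if (any(length < width))
    stop("length must be >= width (cylinder-with-caps geometry)",
         call. = FALSE)
  r <- width / 2
  pi * r^2 * (length - width) + (4 / 3) * pi * r^3
}
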