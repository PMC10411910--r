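#' Configure a synthetic smFISH dataset
#'
#' Defines the ground-truthed populations the generator emits: per-cell
#' mRNA counts drawn from a [model_spec()] by exact simulation, cell sizes
#' in the fission-yeast interphase range, size-scaled transcription (so
#' concentration homeostasis emerges), unimodal log-normal single-molecule
#' spot intensities, multi-mRNA transcription-site spots, nuclear and
#' cytoplasmic compartment labels, a configurable binucleated fraction, and
#' an error rate for transcription sites falling just outside the nuclear
#' mask.
#'
#' @param spec Ground-truth [model_spec()].
#' @param n_cells Number of cells.
#' @param seed Integer seed (mandatory).
#' @param length_range Cell length bounds in micrometers; lengths are drawn
#'   uniformly (default `c(7, 14)`, the typical interphase growth range).
#' @param width_mean,width_sd Cell width distribution (um), truncated to
#'   stay positive and below the minimum length.
#' @param size_scaling Logical: scale each cell's synthesis-cycle rates
#'   (`k_A` and `k_B` jointly) linearly with length relative to the median
#'   length, so mean counts grow with size while concentration stays
#'   approximately constant.
#' @param scale_roles Which rates size scaling multiplies (default the full
#'   synthesis cycle; `"synthesis"` alone is the exposed alternative).
#' @param intensity_cv Coefficient of variation of single-molecule spot
#'   intensities (0 to 1; measured values in calibration data run about
#'   0.24 to 0.37; default 0.3). Log-normal with median 1; `0` gives every
#'   single-molecule spot intensity exactly 1.
#' @param nascent_mean Mean number of nascent transcripts per transcription
#'   site (Poisson).
#' @param nascent_scale,mature_scale Distance scales (um) from the TS
#'   coordinate at which the merged TS spot and mature nuclear spots are
#'   placed; their separation is what makes the TS-distance distribution
#'   bimodal.
#' @param binucleate_fraction Fraction of binucleated cells (late
#'   mitosis/G1/S); default 0.2.
#' @param binucleate_multiplier Gene-dosage multiplier for binucleated
#'   cells: counts are the sum of this many independent model draws.
#' @param mask_error_rate Fraction of cells whose TS sits just outside the
#'   nuclear mask, corrupting its compartment label to cytoplasmic.
#' @param cells_per_image Cells per microscopy image; each image gets an
#'   independent multiplicative intensity gain.
#' @param gain_cv CV of the per-image gain factor.
#' @param n_replicates Number of replicate experiments the images are
#'   assigned to.
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(spec, n_cells = 2000, seed,
                         length_range = c(7, 14),
                         width_mean = 3.3, width_sd = 0.15,
                         size_scaling = TRUE,
                         scale_roles = c("remodel", "synthesis"),
                         intensity_cv = 0.3, nascent_mean = 1,
                         nascent_scale = 0.2, mature_scale = 1.5,
                         binucleate_fraction = 0.2,
                         binucleate_multiplier = 2L,
                         mask_error_rate = 0.02,
                         cells_per_image = 50, gain_cv = 0.2,
                         n_replicates = 3) {
  stopifnot(inherits(spec, "model_spec"), n_cells >= 2)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (intensity_cv < 0 || intensity_cv > 1)
    stop("`intensity_cv` must be in [0, 1]", call. = FALSE)
  for (f in c(binucleate_fraction, mask_error_rate))
    if (f < 0 || f > 1) stop("fractions must be in [0, 1]", call. = FALSE)
  stopifnot(length_range[1] > 0, length_range[1] < length_range[2],
            width_mean > 0, nascent_mean >= 0, nascent_scale > 0,
            mature_scale > nascent_scale, binucleate_multiplier >= 1)
  structure(
    list(spec = spec, n_cells = as.integer(n_cells), seed = as.integer(seed),
         length_range = length_range, width_mean = width_mean,
         width_sd = width_sd, size_scaling = size_scaling,
         scale_roles = scale_roles, intensity_cv = intensity_cv,
         nascent_mean = nascent_mean, nascent_scale = nascent_scale,
         mature_scale = mature_scale,
         binucleate_fraction = binucleate_fraction,
         binucleate_multiplier = as.integer(binucleate_multiplier),
         mask_error_rate = mask_error_rate,
         cells_per_image = as.integer(cells_per_image), gain_cv = gain_cv,
         n_replicates = as.integer(n_replicates)),
    class = "synth_config")
}

#' Generate a ground-truthed cell population
#'
#' Draws cell geometry and per-cell true mRNA counts from the configured
#' model. Mononucleated cells get one model draw; binucleated cells get the
#' sum of `binucleate_multiplier` independent draws (a phenomenological
#' dosage effect — no cell-cycle simulation). With `size_scaling`, each
#' cell's synthesis-cycle rates are multiplied by `length / median(length)`
#' before simulation, so the regression slope of count on length is
#' positive while the size-corrected Fano factor matches the base model.
#'
#' @param config A [synth_config()].
#' @return A list of class `"synth_population"` with elements `cells`
#'   (tibble: `image_id`, `cell_id`, `replicate_id`, `length`, `width`,
#'   `n_nuclei`) and `truth` (tibble: `cell_id`, true mature
#'   nuclear/cytoplasmic/nascent counts, the rate scale used, and the
#'   TS-outside-mask flag), plus `config`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_cells
  len <- runif(n, config$length_range[1], config$length_range[2])
  wid <- pmin(pmax(rnorm(n, config$width_mean, config$width_sd),
                   config$width_mean - 3 * config$width_sd),
              config$width_mean + 3 * config$width_sd)
  n_nuclei <- 1L + rbinom(n, 1L, config$binucleate_fraction)
  scale <- if (config$size_scaling) len / median(len) else rep(1, n)

  # one SSA draw per nucleus-equivalent; binucleated cells sum `mult` draws
  mult <- ifelse(n_nuclei == 2L, config$binucleate_multiplier, 1L)
  cell_of_draw <- rep(seq_len(n), mult)
  draws <- sample_population(
    config$spec, n_cells = length(cell_of_draw),
    seed = config$seed + 1L,
    rate_scale = scale[cell_of_draw], scale_roles = config$scale_roles)
  true_nuclear <- as.integer(tapply(draws$nuclear, cell_of_draw, sum))
  true_cyto <- as.integer(tapply(draws$cytoplasmic, cell_of_draw, sum))

  true_nascent <- rpois(n, config$nascent_mean * scale * n_nuclei)
  ts_outside <- runif(n) < config$mask_error_rate

  image_id <- sprintf("img%03d", ceiling(seq_len(n) / config$cells_per_image))
  n_img <- length(unique(image_id))
  rep_of_img <- rep(seq_len(config$n_replicates), length.out = n_img)
  replicate_id <- paste0("rep", rep_of_img[match(image_id,
                                                 unique(image_id))])
  cell_id <- sprintf("cell%05d", seq_len(n))

  cells <- tibble::tibble(
    image_id = image_id, cell_id = cell_id, replicate_id = replicate_id,
    length = len, width = wid, n_nuclei = n_nuclei)
  truth <- tibble::tibble(
    cell_id = cell_id, image_id = image_id, replicate_id = replicate_id,
    true_nuclear = true_nuclear, true_cytoplasmic = true_cyto,
    true_nascent = true_nascent, rate_scale = scale,
    ts_outside = ts_outside)
  structure(list(cells = cells, truth = truth, config = config),
            class = "synth_population")
}

# random unit vectors in 3D
runit3 <- function(n) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

# log-normal with median 1 and the requested CV
rintensity <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = 0, sdlog = sdlog)
}

#' Render a population into spot tables
#'
#' Emits the spot-table dialect consumed by the quantification functions:
#' one spot per mature mRNA with log-normal intensity (median 1 at the
#' single-molecule scale, CV from the config, times a per-image gain), and
#' one merged transcription-site spot per nucleus with nascent transcripts
#' whose intensity is the *sum* of its per-molecule intensities. Mature
#' nuclear spots sit at the `mature_scale` distance from the TS, the TS
#' spot at the `nascent_scale` distance, and cytoplasmic spots further out;
#' compartment labels are corrupted only for cells whose TS fell outside
#' the nuclear mask (the TS-associated spot is then labeled cytoplasmic).
#' Deterministic given the config (internally seeded with `seed + 2`).
#'
#' @param population A `"synth_population"` from [generate_population()].
#' @param config Defaults to the population's own config.
#' @return A list with `spots` (tibble: `image_id`, `cell_id`,
#'   `replicate_id`, `compartment`, `x`, `y`, `z`, `intensity_amplitude`,
#'   `true_molecules`) and `ts_spots` (one GFP TS spot per nucleus), plus
#'   `cells` carried through with TS-QC columns added.
#' @export
render_spot_table <- function(population, config = population$config) {
  stopifnot(inherits(population, "synth_population"))
  set.seed(config$seed + 2L)
  truth <- population$truth
  n <- nrow(truth)
  gain_by_img <- rintensity(length(unique(truth$image_id)), config$gain_cv)
  names(gain_by_img) <- unique(truth$image_id)

  spot_rows <- vector("list", n)
  ts_rows <- vector("list", n)
  for (i in seq_len(n)) {
    nn <- population$cells$n_nuclei[i]
    gain <- gain_by_img[[truth$image_id[i]]]
    # one TS per nucleus at a fixed per-nucleus anchor
    ts_xyz <- cbind(x = 3 * (seq_len(nn) - 1), y = 0, z = 0)
    ts_rows[[i]] <- tibble::tibble(
      image_id = truth$image_id[i], cell_id = truth$cell_id[i],
      nucleus = seq_len(nn),
      x = ts_xyz[, 1], y = ts_xyz[, 2], z = ts_xyz[, 3])

    place <- function(k, dist_scale, sdlog) {
      if (k == 0) return(NULL)
      d <- dist_scale * exp(rnorm(k, 0, sdlog))
      anchor <- ts_xyz[sample.int(nn, k, replace = TRUE), , drop = FALSE]
      anchor + runit3(k) * d
    }

    nas <- truth$true_nascent[i]
    nuc <- truth$true_nuclear[i]
    cyt <- truth$true_cytoplasmic[i]
    parts <- list()
    if (nas > 0) {
      # nascent mRNAs merge into a single TS spot per nucleus
      nuc_of <- sample.int(nn, nas, replace = TRUE)
      for (nu in unique(nuc_of)) {
        kk <- sum(nuc_of == nu)
        xyz <- ts_xyz[nu, ] + runit3(1) *
          (config$nascent_scale * exp(rnorm(1, 0, 0.3)))
        parts[[length(parts) + 1L]] <- tibble::tibble(
          compartment = if (truth$ts_outside[i]) "cytoplasmic" else "nuclear",
          x = xyz[1], y = xyz[2], z = xyz[3],
          intensity_amplitude = sum(rintensity(kk, config$intensity_cv)) *
            gain,
          true_molecules = kk)
      }
    }
    if (nuc > 0) {
      xyz <- place(nuc, config$mature_scale, 0.25)
      parts[[length(parts) + 1L]] <- tibble::tibble(
        compartment = "nuclear", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        intensity_amplitude = rintensity(nuc, config$intensity_cv) * gain,
        true_molecules = 1L)
    }
    if (cyt > 0) {
      xyz <- place(cyt, 3.5 * config$mature_scale, 0.35)
      parts[[length(parts) + 1L]] <- tibble::tibble(
        compartment = "cytoplasmic", x = xyz[, 1], y = xyz[, 2],
        z = xyz[, 3],
        intensity_amplitude = rintensity(cyt, config$intensity_cv) * gain,
        true_molecules = 1L)
    }
    if (length(parts)) {
      sp <- dplyr::bind_rows(parts)
      sp$image_id <- truth$image_id[i]
      sp$cell_id <- truth$cell_id[i]
      sp$replicate_id <- truth$replicate_id[i]
      spot_rows[[i]] <- sp
    }
  }
  spots <- dplyr::bind_rows(spot_rows)
  spots <- spots[, c("image_id", "cell_id", "replicate_id", "compartment",
                     "x", "y", "z", "intensity_amplitude",
                     "true_molecules")]
  ts_spots <- dplyr::bind_rows(ts_rows)
  cells <- population$cells
  cells$n_gfp_spots <- 1L  # the renderer labels exactly one TS per nucleus
  cells$cytoplasmic_gfp <- FALSE
  list(spots = spots, ts_spots = ts_spots, cells = cells)
}

#' End-to-end calibration of the counting and noise estimators
#'
#' Generates a population, renders its spot table, runs the counting
#' methods and the size-corrected Fano estimator, and reports each
#' method's bias against the ground truth and against the analytic model
#' moments. This is the harness behind the estimator-calibration tests.
#'
#' @param config A [synth_config()].
#' @param n_boot Bootstrap resamples for the Fano CI.
#' @return A list of class `"roundtrip_report"`: `count_bias` (tibble:
#'   method, compartment, true and estimated mean, relative bias),
#'   `fano` (tibble: analytic Fano, size-corrected hybrid/spot/intensity
#'   Fano with CI and SE for the mononucleated stratum), and the underlying
#'   tables.
#' @export
roundtrip_check <- function(config, n_boot = 2000) {
  pop <- generate_population(config)
  rend <- render_spot_table(pop)
  spots <- normalize_intensities(rend$spots)
  cells <- rend$cells

  methods <- c("spot", "hybrid", "intensity")
  counts <- lapply(methods, function(m)
    count_cells(spots, cells = cells, method = m))
  names(counts) <- methods

  truth <- pop$truth
  truth$true_nuclear_all <- truth$true_nuclear + truth$true_nascent
  bias_rows <- list()
  for (m in methods) {
    ct <- counts[[m]]
    for (cmp in c("nuclear", "cytoplasmic")) {
      est <- ct$count[ct$compartment == cmp][
        match(truth$cell_id, ct$cell_id[ct$compartment == cmp])]
      tru <- if (cmp == "nuclear") truth$true_nuclear_all else
        truth$true_cytoplasmic
      bias_rows[[length(bias_rows) + 1L]] <- tibble::tibble(
        method = m, compartment = cmp,
        mean_true = mean(tru), mean_est = mean(est, na.rm = TRUE),
        rel_bias = mean(est, na.rm = TRUE) / mean(tru) - 1)
    }
  }

  mono <- cells$cell_id[cells$n_nuclei == 1L]
  sizes <- cells$length[match(mono, cells$cell_id)]
  analytic <- steady_state_moments(config$spec)
  fano_rows <- lapply(methods, function(m) {
    ct <- counts[[m]]
    cyt <- ct[ct$compartment == "cytoplasmic", ]
    est <- cyt$count[match(mono, cyt$cell_id)]
    fe <- size_corrected_fano(est, sizes, n_boot = n_boot,
                              seed = config$seed)
    tibble::tibble(method = m, fano_analytic = analytic$fano_cytoplasmic,
                   fano_corrected = fe$fano, lo = fe$ci[1], hi = fe$ci[2],
                   se = fe$se, n_cells = fe$n_cells)
  })
  structure(
    list(count_bias = dplyr::bind_rows(bias_rows),
         fano = dplyr::bind_rows(fano_rows),
         counts = counts, population = pop, spots = spots, cells = cells),
    class = "roundtrip_report")
}

#' @export
print.roundtrip_report <- function(x, ...) {
  cat("<roundtrip_report>\n\nCount bias vs ground truth:\n")
  print(as.data.frame(x$count_bias), digits = 3)
  cat("\nSize-corrected cytoplasmic Fano (mononucleated):\n")
  print(as.data.frame(x$fano), digits = 3)
  invisible(x)
}

#' Write the synthetic spot/cell tables with a YAML config sidecar
#'
#' @param rendered Output of [render_spot_table()].
#' @param dir Output directory (created if needed).
#' @param config The generating [synth_config()] (for the sidecar).
#' @return `dir`, invisibly.
#' @export
write_synth_tables <- function(rendered, dir, config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(rendered$spots),
                     file.path(dir, "spots.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(rendered$ts_spots),
                     file.path(dir, "ts_spots.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(rendered$cells),
                     file.path(dir, "cells.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  sp <- config$spec
  yaml::write_yaml(
    list(model = list(S = sp$S, R = sp$R, kA = sp$k_A, kB = sp$k_B,
                      kC = sp$k_C, kD = sp$k_D, time_unit = sp$time_unit),
         n_cells = config$n_cells, seed = config$seed,
         size_scaling = config$size_scaling,
         intensity_cv = config$intensity_cv,
         binucleate_fraction = config$binucleate_fraction,
         mask_error_rate = config$mask_error_rate),
    file.path(dir, "synth_config.yml"))
  invisible(dir)
}
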