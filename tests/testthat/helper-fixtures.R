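# Shared fixtures, built in code.

# random open-chromatin or telegraph model specs for property loops
random_spec <- function(multi_step = TRUE, telegraph = FALSE,
                        s_max = 4, r_max = 4) {
  S <- if (telegraph) 1L else if (multi_step) sample(2:s_max, 1) else 1L
  R <- sample(seq_len(r_max), 1)
  model_spec(
    S = S, R = R,
    k_A = 10^runif(1, -0.5, 2), k_B = 10^runif(1, -0.5, 2),
    k_C = 10^runif(1, -1, 2),
    chromatin = if (telegraph)
      c(10^runif(1, -1, 1), 10^runif(1, -1, 1)) else NULL)
}

# a tiny one-image spot table with known intensities
tiny_spot_table <- function() {
  tibble::tibble(
    image_id = "img1",
    cell_id = c("c1", "c1", "c1", "c2", "c2", "c2"),
    replicate_id = "rep1",
    compartment = c("cytoplasmic", "cytoplasmic", "cytoplasmic",
                    "cytoplasmic", "nuclear", "nuclear"),
    x = 0, y = 0, z = 0,
    intensity_amplitude = c(2, 4, 6, 4, 12, 4))
}

# per-cell spot table around per-cell TS positions with controlled
# near/far nuclear distances (ground truth in `truth` column)
bimodal_ts_fixture <- function(n_cells = 40, near = 0.2, far = 1.5,
                               seed = 99) {
  set.seed(seed)
  rows <- list()
  ts <- list()
  for (i in seq_len(n_cells)) {
    cid <- sprintf("c%03d", i)
    ts[[i]] <- tibble::tibble(image_id = "img1", cell_id = cid,
                              x = 0, y = 0, z = 0)
    d <- c(near * exp(rnorm(3, 0, 0.2)), far * exp(rnorm(3, 0, 0.2)))
    truth <- rep(c("nascent", "mature_nuclear"), each = 3)
    u <- matrix(rnorm(18), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    rows[[i]] <- tibble::tibble(
      image_id = "img1", cell_id = cid, compartment = "nuclear",
      x = u[, 1] * d, y = u[, 2] * d, z = u[, 3] * d,
      intensity_amplitude = 1, truth = truth)
  }
  list(spots = dplyr::bind_rows(rows), ts_spots = dplyr::bind_rows(ts))
}

# sample Fano factor and its bootstrap SE
fano_with_se <- function(x, n_boot = 200, seed = 1) {
  f <- var(x) / mean(x)
  set.seed(seed)
  n <- length(x)
  reps <- replicate(n_boot, {
    b <- x[sample.int(n, n, replace = TRUE)]
    var(b) / mean(b)
  })
  list(fano = f, se = sd(reps))
}
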