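#' Summary statistics of a per-cell count dataset for ABC
#'
#' The summary vector fitted by the ABC sampler: nuclear and cytoplasmic
#' means and Fano factors. For data, the Fano factors are size-corrected
#' when `sizes` are supplied (the model has no size covariate, so model
#' summaries are always raw — flagged in the documentation of
#' [abc_rejection()]). The nuclear fraction is deliberately excluded from
#' the summaries so it remains available as an independent check of a
#' fitted model.
#'
#' @param nuclear,cytoplasmic Aligned per-cell counts (mononucleated
#'   stratum).
#' @param sizes Optional per-cell sizes; when given, Fano factors are
#'   size-corrected.
#' @return Named numeric vector `mean_nuclear`, `mean_cytoplasmic`,
#'   `fano_nuclear`, `fano_cytoplasmic`.
#' @export
summarize_population <- function(nuclear, cytoplasmic, sizes = NULL) {
  if (!length(nuclear) || !length(cytoplasmic))
    stop("empty dataset", call. = FALSE)
  stopifnot(length(nuclear) == length(cytoplasmic))
  if (is.null(sizes)) {
    fn <- var(nuclear) / mean(nuclear)
    fc <- var(cytoplasmic) / mean(cytoplasmic)
  } else {
    fn <- fano_corrected_point(nuclear, sizes)
    fc <- fano_corrected_point(cytoplasmic, sizes)
  }
  c(mean_nuclear = mean(nuclear), mean_cytoplasmic = mean(cytoplasmic),
    fano_nuclear = fn, fano_cytoplasmic = fc)
}

#' Log-uniform priors for the ABC sampler
#'
#' @param k_A,k_B,k_C Length-2 positive ranges (effective-lifetime units).
#' @return A list of class `"abc_priors"`.
#' @export
abc_priors <- function(k_A = c(1e-1, 1e3), k_B = c(1e-1, 1e3),
                       k_C = c(1e-1, 1e3)) {
  pr <- list(k_A = k_A, k_B = k_B, k_C = k_C)
  ok <- vapply(pr, function(r) length(r) == 2 && all(r > 0) && r[1] < r[2],
               logical(1))
  if (!all(ok)) stop("each prior must be a positive increasing range",
                     call. = FALSE)
  structure(pr, class = "abc_priors")
}

# draw n log-uniform triples from the priors; returns n x 3 matrix
draw_priors <- function(priors, n) {
  m <- vapply(priors, function(r)
    10^runif(n, log10(r[1]), log10(r[2])), numeric(n))
  matrix(m, nrow = n, dimnames = list(NULL, names(priors)))
}

# model summaries for a matrix of (k_A, k_B, k_C) draws at fixed (S, R),
# k_D = R (effective-lifetime units); analytic moments, no simulation.
model_summaries <- function(S, R, draws) {
  template <- model_spec(S = S, R = R, k_A = 1, k_B = 1, k_C = 1,
                         time_unit = "effective_lifetime")
  net <- build_network(template)
  role <- net$role
  i_rem <- which(role == "remodel")
  i_syn <- which(role == "synthesis")
  i_exp <- which(role == "export")
  out <- matrix(NA_real_, nrow(draws), 4,
                dimnames = list(NULL, c("mean_nuclear", "mean_cytoplasmic",
                                        "fano_nuclear", "fano_cytoplasmic")))
  rates <- net$rates
  for (i in seq_len(nrow(draws))) {
    rates[i_rem] <- draws[i, 1]
    rates[i_syn] <- draws[i, 2]
    rates[i_exp] <- draws[i, 3]
    sol <- solve_moments(net, rates)
    out[i, ] <- c(sol$mean_nuclear, sol$mean_cytoplasmic,
                  sol$fano_nuclear, sol$fano_cytoplasmic)
  }
  out
}

# standardized Euclidean distance of each row of `sims` to `obs`;
# `scales` defaults to the per-summary SD over sims, making the distance
# invariant to rescaling any summary by a constant.
abc_distances <- function(sims, obs, scales = NULL) {
  if (is.null(scales)) scales <- apply(sims, 2, sd)
  scales[scales < .Machine$double.eps] <- 1
  sweep(sims, 2, obs) |>
    sweep(2, scales, "/") |>
    (\(z) sqrt(rowSums(z^2)))()
}

#' ABC rejection sampling of the expression rates
#'
#' Fits `(k_A, k_B, k_C)` — promoter remodeling, promoter freeing and
#' nuclear export, relative to the effective cytoplasmic degradation rate
#' (`k_D = R` fixed) — for a given number of transcription and degradation
#' steps `(S, R)`. Each proposal is drawn log-uniformly from the priors;
#' its summary vector (nuclear/cytoplasmic mean and Fano factor) is
#' computed from the *analytic* steady-state moments, which is exact and
#' orders of magnitude faster than per-proposal simulation; the proposals
#' with the smallest standardized Euclidean distance to the data summary
#' are accepted.
#'
#' Note the deliberate asymmetry: data Fano factors should be
#' size-corrected ([summarize_population()] with sizes), while model Fano
#' factors are raw — the model has no cell-size covariate, so the
#' size-corrected data statistic is the comparable quantity.
#'
#' @param data_summary Named summary vector from [summarize_population()].
#' @param S,R Step numbers of the candidate model.
#' @param priors An [abc_priors()].
#' @param n_proposals Number of prior draws (default 10000).
#' @param tolerance_quantile Fraction of proposals accepted (default 0.01).
#' @param seed Integer seed (mandatory).
#' @return An object of class `"abc_posterior"`: tibble `draws` of accepted
#'   `(k_A, k_B, k_C)` with `distance`, plus `tolerance` (the realized
#'   absolute distance threshold), `n_proposals`, `priors`, `seed`, `S`,
#'   `R`, `scales` and `data_summary`.
#' @export
abc_rejection <- function(data_summary, S, R, priors = abc_priors(),
                          n_proposals = 10000, tolerance_quantile = 0.01,
                          seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(inherits(priors, "abc_priors"),
            all(c("mean_nuclear", "mean_cytoplasmic", "fano_nuclear",
                  "fano_cytoplasmic") %in% names(data_summary)),
            tolerance_quantile > 0, tolerance_quantile <= 1)
  if (any(data_summary[c("mean_nuclear", "mean_cytoplasmic")] <= 0))
    stop("data summary means must be positive", call. = FALSE)
  set.seed(seed)
  draws <- draw_priors(priors, n_proposals)
  sims <- model_summaries(S, R, draws)
  obs <- data_summary[colnames(sims)]
  scales <- apply(sims, 2, sd)
  d <- abc_distances(sims, obs, scales)
  tol <- quantile(d, tolerance_quantile, names = FALSE)
  acc <- which(d <= tol)
  if (!length(acc))
    stop("zero acceptances; increase `tolerance_quantile`", call. = FALSE)
  structure(
    list(draws = tibble::tibble(k_A = draws[acc, 1], k_B = draws[acc, 2],
                                k_C = draws[acc, 3], distance = d[acc]),
         tolerance = tol, n_proposals = n_proposals, priors = priors,
         seed = seed, S = S, R = R, scales = scales,
         data_summary = data_summary),
    class = "abc_posterior"
  )
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat(sprintf("<abc_posterior> S = %d, R = %d: %d accepted / %d proposals (tol %.3g)\n",
              x$S, x$R, nrow(x$draws), x$n_proposals, x$tolerance))
  print(posterior_summary(x))
  invisible(x)
}

#' Posterior medians and 95% credible intervals
#'
#' @param post An `"abc_posterior"`.
#' @return A tibble with `parameter`, `median`, `lower`, `upper` (central
#'   95% interval). Fewer than 100 accepted draws triggers a warning.
#' @export
posterior_summary <- function(post) {
  stopifnot(inherits(post, "abc_posterior"))
  dr <- post$draws
  if (nrow(dr) < 100)
    warning("fewer than 100 accepted draws; posterior summaries are coarse",
            call. = FALSE)
  par <- c("k_A", "k_B", "k_C")
  tibble::tibble(
    parameter = par,
    median = vapply(par, function(p) median(dr[[p]]), numeric(1),
                    USE.NAMES = FALSE),
    lower = vapply(par, function(p)
      quantile(dr[[p]], 0.025, names = FALSE), numeric(1),
      USE.NAMES = FALSE),
    upper = vapply(par, function(p)
      quantile(dr[[p]], 0.975, names = FALSE), numeric(1),
      USE.NAMES = FALSE))
}

#' ABC model selection over candidate step numbers
#'
#' Approximate posterior model probabilities over candidate `(S, R)` pairs
#' under a uniform model prior: each candidate receives the same number of
#' prior draws, distances are standardized by the pooled per-summary SD so
#' they are comparable across candidates, and a common absolute tolerance
#' (by default a quantile of the pooled distances) determines acceptance.
#' Probabilities are proportional to acceptance counts. Candidates with
#' `S = 1` cannot produce Fano factors below 1, so sub-Poissonian data
#' summaries drive their probability to ~0.
#'
#' @param data_summary Named summary vector.
#' @param candidates Data frame (or list of pairs) with columns `S` and `R`.
#' @param priors An [abc_priors()] shared by all candidates.
#' @param n_proposals Prior draws per candidate.
#' @param tolerance Common absolute distance threshold; `NULL` (default)
#'   uses the `tolerance_quantile` of the pooled distances.
#' @param tolerance_quantile Pooled-distance quantile used when
#'   `tolerance` is `NULL`.
#' @param seed Integer seed (mandatory).
#' @return A tibble of class `"model_choice"` with `S`, `R`, `n_accepted`,
#'   `probability`; attributes `tolerance` and `ties` (rows of all
#'   candidates sharing the maximum probability — reported, never broken).
#' @export
model_selection <- function(data_summary, candidates,
                            priors = abc_priors(), n_proposals = 5000,
                            tolerance = NULL, tolerance_quantile = 0.01,
                            seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  candidates <- as.data.frame(candidates)
  stopifnot(nrow(candidates) >= 1,
            all(c("S", "R") %in% names(candidates)))
  set.seed(seed)
  sims <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    draws <- draw_priors(priors, n_proposals)
    sims[[i]] <- model_summaries(candidates$S[i], candidates$R[i], draws)
  }
  pooled <- do.call(rbind, sims)
  scales <- apply(pooled, 2, sd)
  obs <- data_summary[colnames(pooled)]
  dists <- lapply(sims, abc_distances, obs = obs, scales = scales)
  if (is.null(tolerance))
    tolerance <- quantile(unlist(dists), tolerance_quantile, names = FALSE)
  n_acc <- vapply(dists, function(d) sum(d <= tolerance), numeric(1))
  if (sum(n_acc) == 0)
    stop("no candidate accepted any proposal; increase the tolerance",
         call. = FALSE)
  out <- tibble::tibble(S = candidates$S, R = candidates$R,
                        n_accepted = as.integer(n_acc),
                        probability = n_acc / sum(n_acc))
  attr(out, "tolerance") <- tolerance
  attr(out, "ties") <- out[out$probability == max(out$probability), ]
  class(out) <- c("model_choice", class(out))
  out
}

#' Write ABC results as delimited text with a YAML provenance sidecar
#'
#' @param post An `"abc_posterior"`.
#' @param path Output path for the accepted-draw table (tab-separated); the
#'   sidecar goes to `<path>.yml`.
#' @return `path`, invisibly.
#' @export
write_abc_posterior <- function(post, path) {
  stopifnot(inherits(post, "abc_posterior"))
  utils::write.table(as.data.frame(post$draws), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  yaml::write_yaml(
    list(S = post$S, R = post$R,
         priors = lapply(unclass(post$priors), as.numeric),
         n_proposals = post$n_proposals,
         tolerance = as.numeric(post$tolerance), seed = post$seed,
         data_summary = as.list(post$data_summary)),
    paste0(path, ".yml"))
  invisible(path)
}
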