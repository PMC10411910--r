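#' Exact stochastic simulation of a reaction network
#'
#' Direct-method Gillespie simulation of a [build_network()] network: a
#' statistically exact sample path of the chemical master equation,
#' reproducible for a fixed seed. Intended for inspecting single
#' trajectories; use [sample_population()] for steady-state ensembles.
#'
#' @param network A `"reaction_network"`.
#' @param t_end Simulation end time (> 0), in the network's time unit.
#' @param seed Integer seed.
#' @param init Optional named integer initial state (one promoter indicator
#'   set); defaults to chromatin open, promoter in `U1`, no mRNA.
#' @param max_events Safety cap on the number of recorded events.
#' @return An object of class `"trajectory"`: list with `times` (strictly
#'   increasing event times, starting at 0), `states` (events x species
#'   integer matrix), `seed` and `spec`.
#'
#' @examples
#' net <- build_network(model_spec(S = 1, R = 1, k_A = 1, k_B = 1, k_C = 1,
#'                                 k_D = 1, time_unit = "absolute"))
#' tr <- ssa_simulate(net, t_end = 20, seed = 7)
#' @export
ssa_simulate <- function(network, t_end, seed, init = NULL,
                         max_events = 1e6) {
  stopifnot(inherits(network, "reaction_network"), t_end > 0)
  if (is.null(init)) init <- initial_state(network)
  init <- init[network$species]
  if (any(is.na(init)) || any(init < 0))
    stop("`init` must be a named non-negative state over all species",
         call. = FALSE)
  prom <- grep("^U", network$species)
  if (sum(init[prom]) != 1L)
    stop("`init` must have exactly one promoter indicator set", call. = FALSE)
  set.seed(seed)
  x <- as.integer(init)
  reactant <- network$reactant
  rates <- network$rates
  stoich <- network$stoich
  times <- numeric(256); nst <- matrix(0L, 256, length(x))
  times[1] <- 0; nst[1, ] <- x
  n <- 1L; t <- 0
  while (n < max_events) {
    a <- rates * x[reactant]
    atot <- sum(a)
    if (atot <= 0) break
    t <- t + stats::rexp(1, atot)
    if (t > t_end) break
    j <- sample.int(length(a), 1L, prob = a)
    x <- x + stoich[, j]
    n <- n + 1L
    if (n > length(times)) {  # grow storage
      times <- c(times, numeric(length(times)))
      nst <- rbind(nst, matrix(0L, nrow(nst), ncol(nst)))
    }
    times[n] <- t; nst[n, ] <- x
  }
  structure(
    list(times = times[seq_len(n)],
         states = `colnames<-`(nst[seq_len(n), , drop = FALSE],
                               network$species),
         seed = seed, t_end = t_end, spec = network$spec),
    class = "trajectory"
  )
}

#' Time-averaged species means of a trajectory
#'
#' Holding-time-weighted average of each species count over the simulated
#' interval, discarding an optional burn-in prefix.
#'
#' @param trajectory A `"trajectory"`.
#' @param burn_in Time before which states are discarded.
#' @return Named numeric vector of time-averaged counts.
#' @export
trajectory_means <- function(trajectory, burn_in = 0) {
  tt <- c(trajectory$times, trajectory$t_end)
  st <- trajectory$states
  keep <- which(tt[-1] > burn_in)
  lo <- pmax(tt[keep], burn_in)
  hi <- tt[keep + 1]
  w <- hi - lo
  colSums(st[keep, , drop = FALSE] * w) / sum(w)
}

#' Steady-state population snapshot by independent SSA runs
#'
#' Simulates `n_cells` independent cells (one SSA realization each, matching
#' the snapshot nature of smFISH) from the standard initial state, records
#' each once after a burn-in of `burn_in_lifetimes` effective cytoplasmic
#' lifetimes, and returns per-cell nuclear (`M_N`) and total cytoplasmic
#' (`sum MC_i`) counts.
#'
#' @param spec A [model_spec()].
#' @param n_cells Number of cells (>= 2; fewer than 30 is flagged as
#'   low-precision).
#' @param seed Integer seed (mandatory; results are reproducible).
#' @param burn_in_lifetimes Burn-in, in units of the effective cytoplasmic
#'   lifetime `R / k_D` (default 10, enough to forget the empty initial
#'   state).
#' @param rate_scale Optional per-cell positive scaling factor (length
#'   `n_cells`) applied to the rates named in `scale_roles`; used by the
#'   synthetic-data generator for size-scaled transcription.
#' @param scale_roles Which reaction roles `rate_scale` multiplies
#'   (default the whole synthesis cycle: `"remodel"` and `"synthesis"`).
#' @return A tibble of class `"population_sample"` with integer columns
#'   `nuclear` and `cytoplasmic`; attributes `spec`, `seed`,
#'   `burn_in_lifetimes`.
#'
#' @examples
#' ps <- sample_population(model_spec(S = 1, R = 1, k_A = 1, k_B = 5,
#'                                    k_C = 10, k_D = 1,
#'                                    time_unit = "absolute"),
#'                         n_cells = 200, seed = 1)
#' colMeans(ps)
#' @export
sample_population <- function(spec, n_cells, seed, burn_in_lifetimes = 10,
                              rate_scale = NULL,
                              scale_roles = c("remodel", "synthesis")) {
  stopifnot(inherits(spec, "model_spec"))
  if (n_cells < 2) stop("`n_cells` must be >= 2 (no variance otherwise)",
                        call. = FALSE)
  if (n_cells < 30)
    warning("n_cells < 30: low-precision population sample", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  net <- build_network(spec)
  t_end <- burn_in_lifetimes / effective_degradation_rate(spec)
  rates <- matrix(net$rates, nrow = n_cells, ncol = length(net$rates),
                  byrow = TRUE)
  if (!is.null(rate_scale)) {
    stopifnot(length(rate_scale) == n_cells, all(rate_scale > 0))
    sc <- net$role %in% scale_roles
    rates[, sc] <- rates[, sc, drop = FALSE] * rate_scale
  }
  set.seed(seed)
  st <- ssa_ensemble_cpp(net$reactant - 1L, net$stoich, rates,
                         as.integer(initial_state(net)), t_end)
  mn <- match("MN", net$species)
  mc <- grep("^MC", net$species)
  out <- tibble::tibble(
    nuclear = st[, mn],
    cytoplasmic = as.integer(rowSums(st[, mc, drop = FALSE])))
  attr(out, "spec") <- spec
  attr(out, "seed") <- seed
  attr(out, "burn_in_lifetimes") <- burn_in_lifetimes
  class(out) <- c("population_sample", class(out))
  out
}

#' Write / read a population sample with its provenance sidecar
#'
#' The sample is written as a two-column tab-separated table and the
#' generating model, seed and burn-in as a YAML sidecar (`<path>.yml`).
#'
#' @param x A `"population_sample"`.
#' @param path Output path for the table.
#' @return `path`, invisibly.
#' @export
write_population <- function(x, path) {
  stopifnot(inherits(x, "population_sample"))
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  spec <- attr(x, "spec")
  side <- list(S = spec$S, R = spec$R, kA = spec$k_A, kB = spec$k_B,
               kC = spec$k_C, kD = spec$k_D, time_unit = spec$time_unit,
               seed = attr(x, "seed"),
               burn_in_lifetimes = attr(x, "burn_in_lifetimes"),
               n_cells = nrow(x))
  if (!is.null(spec$chromatin)) {
    side$k_open <- unname(spec$chromatin[["k_open"]])
    side$k_close <- unname(spec$chromatin[["k_close"]])
  }
  yaml::write_yaml(side, paste0(path, ".yml"))
  invisible(path)
}
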