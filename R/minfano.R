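#' Minimum achievable Fano factor for given step numbers
#'
#' Numerically minimizes the analytic steady-state Fano factor (nuclear or
#' total-cytoplasmic) over the rates `(k_A, k_B, k_C)` at fixed effective
#' degradation rate 1 (`k_D = R`, effective-lifetime units), for an
#' open-chromatin model with `S` transcription steps and `R` degradation
#' steps. The optimization is multi-start (log-scale L-BFGS-B from
#' quasi-random starting points) to be restart-robust; non-convergence of
#' every start is flagged, never silent.
#'
#' For `S = 1` synthesis is a single rate-limiting step, mRNA numbers are
#' Poisson, and the minimum is exactly 1; increasing `S` lowers the
#' attainable minimum below 1.
#'
#' @param S,R Integers >= 1: numbers of transcription and degradation steps.
#' @param compartment `"cytoplasmic"` (default) or `"nuclear"`.
#' @param rate_bounds Length-2 positive numeric: common box for each of
#'   `k_A`, `k_B`, `k_C` (default `c(1e-1, 1e3)` in effective-lifetime
#'   units, several orders of magnitude around the degradation rate).
#' @param n_starts Number of optimizer restarts.
#' @param seed Integer seed for the restart points.
#' @return A list of class `"min_fano"`: `min_value`, `argmin` (named rate
#'   vector), `compartment`, `S`, `R`, `converged` (logical) and `starts`
#'   (per-start minima).
#'
#' @examples
#' min_fano(S = 1, R = 2, n_starts = 4, seed = 1)$min_value  # exactly 1
#' @export
min_fano <- function(S, R, compartment = c("cytoplasmic", "nuclear"),
                     rate_bounds = c(1e-1, 1e3), n_starts = 24, seed = 1) {
  compartment <- match.arg(compartment)
  stopifnot(S >= 1, R >= 1, length(rate_bounds) == 2, all(rate_bounds > 0),
            rate_bounds[1] < rate_bounds[2])
  template <- model_spec(S = S, R = R, k_A = 1, k_B = 1, k_C = 1,
                         time_unit = "effective_lifetime")
  net <- build_network(template)
  role <- net$role
  objective <- function(logk) {
    k <- 10^logk
    rates <- net$rates
    rates[role == "remodel"] <- k[1]
    rates[role == "synthesis"] <- k[2]
    rates[role == "export"] <- k[3]
    sol <- solve_moments(net, rates)
    if (compartment == "cytoplasmic") sol$fano_cytoplasmic else sol$fano_nuclear
  }
  lb <- rep(log10(rate_bounds[1]), 3)
  ub <- rep(log10(rate_bounds[2]), 3)
  set.seed(seed)
  # stratified random starts across the log box
  starts <- matrix(runif(3 * n_starts, min = lb, max = ub),
                   ncol = 3, byrow = TRUE)
  fits <- lapply(seq_len(n_starts), function(i) {
    tryCatch(
      optim(starts[i, ], objective, method = "L-BFGS-B",
            lower = lb, upper = ub,
            control = list(factr = 1e4, maxit = 500)),
      error = function(e) list(value = Inf, par = starts[i, ],
                               convergence = 99L))
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  conv <- vapply(fits, `[[`, numeric(1), "convergence") == 0
  best <- which.min(vals)
  if (!any(conv))
    warning("min_fano: no optimizer start converged; result is flagged",
            call. = FALSE)
  argmin <- 10^fits[[best]]$par
  names(argmin) <- c("k_A", "k_B", "k_C")
  structure(
    list(min_value = vals[best], argmin = argmin,
         compartment = compartment, S = S, R = R,
         converged = any(conv), starts = vals),
    class = "min_fano"
  )
}

#' @export
print.min_fano <- function(x, ...) {
  cat(sprintf("<min_fano> S = %d, R = %d, %s: min = %.6g%s\n",
              x$S, x$R, x$compartment, x$min_value,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  at k_A = %.4g, k_B = %.4g, k_C = %.4g\n",
              x$argmin[1], x$argmin[2], x$argmin[3]))
  invisible(x)
}

#' Nuclear export rate at which nuclear and cytoplasmic Fano factors cross
#'
#' For a sub-Poissonian open-chromatin model the cytoplasmic Fano factor
#' exceeds the nuclear one at slow nuclear export and drops below it at fast
#' export. This locates the export rate `k_C` at which the two analytic Fano
#' factors are equal, by bracketing the sign change of
#' `fano_cytoplasmic - fano_nuclear` on a grid and bisecting to a relative
#' tolerance of 1e-6. The crossover rate decreases with the number of
#' rate-limiting steps at matched `k_A = k_B`.
#'
#' @param spec A [model_spec()] with `chromatin = NULL`; its `k_C` entry is
#'   ignored (swept).
#' @param k_C_grid Positive grid of export rates to scan for a sign change
#'   (default log-spaced `1e-2 ... 1e3` in effective-lifetime units).
#' @return A list of class `"export_crossover"`: `crossover_rate` (`NA` when
#'   no sign change is bracketed), `status` (`"ok"`, `"no crossover in
#'   range"`, or `"degenerate"` when the difference is identically ~0, as
#'   for `S = 1`), and the grid of Fano differences.
#'
#' @examples
#' sp <- model_spec(S = 3, R = 3, k_A = 10, k_B = 10, k_C = 1)
#' export_crossover(sp)$crossover_rate
#' @export
export_crossover <- function(spec,
                             k_C_grid = 10^seq(-2, 3, length.out = 41)) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.null(spec$chromatin))
    stop("export_crossover() expects an open-chromatin spec", call. = FALSE)
  stopifnot(all(k_C_grid > 0), !is.unsorted(k_C_grid))
  net <- build_network(spec)
  role <- net$role
  fdiff <- function(k_C) {
    rates <- net$rates
    rates[role == "export"] <- k_C
    sol <- solve_moments(net, rates)
    sol$fano_cytoplasmic - sol$fano_nuclear
  }
  d <- vapply(k_C_grid, fdiff, numeric(1))
  if (all(abs(d) < 1e-10)) {
    return(structure(list(crossover_rate = NA_real_, status = "degenerate",
                          k_C_grid = k_C_grid, fano_difference = d),
                     class = "export_crossover"))
  }
  sgn <- sign(d)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(flip)) {
    return(structure(list(crossover_rate = NA_real_,
                          status = "no crossover in range",
                          k_C_grid = k_C_grid, fano_difference = d),
                     class = "export_crossover"))
  }
  i <- flip[1]
  root <- uniroot(function(l) fdiff(10^l),
                  lower = log10(k_C_grid[i]), upper = log10(k_C_grid[i + 1]),
                  tol = 1e-6 / log(10))  # ~1e-6 relative in k_C
  structure(list(crossover_rate = 10^root$root, status = "ok",
                 k_C_grid = k_C_grid, fano_difference = d),
            class = "export_crossover")
}

#' @export
print.export_crossover <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("<export_crossover> k_C* = %.6g\n", x$crossover_rate))
  } else {
    cat("<export_crossover>", x$status, "\n")
  }
  invisible(x)
}
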