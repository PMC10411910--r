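#' Specify a multi-step gene expression model
#'
#' Parameterizes the reaction scheme
#' \deqn{U_0 \rightleftharpoons U_1 \to U_2 \to \cdots \to U_S \to U_1 + M_N,
#'       \quad M_N \to MC_1 \to \cdots \to MC_R \to \varnothing}
#' in which a promoter traverses `S` sequential states before each synthesis
#' event (making inter-synthesis wait times narrower than exponential for
#' `S > 1`), mature nuclear mRNA `M_N` is exported to the cytoplasm at rate
#' `k_C`, and cytoplasmic mRNA is degraded through `R` sequential
#' rate-limiting steps. The optional closed-chromatin state `U_0` turns the
#' `S = 1` case into the classical two-state telegraph model.
#'
#' @param S Integer >= 1. Number of sequential promoter states in the
#'   productive cycle (`U_1 ... U_S`).
#' @param R Integer >= 1. Number of sequential cytoplasmic degradation steps.
#' @param k_A Positive rate of each promoter remodeling step
#'   `U_i -> U_{i+1}` (`i = 1 ... S-1`). Unused (but still validated) when
#'   `S = 1`.
#' @param k_B Positive rate of promoter freeing / synthesis
#'   `U_S -> U_1 + M_N`.
#' @param k_C Positive nuclear export rate `M_N -> MC_1`.
#' @param k_D Positive per-step cytoplasmic degradation rate. Defaults to `R`
#'   when `time_unit = "effective_lifetime"`, which fixes the effective
#'   degradation rate (`k_D / R`, the inverse of the summed lifetimes of all
#'   `MC_i`) at 1.
#' @param chromatin `NULL` (chromatin always open; no `U_0` state) or a
#'   numeric vector `c(k_open, k_close)` of positive switching rates
#'   `U_0 -> U_1` and `U_1 -> U_0`.
#' @param time_unit `"absolute"` or `"effective_lifetime"`. In
#'   `"effective_lifetime"` units all rates are relative to the effective
#'   cytoplasmic degradation rate, so `k_D` must equal `R`.
#'
#' @return An object of class `"model_spec"`.
#'
#' @examples
#' # single rate-limiting synthesis step: Poissonian mRNA numbers
#' model_spec(S = 1, R = 1, k_A = 1, k_B = 2, k_C = 4, k_D = 1,
#'            time_unit = "absolute")
#'
#' # three steps in synthesis and degradation, effective-lifetime units
#' model_spec(S = 3, R = 3, k_A = 10, k_B = 10, k_C = 5)
#' @export
model_spec <- function(S, R, k_A, k_B, k_C, k_D = NULL, chromatin = NULL,
                       time_unit = c("effective_lifetime", "absolute")) {
  time_unit <- match.arg(time_unit)
  if (length(S) != 1L || S < 1 || S != round(S))
    stop("`S` must be a single integer >= 1", call. = FALSE)
  if (length(R) != 1L || R < 1 || R != round(R))
    stop("`R` must be a single integer >= 1", call. = FALSE)
  if (is.null(k_D)) {
    if (time_unit == "effective_lifetime") {
      k_D <- as.numeric(R)
    } else {
      stop("`k_D` must be given when time_unit = \"absolute\"", call. = FALSE)
    }
  }
  rates <- c(k_A = k_A, k_B = k_B, k_C = k_C, k_D = k_D)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("all rates must be finite and strictly positive", call. = FALSE)
  if (!is.null(chromatin)) {
    chromatin <- as.numeric(chromatin)
    if (length(chromatin) != 2L || any(!is.finite(chromatin)) ||
        any(chromatin <= 0))
      stop("`chromatin` must be c(k_open, k_close), both positive",
           call. = FALSE)
    names(chromatin) <- c("k_open", "k_close")
  }
  if (time_unit == "effective_lifetime" && abs(k_D / R - 1) > 1e-8)
    stop("in effective-lifetime units the effective degradation rate ",
         "k_D / R must equal 1 (set k_D = R)", call. = FALSE)
  structure(
    list(S = as.integer(S), R = as.integer(R),
         k_A = as.numeric(k_A), k_B = as.numeric(k_B),
         k_C = as.numeric(k_C), k_D = as.numeric(k_D),
         chromatin = chromatin, time_unit = time_unit),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>  S =", x$S, " R =", x$R, "\n")
  cat(sprintf("  k_A = %g  k_B = %g  k_C = %g  k_D = %g\n",
              x$k_A, x$k_B, x$k_C, x$k_D))
  if (is.null(x$chromatin)) {
    cat("  chromatin: always open\n")
  } else {
    cat(sprintf("  chromatin: k_open = %g, k_close = %g\n",
                x$chromatin[["k_open"]], x$chromatin[["k_close"]]))
  }
  cat("  time unit:", x$time_unit, "\n")
  invisible(x)
}

#' Effective cytoplasmic degradation rate of a model
#'
#' The inverse of the summed mean lifetimes of all cytoplasmic degradation
#' intermediates, `k_D / R`. Equals 1 in effective-lifetime units.
#'
#' @param spec A [model_spec()].
#' @return A single positive number.
#' @export
effective_degradation_rate <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  spec$k_D / spec$R
}

#' Read and write model specifications as YAML
#'
#' A `model_spec` serializes to a flat YAML mapping with keys `S`, `R`,
#' `kA`, `kB`, `kC`, `kD`, optionally `k_open`/`k_close`, and `time_unit`.
#'
#' @param spec A [model_spec()].
#' @param path File path.
#' @return `write_model_spec()` returns `path` invisibly;
#'   `read_model_spec()` returns a `model_spec`.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "model_spec"))
  out <- list(S = spec$S, R = spec$R, kA = spec$k_A, kB = spec$k_B,
              kC = spec$k_C, kD = spec$k_D)
  if (!is.null(spec$chromatin)) {
    out$k_open <- unname(spec$chromatin[["k_open"]])
    out$k_close <- unname(spec$chromatin[["k_close"]])
  }
  out$time_unit <- spec$time_unit
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  y <- yaml::read_yaml(path)
  chrom <- if (!is.null(y$k_open)) c(y$k_open, y$k_close) else NULL
  model_spec(S = y$S, R = y$R, k_A = y$kA, k_B = y$kB, k_C = y$kC,
             k_D = y$kD, chromatin = chrom, time_unit = y$time_unit)
}
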