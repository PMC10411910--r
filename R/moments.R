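# Exact steady-state moments of the linear reaction network.
#
# All propensities are first-order, so the moment hierarchy closes exactly.
# The promoter indicators satisfy sum(U_i) = 1; eliminating U1 via that
# conservation law yields an affine system in the remaining species x:
#   propensity a_j(x) = w_j' x + c_j,   dE[x]/dt = A m + b,
# and the (exact) covariance solves the Lyapunov equation
#   A C + C A' + D(m) = 0,  D = sum_j (w_j' m + c_j) s_j s_j'.

# Solve moments for a network, optionally overriding the rate vector
# (same structure, new rates) -- the hot path for ABC and optimization.
solve_moments <- function(network, rates = network$rates) {
  sp <- network$species
  u1 <- match("U1", sp)
  prom <- grep("^U", sp)
  keep <- setdiff(seq_along(sp), u1)
  promk <- setdiff(prom, u1)           # retained promoter species (full idx)
  red <- match(seq_along(sp), keep)    # full index -> reduced index
  Sr <- network$stoich[keep, , drop = FALSE]
  storage.mode(Sr) <- "double"
  r <- network$reactant
  n <- length(keep)
  nrxn <- ncol(Sr)

  W <- matrix(0, nrxn, n)
  cvec <- numeric(nrxn)
  for (j in seq_len(nrxn)) {
    if (r[j] == u1) {
      if (length(promk)) W[j, red[promk]] <- -rates[j]
      cvec[j] <- rates[j]
    } else {
      W[j, red[r[j]]] <- rates[j]
    }
  }
  A <- Sr %*% W
  b <- as.numeric(Sr %*% cvec)
  m <- tryCatch(solve(A, -b), error = function(e)
    stop("singular moment system; spec: ", conditionMessage(e), call. = FALSE))

  amean <- as.numeric(W %*% m) + cvec
  D <- Sr %*% (amean * t(Sr))          # sum_j a_j s_j s_j'
  In <- diag(n)
  K <- kronecker(In, A) + kronecker(A, In)
  Cv <- tryCatch(solve(K, -as.vector(D)), error = function(e)
    stop("singular second-moment system: ", conditionMessage(e),
         call. = FALSE))
  C <- matrix(Cv, n, n)
  C <- (C + t(C)) / 2

  # reconstruct the eliminated U1 row/column from conservation
  nfull <- length(sp)
  mfull <- numeric(nfull)
  mfull[keep] <- m
  mfull[u1] <- 1 - sum(m[red[promk]])
  Cfull <- matrix(0, nfull, nfull, dimnames = list(sp, sp))
  Cfull[keep, keep] <- C
  if (length(promk)) {
    cr <- C[red[promk], , drop = FALSE]
    Cfull[u1, keep] <- -colSums(cr)
    Cfull[keep, u1] <- -colSums(cr)
    Cfull[u1, u1] <- sum(cr[, red[promk], drop = FALSE])
  }
  names(mfull) <- sp

  mn <- match("MN", sp)
  mc <- grep("^MC", sp)
  mean_c <- sum(mfull[mc])
  var_c <- sum(Cfull[mc, mc])
  list(means = mfull, cov = Cfull,
       fano_nuclear = Cfull[mn, mn] / mfull[[mn]],
       fano_cytoplasmic = var_c / mean_c,
       cov_nuc_cyto = sum(Cfull[mn, mc]),
       mean_nuclear = mfull[[mn]], mean_cytoplasmic = mean_c)
}

#' Exact steady-state moments of the gene expression model
#'
#' Solves the steady-state first- and second-moment equations of the full
#' joint state (promoter-state indicators included) exactly, up to linear
#' solver tolerance, and reports the derived noise statistics: the nuclear
#' Fano factor `Var(M_N)/E(M_N)`, the cytoplasmic Fano factor of the
#' *total* cytoplasmic count `C = sum_i MC_i` (smFISH cannot distinguish
#' degradation intermediates, so totals are what data are compared to), and
#' their covariance `Cov(M_N, C)`.
#'
#' For `S = 1` with open chromatin the synthesis process is Poisson and the
#' network is an open linear conversion chain, so both Fano factors are
#' exactly 1 and the covariance 0, whatever the rates. For `S > 1` the
#' narrower-than-exponential synthesis wait times can push both Fano factors
#' below 1; with chromatin switching (`S = 1` telegraph case) they exceed 1.
#'
#' @param spec A [model_spec()].
#' @return An object of class `"moment_solution"`: list with `means` (named
#'   per-species vector), `second_moments` (covariance matrix of the full
#'   state), `fano_nuclear`, `fano_cytoplasmic`, `cov_nuc_cyto`,
#'   `mean_nuclear`, `mean_cytoplasmic` and the `spec`.
#'
#' @examples
#' steady_state_moments(model_spec(S = 1, R = 3, k_A = 1, k_B = 2, k_C = 4))
#' @export
steady_state_moments <- function(spec) {
  net <- build_network(spec)
  sol <- solve_moments(net)
  structure(
    list(means = sol$means, second_moments = sol$cov,
         fano_nuclear = sol$fano_nuclear,
         fano_cytoplasmic = sol$fano_cytoplasmic,
         cov_nuc_cyto = sol$cov_nuc_cyto,
         mean_nuclear = sol$mean_nuclear,
         mean_cytoplasmic = sol$mean_cytoplasmic,
         spec = spec),
    class = "moment_solution"
  )
}

#' @export
print.moment_solution <- function(x, ...) {
  cat("<moment_solution>\n")
  cat(sprintf("  mean nuclear:      %.6g\n", x$mean_nuclear))
  cat(sprintf("  mean cytoplasmic:  %.6g\n", x$mean_cytoplasmic))
  cat(sprintf("  Fano nuclear:      %.6g\n", x$fano_nuclear))
  cat(sprintf("  Fano cytoplasmic:  %.6g\n", x$fano_cytoplasmic))
  cat(sprintf("  Cov(N, C):         %.6g\n", x$cov_nuc_cyto))
  invisible(x)
}

#' Export a moment solution as a delimited table
#'
#' @param x A `"moment_solution"`.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_moment_solution <- function(x, path) {
  stopifnot(inherits(x, "moment_solution"))
  tab <- data.frame(
    quantity = c(paste0("mean_", names(x$means)),
                 "mean_nuclear", "mean_cytoplasmic",
                 "fano_nuclear", "fano_cytoplasmic", "cov_nuc_cyto"),
    value = c(unname(x$means), x$mean_nuclear, x$mean_cytoplasmic,
              x$fano_nuclear, x$fano_cytoplasmic, x$cov_nuc_cyto))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Closed-form mean expression for open-chromatin models
#'
#' Synthesis is a renewal process with cycle time `(S-1)/k_A + 1/k_B`, hence
#' production rate `lambda = 1 / ((S-1)/k_A + 1/k_B)`; the nuclear and total
#' cytoplasmic means are `lambda / k_C` and `lambda * R / k_D`. Serves as an
#' independent closed-form check on [steady_state_moments()].
#'
#' @param spec A [model_spec()] with `chromatin = NULL`.
#' @return Named numeric vector `c(nuclear =, cytoplasmic =)`.
#' @export
mean_expression <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.null(spec$chromatin))
    stop("mean_expression() supports only open-chromatin models ",
         "(chromatin = NULL)", call. = FALSE)
  lambda <- 1 / ((spec$S - 1) / spec$k_A + 1 / spec$k_B)
  c(nuclear = lambda / spec$k_C,
    cytoplasmic = lambda * spec$R / spec$k_D)
}
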