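#' Build the reaction network for a model specification
#'
#' Expands a [model_spec()] into its species list, stoichiometry matrix and
#' rate vector. Every reaction is a first-order conversion (propensity
#' `rate * count(reactant)`), which is what makes the moment equations close
#' exactly and the promoter-state indicators a conserved unit
#' (exactly one `U` state is occupied at any time).
#'
#' Reactions, in order: chromatin opening/closing (iff `chromatin` present),
#' the `S - 1` remodeling steps at `k_A`, synthesis `U_S -> U_1 + M_N` at
#' `k_B`, export `M_N -> MC_1` at `k_C`, and the `R` degradation steps at
#' `k_D` (the last to the empty set).
#'
#' @param spec A [model_spec()].
#' @return An object of class `"reaction_network"`: a list with elements
#'   `species` (character), `stoich` (integer matrix, species x reactions),
#'   `rates` (numeric), `reactant` (integer index of the single reactant of
#'   each reaction), `role` (character label per reaction) and `spec`.
#'
#' @examples
#' net <- build_network(model_spec(S = 3, R = 3, k_A = 10, k_B = 10, k_C = 5))
#' ncol(net$stoich)  # 2 remodeling + synthesis + export + 3 decay = 7
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  S <- spec$S; R <- spec$R
  chrom <- !is.null(spec$chromatin)
  species <- c(if (chrom) "U0", paste0("U", seq_len(S)), "MN",
               paste0("MC", seq_len(R)))
  idx <- function(nm) match(nm, species)
  reactions <- list()
  add <- function(reactant, change, rate, role) {
    reactions[[length(reactions) + 1L]] <<- list(
      reactant = idx(reactant), change = change, rate = rate, role = role)
  }
  if (chrom) {
    add("U0", c(U0 = -1L, U1 = +1L), spec$chromatin[["k_open"]], "open")
    add("U1", c(U1 = -1L, U0 = +1L), spec$chromatin[["k_close"]], "close")
  }
  if (S > 1) {
    for (i in seq_len(S - 1)) {
      add(paste0("U", i),
          setNames(c(-1L, +1L), paste0("U", c(i, i + 1))),
          spec$k_A, "remodel")
    }
  }
  synth_change <- if (S > 1) {
    setNames(c(-1L, +1L, +1L), c(paste0("U", S), "U1", "MN"))
  } else {
    c(MN = +1L)  # U1 -> U1 + MN leaves the promoter unchanged
  }
  add(paste0("U", S), synth_change, spec$k_B, "synthesis")
  add("MN", c(MN = -1L, MC1 = +1L), spec$k_C, "export")
  if (R > 1) {
    for (i in seq_len(R - 1)) {
      add(paste0("MC", i),
          setNames(c(-1L, +1L), paste0("MC", c(i, i + 1))),
          spec$k_D, "decay")
    }
  }
  add(paste0("MC", R), setNames(-1L, paste0("MC", R)), spec$k_D, "decay")

  nrxn <- length(reactions)
  stoich <- matrix(0L, nrow = length(species), ncol = nrxn,
                   dimnames = list(species, NULL))
  for (j in seq_len(nrxn)) {
    ch <- reactions[[j]]$change
    stoich[names(ch), j] <- stoich[names(ch), j] + ch
  }
  structure(
    list(species = species, stoich = stoich,
         rates = vapply(reactions, `[[`, numeric(1), "rate"),
         reactant = vapply(reactions, `[[`, integer(1), "reactant"),
         role = vapply(reactions, `[[`, character(1), "role"),
         spec = spec),
    class = "reaction_network"
  )
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network>", length(x$species), "species,",
      ncol(x$stoich), "reactions\n")
  cat("  species:", paste(x$species, collapse = " "), "\n")
  invisible(x)
}

# Default initial state for simulation: chromatin open, promoter in U1,
# no mRNA anywhere.
initial_state <- function(network) {
  x <- setNames(integer(length(network$species)), network$species)
  x["U1"] <- 1L
  x
}
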