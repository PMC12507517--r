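# Equilibrium occupancy projection from dissociation constants.

#' Equilibrium fraction of sites bound by a transcription factor
#'
#' Under the free-ligand approximation (site concentration much smaller than
#' the free nuclear TF concentration C), the equilibrium fractional
#' occupancy of a site with dissociation constant K_D is
#' `f = C / (C + K_D)`. With a nuclear RelA dimer concentration of ~200 nM
#' and a weak site of K_D ~3 uM this projects to f = 0.0625, i.e. only
#' about 6% of such sites bound at equilibrium — the scale of occupancy a
#' single weak kB site can reach on its own.
#'
#' @param concentration free nuclear TF dimer concentration, nM (> 0).
#' @param kd equilibrium dissociation constant, nM (> 0). Both arguments
#'   are recycled to a common length.
#' @return Fraction bound in (0, 1).
#' @examples
#' fraction_bound(200, 3000)       # ~6% bound
#' fraction_bound(100, 100)        # half-saturation
#' @export
fraction_bound <- function(concentration, kd) {
  concentration <- as.numeric(concentration)
  kd <- as.numeric(kd)
  if (any(!is.finite(concentration)) || any(concentration <= 0))
    stop("concentration must be a positive finite number (nM)")
  if (any(!is.finite(kd)) || any(kd <= 0))
    stop("kd must be a positive finite number (nM)")
  concentration / (concentration + kd)
}

#' Grid of equilibrium occupancies over concentrations and K_D values
#'
#' @param concentrations numeric vector of TF concentrations, nM.
#' @param kds numeric vector of dissociation constants, nM.
#' @return Matrix of fractions bound with one row per concentration and one
#'   column per K_D; monotone increasing down the rows (concentration) and
#'   decreasing across the columns (K_D). Empty inputs give an empty grid.
#' @export
occupancy_table <- function(concentrations, kds) {
  if (!length(concentrations) || !length(kds)) {
    out <- matrix(numeric(0), nrow = length(concentrations),
                  ncol = length(kds))
  } else {
    out <- outer(concentrations, kds, fraction_bound)
  }
  dimnames(out) <- list(conc_nM = as.character(concentrations),
                        kd_nM = as.character(kds))
  out
}
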