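#' Unit conventions
#'
#' Toy surfaces work in model units: mass = 1, energy, length and time
#' dimensionless, Boltzmann constant \eqn{k_B = 1} (the fictitious
#' temperature then carries energy units directly).  For molecular systems
#' described in kcal/mol, Angstrom and amu, a single conversion keeps the
#' kinetic prefactor \eqn{m/(2\Delta^2)} of the discretized Lagrangian
#' dimensionally consistent with the potential: with time in picoseconds,
#' \deqn{1\ \mathrm{kcal/mol} = 418.4\ \mathrm{amu\,\AA^2/ps^2},}
#' so energies are converted to amu A^2/ps^2 before entering the action, and
#' \eqn{k_B = 0.0019872\ \mathrm{kcal/mol\,K} = 0.8314\ \mathrm{amu\,\AA^2/ps^2\,K}}.
#'
#' @return named numeric vector of conversion constants.
#' @examples
#' unitConstants()["kcalPerMol"]  # in amu A^2 / ps^2
#' @export
unitConstants <- function() {
  c(kcalPerMol = 418.4,          # amu A^2 / ps^2
    kBkcalMolK = 0.0019872,      # kcal / (mol K)
    kBamuA2ps2K = 0.8314)        # amu A^2 / (ps^2 K)
}

## atomic masses (amu) used when reading structures / building fixtures
.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974)

elementMass <- function(element) {
  m <- .ELEMENT_MASS[element]
  if (anyNA(m))
    stop("no mass tabulated for element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  unname(m)
}
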