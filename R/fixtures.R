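## Seeded toy-protein fixtures: a glycine/alanine-like backbone (N, H, CA,
## CB, C, O per residue) built from ideal bond lengths and angles with
## helical or extended dihedrals.  The native endpoint is a compact helix
## (with native contacts and backbone hydrogen bonds under the standard
## rules); the disordered endpoint is the same covalent geometry with
## extended dihedrals plus a seeded perturbation, so it has no native
## contacts, no hydrogen bonds, and a larger radius of gyration.

.cross3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

.unit <- function(v) v / sqrt(sum(v^2))

## natural-extension-reference-frame placement: position a new atom at the
## given bond length / bond angle / dihedral relative to atoms a-b-c
placeAtom <- function(a, b, c, bond, angleDeg, dihedralDeg) {
  ang <- angleDeg * pi / 180
  dih <- dihedralDeg * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
         bond * sin(ang) * sin(dih))
  c + d[1] * bc + d[2] * m + d[3] * n
}

## ideal backbone geometry (lengths in Angstrom, angles in degrees)
.GEO <- list(nca = 1.458, cac = 1.525, cn = 1.329, co = 1.231, nh = 1.01,
             cacb = 1.53,
             angNCAC = 111.2, angCACN = 116.2, angCNCA = 121.7,
             angCACO = 120.5, angCCACB = 110.5, dihNCCACB = 122.5,
             omega = 180)

.buildChain <- function(nres, phi, psi) {
  g <- .GEO
  N <- CA <- C <- O <- H <- CB <- matrix(NA_real_, nres, 3L)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$nca, 0, 0)
  a <- g$angNCAC * pi / 180
  C[1, ] <- CA[1, ] + g$cac * c(-cos(a), sin(a), 0)
  for (i in 2:nres) {
    N[i, ] <- placeAtom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], g$cn,
                        g$angCACN, psi)
    CA[i, ] <- placeAtom(CA[i - 1, ], C[i - 1, ], N[i, ], g$nca,
                         g$angCNCA, g$omega)
    C[i, ] <- placeAtom(C[i - 1, ], N[i, ], CA[i, ], g$cac,
                        g$angNCAC, phi)
  }
  for (i in 1:nres) {
    # carbonyl O in the peptide plane, trans to the next N
    O[i, ] <- placeAtom(N[i, ], CA[i, ], C[i, ], g$co, g$angCACO,
                        psi - 180)
    CB[i, ] <- placeAtom(N[i, ], C[i, ], CA[i, ], g$cacb, g$angCCACB,
                         g$dihNCCACB)
    if (i > 1) {
      # amide H along the in-plane bisector, trans to the carbonyl
      u <- -.unit(.unit(CA[i, ] - N[i, ]) + .unit(C[i - 1, ] - N[i, ]))
      H[i, ] <- N[i, ] + g$nh * u
    }
  }
  list(N = N, CA = CA, C = C, O = O, H = H, CB = CB)
}

.assembleAtoms <- function(chain, nres) {
  names <- character(0); resid <- integer(0); coords <- NULL
  for (i in 1:nres) {
    order <- c("N", if (i > 1) "H", "CA", "CB", "C", "O")
    for (at in order) {
      names <- c(names, at)
      resid <- c(resid, i)
      coords <- rbind(coords, chain[[at]][i, ])
    }
  }
  list(names = names, resid = resid, coords = coords)
}

#' Generate a toy protein fixture
#'
#' Builds a small peptide-like chain twice from identical ideal covalent
#' geometry: once with helical backbone dihedrals (the compact native
#' endpoint) and once with extended dihedrals plus a seeded random
#' perturbation (the disordered endpoint).  The native endpoint has native
#' contacts and backbone hydrogen bonds under the standard rules; the
#' disordered endpoint has neither, and a larger radius of gyration.
#'
#' @param nres chain length in residues (>= 3).
#' @param seed integer seed (the fixture is deterministic in it).
#' @param noise amplitude (Angstrom) of the perturbation applied to the
#'   disordered endpoint; the native endpoint is never perturbed, so it
#'   remains an exact minimum of the Go-chain potential built from it.
#' @param phiHelix,psiHelix native backbone dihedrals (degrees).
#' @param phiExt,psiExt disordered backbone dihedrals (degrees).
#' @return list with `system` (a [MolecularSystem]), `native` and
#'   `disordered` (atoms x 3 coordinate matrices).
#' @examples
#' toy <- makeToyProtein(nres = 10, seed = 7)
#' radiusOfGyration(toy$disordered) > radiusOfGyration(toy$native)
#' @export
makeToyProtein <- function(nres = 12L, seed = 1L, noise = 0.05,
                           phiHelix = -57, psiHelix = -47,
                           phiExt = -135, psiExt = 135) {
  nres <- as.integer(nres)
  if (nres < 3L) stop("nres must be >= 3")
  stopifnot(noise >= 0)
  nat <- .assembleAtoms(.buildChain(nres, phiHelix, psiHelix), nres)
  dis <- .assembleAtoms(.buildChain(nres, phiExt, psiExt), nres)
  disCoords <- dis$coords
  if (noise > 0)
    disCoords <- disCoords + withSeed(seed,
      matrix(stats::rnorm(length(disCoords), sd = noise),
             nrow(disCoords), 3L))
  elements <- substr(nat$names, 1L, 1L)
  system <- new("MolecularSystem",
                atomNames = nat$names, elements = elements,
                masses = elementMass(elements),
                resid = nat$resid,
                resname = rep("ALA", length(nat$names)),
                role = .roleFromName(nat$names))
  list(system = system, native = unname(nat$coords),
       disordered = unname(disCoords))
}
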