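#' Monoisotopic mass table for glycan arithmetic
#'
#' Single source of truth for every mass computation in the package:
#' monoisotopic residue (dehydrated monomer) masses in Da for the four
#' monosaccharide classes used in N-glycan compositions, plus the masses of
#' water, the proton, and the +2H reducing-end reduction (alditol) delta.
#'
#' @return A named list with components `residues` (named numeric vector with
#'   entries `hex`, `hexnac`, `fuc`, `neuac`), `water`, `proton`, and
#'   `reduction`.
#' @examples
#' mass_table()$residues[["hexnac"]]
#' @export
mass_table <- function() {
  list(
    residues = c(
      hex    = 162.052824,  # Hex (Man/Gal/Glc)
      hexnac = 203.079373,  # HexNAc (GlcNAc/GalNAc)
      fuc    = 146.057909,  # dHex (Fuc)
      neuac  = 291.095417   # NeuAc (sialic acid)
    ),
    water     = 18.010565,
    proton    = 1.007276,
    reduction = 2.015650    # open-chain alditol, +2H
  )
}

.MASS <- mass_table()

#' Neutral monoisotopic mass of a glycan composition
#'
#' Sum of residue masses plus one water for the intact glycan; reduced
#' (alditol) glycans, the default form after PNGase F release and
#' borohydride reduction for PGC-LC-MS, carry an additional +2H.
#'
#' @param comp A [glycan_composition] object or a composition string such as
#'   `"H5N4F1S2"`.
#' @param reduced Logical; is the reducing end an alditol? Default `TRUE`.
#' @return Neutral mass in Da.
#' @examples
#' neutral_mass("H6N2F1")            # reduced core-fucosylated Man6
#' neutral_mass("H2N2", reduced = TRUE)
#' @export
neutral_mass <- function(comp, reduced = TRUE) {
  comp <- as_glycan_composition(comp)
  stopifnot(is.logical(reduced), length(reduced) == 1L, !is.na(reduced))
  sum(unclass(comp) * .MASS$residues) + .MASS$water +
    if (reduced) .MASS$reduction else 0
}

#' m/z of a deprotonated glycan ion
#'
#' Negative-mode electrospray of released glycans yields `[M - zH]^z-` ions;
#' the m/z is `(M - z * proton) / z`.
#'
#' @inheritParams neutral_mass
#' @param charge Positive integer charge state (number of protons removed).
#' @return m/z of the deprotonated ion.
#' @examples
#' glycan_mz("H6N2F1", charge = 2)   # ~771.27, the (M-2H)2- ion of Man6Fuc
#' @export
glycan_mz <- function(comp, charge = 1L, reduced = TRUE) {
  stopifnot(is.numeric(charge), length(charge) == 1L, is.finite(charge))
  if (charge < 1 || charge != round(charge)) {
    stop("`charge` must be a positive integer, got ", charge)
  }
  m <- neutral_mass(comp, reduced = reduced)
  (m - charge * .MASS$proton) / charge
}

# m/z of an arbitrary neutral fragment mass (internal)
.mz_from_neutral <- function(neutral, charge) {
  (neutral - charge * .MASS$proton) / charge
}
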