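## 3-letter -> 1-letter residue mapping. MSE (selenomethionine) is the one
## modified residue kept in chains; everything else non-standard maps to X.

.AA321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

.AA1 <- unname(.AA321)

.AA123 <- structure(names(.AA321), names = .AA321)

#' Map 3-letter residue names to 1-letter codes
#'
#' The 20 standard residues map to their usual letters; selenomethionine
#' (\code{MSE}) maps to \code{M} when \code{mseToMet} is TRUE (the default,
#' since MSE substitutes for methionine in crystallographic constructs); any
#' other name maps to \code{X}.
#'
#' @param resid character vector of 3-letter residue names.
#' @param mseToMet logical; map MSE to M instead of X.
#' @return character vector of single letters.
#' @examples
#' aaThreeToOne(c("GLN", "LYS", "MSE", "SEP"))
#' @export
aaThreeToOne <- function(resid, mseToMet = TRUE) {
  resid <- toupper(trimws(resid))
  one <- unname(.AA321[resid])
  one[is.na(one)] <- "X"
  if (mseToMet) one[resid == "MSE"] <- "M"
  one
}
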