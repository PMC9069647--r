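## Synthetic stand-in structures for well-known reference entries.
##
## These are NOT the deposited coordinates: they are generator-built
## cross-beta models carrying the biologically relevant sequence with the
## strand planted at the documented boundary, so the worked examples of the
## boundary-prefix analysis can run without any download. Each stand-in is
## keyed by the PDB code of the entry it emulates.

#' Sequences used by the synthetic stand-ins
#'
#' \describe{
#'   \item{abeta40}{amyloid-beta(1-40), the peptide of the amyloid fibril
#'     entries 2MPZ/2LMN/2LMO/2LMP/2LMQ/2LNQ; numbering starts at D1. Its
#'     residues 13-19 (HHQKLVF) carry all three fibril boundary prefixes
#'     HHQKL, HQKLV and QKLVF, depending on where the beta-strand starts.}
#'   \item{p53tet}{the p53 tetramerization-domain region around the
#'     beta-strand that starts at GE|YFT (entries 1OLG/1SAE/...).}
#'   \item{tap_like}{a synthetic tick-anticoagulant-peptide-like sequence
#'     containing the GGERA motif, standing in for the 1TCP chain.}
#'   \item{bin1_like}{a synthetic alpha-helical BAR-domain-like sequence
#'     containing HQKLV in a helix, standing in for the 2FIC chain.}
#'   \item{cyanase_like}{a synthetic bacterial-cyanase-like sequence whose
#'     beta-strand starts at GG|ERA (entries 1DW9/1DWK/2IU7/2IV1/2IVQ/2Y42).}
#' }
#'
#' @format named character vector of amino-acid strings.
#' @seealso [standInSheetSpec()], [standInSequenceCollection()]
#' @export
standInSequences <- c(
  abeta40 = "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVV",
  p53tet = "KKPLDGEYFTLQIRGRERFEMFRELNEALELKDAQAGKE",
  tap_like = "YNRLCIKPRDWIDECDSNEGGERAYFRNGKGGCDSFWICPEDHTGADYYSSYRDCFNACI",
  bin1_like = "MADIKTGIFAKNVQKRLNRAQEKVLQKLGKHQKLVAEGHELSAHNAYLKSLEAFSREL",
  cyanase_like = "MNREAIAKTLVALGGERAFVTLAQEAGLSEAFVTAALLGQQALPADAARLVG")

## entry -> stand-in recipe
.STANDINS <- list(
  `2MPZ` = list(seqname = "abeta40", segmentStart = 17L, segmentLength = 9L,
                methodClass = "NMR"),
  `2LMN` = list(seqname = "abeta40", segmentStart = 17L, segmentLength = 9L,
                methodClass = "NMR"),
  `2LMO` = list(seqname = "abeta40", segmentStart = 17L, segmentLength = 9L,
                methodClass = "NMR"),
  `2LMP` = list(seqname = "abeta40", segmentStart = 17L, segmentLength = 9L,
                methodClass = "NMR"),
  `2LMQ` = list(seqname = "abeta40", segmentStart = 17L, segmentLength = 9L,
                methodClass = "NMR"),
  `2LNQ` = list(seqname = "abeta40", segmentStart = 17L, segmentLength = 9L,
                methodClass = "NMR"),
  `5KK3` = list(seqname = "abeta40", segmentStart = 15L, segmentLength = 9L,
                methodClass = "NMR"),
  `1OLG` = list(seqname = "p53tet", segmentStart = 8L, segmentLength = 7L,
                methodClass = "NMR"),
  `1SAE` = list(seqname = "p53tet", segmentStart = 8L, segmentLength = 7L,
                methodClass = "NMR"),
  `1SAF` = list(seqname = "p53tet", segmentStart = 8L, segmentLength = 7L,
                methodClass = "NMR"),
  `1SAK` = list(seqname = "p53tet", segmentStart = 8L, segmentLength = 7L,
                methodClass = "NMR"),
  `1SAL` = list(seqname = "p53tet", segmentStart = 8L, segmentLength = 7L,
                methodClass = "NMR"),
  `3SAK` = list(seqname = "p53tet", segmentStart = 8L, segmentLength = 7L,
                methodClass = "NMR"),
  `1DW9` = list(seqname = "cyanase_like", segmentStart = 16L,
                segmentLength = 8L, methodClass = "XRAY"),
  `1DWK` = list(seqname = "cyanase_like", segmentStart = 16L,
                segmentLength = 8L, methodClass = "XRAY"),
  `2IU7` = list(seqname = "cyanase_like", segmentStart = 16L,
                segmentLength = 8L, methodClass = "XRAY"),
  `2IV1` = list(seqname = "cyanase_like", segmentStart = 16L,
                segmentLength = 8L, methodClass = "XRAY"),
  `2IVQ` = list(seqname = "cyanase_like", segmentStart = 16L,
                segmentLength = 8L, methodClass = "XRAY"),
  `2Y42` = list(seqname = "cyanase_like", segmentStart = 16L,
                segmentLength = 8L, methodClass = "XRAY"))

#' Sheet specification of a synthetic stand-in entry
#'
#' Builds the [sheetSpec()] of the generator-based stand-in for one of the
#' reference entries of the boundary-prefix survey. The stand-in is a
#' synthetic in-register cross-beta model -- not the deposited structure --
#' whose chains carry the relevant sequence with the beta-strand planted at
#' the documented boundary, e.g. the amyloid-beta strand starting at L17 so
#' the boundary prefix is QK|LVF for the 2MPZ-like fibril, or the p53
#' strand starting at Y so the prefix is GE|YFT for the 1OLG-like tetramer.
#'
#' @param entry a PDB code with a defined stand-in (see
#'   [standInSequences]): the amyloid-beta entries 2MPZ, 2LMN, 2LMO, 2LMP,
#'   2LMQ, 2LNQ, 5KK3; the p53 entries 1OLG, 1SAE, 1SAF, 1SAK, 1SAL, 3SAK;
#'   the cyanase entries 1DW9, 1DWK, 2IU7, 2IV1, 2IVQ, 2Y42.
#' @param segmentStart optional override of the planted strand start, to
#'   emulate a polymorph whose strand begins elsewhere (e.g. 16 on the
#'   amyloid-beta entries yields the HQ|KLV boundary).
#' @param nChains,nModels,noiseSD,seed passed to [sheetSpec()].
#' @return a [sheetSpec()].
#' @examples
#' sheetGroundTruth(standInSheetSpec("2MPZ"))$prefix   # "QKLVF"
#' sheetGroundTruth(standInSheetSpec("1OLG"))$prefix   # "GEYFT"
#' @export
standInSheetSpec <- function(entry, segmentStart = NULL, nChains = 3L,
                             nModels = 1L, noiseSD = 0, seed = 1L) {
  if (!entry %in% names(.STANDINS))
    stop("no synthetic stand-in defined for '", entry, "'")
  rec <- .STANDINS[[entry]]
  sheetSpec(standInSequences[[rec$seqname]],
            segmentStart = if (is.null(segmentStart)) rec$segmentStart
                           else segmentStart,
            segmentLength = rec$segmentLength, nChains = nChains,
            nModels = nModels, noiseSD = noiseSD, seed = seed,
            entryID = entry, methodClass = rec$methodClass)
}

#' Stand-in sequence collection for k-mer search examples
#'
#' A small sequence collection standing in for whole-PDB searches: the
#' TAP-like record (id 1TCP) containing GGERA, the helical BIN1-like record
#' (id 2FIC) containing HQKLV, and the amyloid-beta record (id 2MPZ).
#' Synthetic stand-ins; see [standInSequences].
#'
#' @return data.frame with columns \code{id, chain, sequence}, usable as a
#'   [searchKmer()] collection.
#' @export
standInSequenceCollection <- function() {
  data.frame(
    id = c("1TCP", "2FIC", "2MPZ"),
    chain = "A",
    sequence = unname(standInSequences[c("tap_like", "bin1_like", "abeta40")]),
    stringsAsFactors = FALSE)
}
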