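#' @import methods
NULL

#' Geometric filter parameters for parallel beta-sheet detection
#'
#' Container for the thresholds of the geometric amyloid filter. A pair of
#' equal-length residue runs on two distinct chains is accepted as a parallel
#' beta-sheet segment pair when (a) every per-position C-alpha distance lies
#' in \code{[dMin, dMax]}, (b) the population standard deviation of the
#' distance profile is below \code{sigmaMax}, (c) both runs are straight
#' (end-to-end over contour length at least \code{straightnessMin}, the
#' operational curvature exclusion), (d) the runs point the same way
#' (normalised end-to-end dot product at least \code{parallelDotMin}), and
#' (e) the segment covers at least the fraction \code{coverageMin} of the
#' resolved length of at least one parent chain (both chains if
#' \code{coverageBoth}).
#'
#' @slot dMin minimum inter-strand C-alpha distance, Angstrom (default 2).
#' @slot dMax maximum inter-strand C-alpha distance, Angstrom (default 15).
#' @slot sigmaMax upper bound on the distance-profile standard deviation,
#'   Angstrom (default 1.5). Population form (denominator L).
#' @slot coverageMin minimum segment length over resolved chain length
#'   (default 1/7).
#' @slot minSegmentLength shortest reportable segment, residues (default 3,
#'   the core length of a boundary prefix).
#' @slot straightnessMin minimum end-to-end / contour-length ratio of each
#'   run (default 0.9); curved runs such as helices fall well below it.
#' @slot parallelDotMin minimum normalised dot product of the two run
#'   direction vectors (default 0.5); anti-parallel runs are negative.
#' @slot offsetScan non-negative integer; registration offsets
#'   \code{-offsetScan .. offsetScan} between residue indices of the two
#'   chains are scanned (default 0: strictly in-register pairing, the
#'   cross-beta amyloid hallmark).
#' @slot coverageBoth logical; require the coverage criterion on both parent
#'   chains instead of at least one (default FALSE).
#' @slot maxGapDistance consecutive C-alpha distance above which a chain is
#'   considered broken, Angstrom (default 4.5).
#'
#' @examples
#' GeometryParams()
#' GeometryParams(sigmaMax = 1.0, offsetScan = 2L)
#' @export
setClass("GeometryParams", representation(
  dMin = "numeric", dMax = "numeric", sigmaMax = "numeric",
  coverageMin = "numeric", minSegmentLength = "integer",
  straightnessMin = "numeric", parallelDotMin = "numeric",
  offsetScan = "integer", coverageBoth = "logical",
  maxGapDistance = "numeric"
))

setValidity("GeometryParams", function(object) {
  msg <- character()
  if (!(object@dMin > 0 && object@dMin < object@dMax))
    msg <- c(msg, "need 0 < dMin < dMax")
  if (object@sigmaMax <= 0) msg <- c(msg, "sigmaMax must be positive")
  if (!(object@coverageMin > 0 && object@coverageMin <= 1))
    msg <- c(msg, "coverageMin must be in (0, 1]")
  if (object@minSegmentLength < 3L)
    msg <- c(msg, "minSegmentLength must be >= 3")
  if (!(object@straightnessMin > 0 && object@straightnessMin <= 1))
    msg <- c(msg, "straightnessMin must be in (0, 1]")
  if (!(object@parallelDotMin > 0 && object@parallelDotMin <= 1))
    msg <- c(msg, "parallelDotMin must be in (0, 1]")
  if (object@offsetScan < 0L) msg <- c(msg, "offsetScan must be >= 0")
  if (object@maxGapDistance <= 0) msg <- c(msg, "maxGapDistance must be positive")
  if (length(msg)) msg else TRUE
})

#' @param dMin,dMax,sigmaMax,coverageMin,minSegmentLength,straightnessMin,parallelDotMin,offsetScan,coverageBoth,maxGapDistance
#'   see slot documentation.
#' @return a validated \code{GeometryParams} object.
#' @rdname GeometryParams-class
#' @export
GeometryParams <- function(dMin = 2, dMax = 15, sigmaMax = 1.5,
                           coverageMin = 1 / 7, minSegmentLength = 3L,
                           straightnessMin = 0.9, parallelDotMin = 0.5,
                           offsetScan = 0L, coverageBoth = FALSE,
                           maxGapDistance = 4.5) {
  new("GeometryParams",
      dMin = as.numeric(dMin), dMax = as.numeric(dMax),
      sigmaMax = as.numeric(sigmaMax), coverageMin = as.numeric(coverageMin),
      minSegmentLength = as.integer(minSegmentLength),
      straightnessMin = as.numeric(straightnessMin),
      parallelDotMin = as.numeric(parallelDotMin),
      offsetScan = as.integer(offsetScan),
      coverageBoth = isTRUE(coverageBoth),
      maxGapDistance = as.numeric(maxGapDistance))
}

setMethod("show", "GeometryParams", function(object) {
  cat("GeometryParams\n")
  cat(sprintf("  distance band   : [%.2f, %.2f] Angstrom\n", object@dMin, object@dMax))
  cat(sprintf("  sd bound        : < %.2f Angstrom (population)\n", object@sigmaMax))
  cat(sprintf("  coverage        : >= %.4f of resolved chain length (%s)\n",
              object@coverageMin, if (object@coverageBoth) "both chains" else "either chain"))
  cat(sprintf("  straightness    : >= %.2f ; parallel dot >= %.2f\n",
              object@straightnessMin, object@parallelDotMin))
  cat(sprintf("  min length      : %d residues ; offset scan +/- %d ; gap > %.1f A breaks\n",
              object@minSegmentLength, object@offsetScan, object@maxGapDistance))
  invisible(object)
})

## ---------------------------------------------------------------------------

.chainColumns <- c("resno", "ins", "resid", "aa", "x", "y", "z")

#' Parsed protein structure (C-alpha model)
#'
#' In-memory model of the coordinate section of one PDB/mmCIF entry, as used
#' by the sheet-geometry pipeline: for every model, every chain is a
#' data.frame of residues in author (N- to C-terminal) order with author
#' residue number, insertion code, 3-letter and 1-letter residue name, and
#' the C-alpha position (NA when unresolved). Experimental-method metadata is
#' reduced to the class used to partition count tables: \code{"NMR"}
#' (solution or solid-state), \code{"XRAY"}, or \code{"OTHER"}.
#'
#' @slot entryID 4-character PDB code or a synthetic label.
#' @slot methodClass one of \code{"NMR"}, \code{"XRAY"}, \code{"OTHER"}.
#' @slot models list of models; each model a named list of chain data.frames
#'   with columns \code{resno, ins, resid, aa, x, y, z}.
#' @slot seqres named list (chain id -> 1-letter sequence string) from SEQRES
#'   records when the source file carried them; empty otherwise. Sequences
#'   used for searching default to ATOM-derived ones.
#'
#' @seealso [readStructure()], [generateParallelSheet()], [chainIDs()],
#'   [getChain()], [deriveSequence()]
#' @export
setClass("ProteinStructure", representation(
  entryID = "character", methodClass = "character", models = "list",
  seqres = "list"
))

setValidity("ProteinStructure", function(object) {
  msg <- character()
  if (length(object@entryID) != 1L || is.na(object@entryID))
    msg <- c(msg, "entryID must be a single string")
  if (!(object@methodClass %in% c("NMR", "XRAY", "OTHER")))
    msg <- c(msg, "methodClass must be NMR, XRAY or OTHER")
  for (m in seq_along(object@models)) {
    mod <- object@models[[m]]
    if (!is.list(mod)) { msg <- c(msg, "each model must be a list of chains"); next }
    if (length(mod)) {
      ids <- names(mod)
      if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
        msg <- c(msg, sprintf("model %d: chain ids must be unique and non-empty", m))
      for (ch in mod) {
        if (!is.data.frame(ch) || !all(.chainColumns %in% names(ch))) {
          msg <- c(msg, sprintf("model %d: malformed chain table", m)); break
        }
        xyz <- as.matrix(ch[, c("x", "y", "z")])
        if (any(!is.finite(xyz) & !is.na(xyz)))
          msg <- c(msg, sprintf("model %d: non-finite coordinates", m))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' @param entryID,methodClass,models,seqres see slot documentation.
#' @return a validated \code{ProteinStructure}.
#' @rdname ProteinStructure-class
#' @export
ProteinStructure <- function(entryID, methodClass = "OTHER", models = list(),
                             seqres = list()) {
  new("ProteinStructure", entryID = as.character(entryID),
      methodClass = methodClass, models = models, seqres = seqres)
}

setMethod("show", "ProteinStructure", function(object) {
  nm <- length(object@models)
  cat(sprintf("ProteinStructure \"%s\" [%s], %d model%s\n",
              object@entryID, object@methodClass, nm, if (nm == 1) "" else "s"))
  if (nm) {
    ids <- chainIDs(object)
    nres <- vapply(object@models[[1L]], nrow, integer(1))
    nca <- vapply(object@models[[1L]], function(ch) sum(!is.na(ch$x)), integer(1))
    cat(sprintf("  model 1: %d chain%s\n", length(ids), if (length(ids) == 1) "" else "s"))
    for (i in seq_along(ids))
      cat(sprintf("    chain %s: %d residues (%d with C-alpha)\n", ids[i], nres[i], nca[i]))
  }
  invisible(object)
})

#' Accessors for ProteinStructure objects
#'
#' \code{entryID} and \code{methodClass} return the identifier and
#' experimental-method class; \code{nModels} the number of coordinate models;
#' \code{chainIDs} the chain identifiers of one model; \code{getChain} one
#' chain's residue table; \code{resolvedLength} the number of residues with a
#' C-alpha position (the coverage-filter denominator).
#'
#' @param x a \code{ProteinStructure} (for \code{resolvedLength}, a chain
#'   data.frame).
#' @param model 1-based model index.
#' @param chain chain identifier.
#' @name structure-accessors
NULL

#' @rdname structure-accessors
#' @export
setGeneric("entryID", function(x) standardGeneric("entryID"))
#' @rdname structure-accessors
#' @export
setMethod("entryID", "ProteinStructure", function(x) x@entryID)

#' @rdname structure-accessors
#' @export
setGeneric("methodClass", function(x) standardGeneric("methodClass"))
#' @rdname structure-accessors
#' @export
setMethod("methodClass", "ProteinStructure", function(x) x@methodClass)

#' @rdname structure-accessors
#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))
#' @rdname structure-accessors
#' @export
setMethod("nModels", "ProteinStructure", function(x) length(x@models))

#' @rdname structure-accessors
#' @export
setGeneric("chainIDs", function(x, model = 1L) standardGeneric("chainIDs"))
#' @rdname structure-accessors
#' @export
setMethod("chainIDs", "ProteinStructure", function(x, model = 1L) {
  if (length(x@models) < model) return(character())
  names(x@models[[model]])
})

#' @rdname structure-accessors
#' @export
setGeneric("getChain", function(x, chain, model = 1L) standardGeneric("getChain"))
#' @rdname structure-accessors
#' @export
setMethod("getChain", "ProteinStructure", function(x, chain, model = 1L) {
  mod <- x@models[[model]]
  if (!chain %in% names(mod))
    stop("no chain '", chain, "' in model ", model, " of ", x@entryID)
  mod[[chain]]
})

#' @rdname structure-accessors
#' @export
resolvedLength <- function(x) {
  stopifnot(is.data.frame(x))
  sum(!is.na(x$x))
}
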