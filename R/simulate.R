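## Ground-truth generator: ideal in-register cross-beta sheets with a known
## planted strand (hence known boundary prefix/suffix), plus negative decoys
## that each violate exactly one detection constraint.

.GOLDEN <- 2.399963  # golden-angle chain phasing keeps neighbouring coils apart
.COIL_STEP <- 3.8    # Angstrom, a typical C-alpha virtual bond
.COIL_TURN <- 1.1    # radians of step-direction rotation per coil residue

#' Specification of a synthetic parallel sheet
#'
#' Describes an ideal cross-beta fibril fragment: \code{nChains} identical
#' copies of \code{sequence}, with residues
#' \code{segmentStart .. segmentStart+segmentLength-1} laid out as straight
#' extended strands stacked in register at \code{spacing} (default 4.8
#' Angstrom, the canonical cross-beta inter-strand separation), and the
#' remaining residues as an irregular off-axis coil that deliberately breaks
#' every strand criterion. Optional per-coordinate Gaussian noise and a
#' fibril twist are available; everything is deterministic for a fixed seed.
#'
#' @param sequence amino-acid string shared by all chains.
#' @param segmentStart 1-based index of the first strand residue. Values
#'   >= 3 leave room for the two-residue boundary flank; 1 and 2 are
#'   permitted to exercise the no-flank case.
#' @param segmentLength strand length, >= 3.
#' @param nChains number of chains, >= 2.
#' @param spacing inter-strand C-alpha distance, Angstrom.
#' @param rise C-alpha rise per residue along the strand axis, Angstrom
#'   (default 3.4, extended-strand geometry).
#' @param twistDeg fibril twist per residue, degrees (default 0).
#' @param noiseSD per-coordinate Gaussian noise, Angstrom (default 0).
#' @param seed integer RNG seed for the noise.
#' @param nModels number of models to emit (noise redrawn per model).
#' @param entryID label stored in the structure.
#' @param methodClass method class stored in the structure
#'   (default \code{"NMR"}).
#' @return a list of class \code{"sheetSpec"}.
#' @seealso [generateParallelSheet()], [sheetGroundTruth()]
#' @export
sheetSpec <- function(sequence, segmentStart, segmentLength, nChains = 2L,
                      spacing = 4.8, rise = 3.4, twistDeg = 0, noiseSD = 0,
                      seed = 1L, nModels = 1L, entryID = "SYNTH",
                      methodClass = "NMR") {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  stopifnot(n >= 3L, grepl("^[A-Z]+$", sequence))
  segmentStart <- as.integer(segmentStart)
  segmentLength <- as.integer(segmentLength)
  if (segmentStart < 1L) stop("segmentStart must be >= 1")
  if (segmentLength < 3L) stop("segmentLength must be >= 3")
  if (segmentStart + segmentLength - 1L > n)
    stop("segment exceeds the sequence length")
  if (nChains < 2L) stop("a parallel sheet needs at least 2 chains")
  if (nChains > 26L) stop("at most 26 chains (single-letter chain ids)")
  structure(list(sequence = sequence, segmentStart = segmentStart,
                 segmentLength = segmentLength, nChains = as.integer(nChains),
                 spacing = spacing, rise = rise, twistDeg = twistDeg,
                 noiseSD = noiseSD, seed = as.integer(seed),
                 nModels = as.integer(nModels), entryID = entryID,
                 methodClass = methodClass),
            class = "sheetSpec")
}

## one chain's ideal coordinates (no noise): strand along +x, coil off-axis
.chainCoords <- function(spec, chainIndex) {
  n <- nchar(spec$sequence)
  s0 <- spec$segmentStart; L <- spec$segmentLength
  sEnd <- s0 + L - 1L
  c0 <- chainIndex - 1L
  twist <- spec$twistDeg * pi / 180
  xyz <- matrix(NA_real_, n, 3L)
  for (i in s0:sEnd) {
    phi <- twist * (i - s0)
    xyz[i, ] <- c(i * spec$rise,
                  c0 * spec$spacing * sin(phi),
                  c0 * spec$spacing * cos(phi))
  }
  ## coil: fixed-length steps perpendicular-to-slightly-backward relative to
  ## the strand axis, with golden-angle phasing per chain, so neighbouring
  ## chains' coils diverge and any window reaching into the coil loses
  ## straightness decisively
  coilDir <- function(q, side) {
    psi <- .GOLDEN * c0 + .COIL_TURN * q + if (side == "post") 1.9 else 0
    v <- c(if (side == "pre") 0.35 else -0.35, cos(psi), sin(psi))
    v / sqrt(sum(v^2))
  }
  if (s0 > 1L) for (i in (s0 - 1L):1L) {
    q <- s0 - i
    xyz[i, ] <- xyz[i + 1L, ] + .COIL_STEP * coilDir(q, "pre")
  }
  if (sEnd < n) for (i in (sEnd + 1L):n) {
    q <- i - sEnd
    xyz[i, ] <- xyz[i - 1L, ] + .COIL_STEP * coilDir(q, "post")
  }
  xyz
}

## Per-chain coordinate noise, smoothed along the chain (3-residue moving
## average, rescaled so the marginal per-coordinate sd equals `sd`): real
## ensemble disorder is spatially correlated, and uncorrelated per-residue
## noise would occasionally stretch a virtual C-alpha bond past the
## chain-break threshold, which no physical fluctuation of this size does.
.smoothNoise <- function(n, sd) {
  e <- matrix(stats::rnorm(3L * (n + 2L), sd = sd), n + 2L, 3L)
  (e[1:n, ] + e[2:(n + 1L), ] + e[3:(n + 2L), ]) / sqrt(3)
}

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Generate an ideal parallel cross-beta sheet
#'
#' Builds the [ProteinStructure-class] described by a [sheetSpec()]: the
#' planted strand region of every chain is an ideal extended strand, chains
#' are stacked in register at the requested spacing (so the inter-strand
#' distance profile is exactly constant at zero noise), and the flanking
#' residues form an irregular coil that no detection constraint accepts.
#' Deterministic for a fixed seed.
#'
#' @param spec a [sheetSpec()].
#' @return a [ProteinStructure-class] with \code{spec$nModels} models.
#' @examples
#' sheet <- generateParallelSheet(sheetSpec("GAQKLVFFAEDGA", 4, 7))
#' findParallelPairs(sheet)
#' @export
generateParallelSheet <- function(spec) {
  stopifnot(inherits(spec, "sheetSpec"))
  n <- nchar(spec$sequence)
  aa <- strsplit(spec$sequence, "")[[1L]]
  resid <- unname(.AA123[aa])
  resid[is.na(resid)] <- "UNK"
  ideal <- lapply(seq_len(spec$nChains), function(ci) .chainCoords(spec, ci))
  .withSeed(spec$seed, {
    models <- vector("list", spec$nModels)
    for (m in seq_len(spec$nModels)) {
      model <- list()
      for (ci in seq_len(spec$nChains)) {
        xyz <- ideal[[ci]]
        if (spec$noiseSD > 0)
          xyz <- xyz + .smoothNoise(n, spec$noiseSD)
        model[[LETTERS[ci]]] <- data.frame(
          resno = seq_len(n), ins = "", resid = resid, aa = aa,
          x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
          stringsAsFactors = FALSE)
      }
      models[[m]] <- model
    }
    ProteinStructure(spec$entryID, spec$methodClass, models = models)
  })
}

#' Ground truth of a synthetic sheet
#'
#' The planted segment range and the boundary k-mers a correct pipeline must
#' recover from a [generateParallelSheet()] structure.
#'
#' @param spec a [sheetSpec()].
#' @return list with \code{segmentStart}, \code{segmentEnd},
#'   \code{segmentLength}, \code{nChains}, and \code{prefix} / \code{suffix}
#'   (NA when the flank does not exist or contains a non-standard letter).
#' @export
sheetGroundTruth <- function(spec) {
  stopifnot(inherits(spec, "sheetSpec"))
  n <- nchar(spec$sequence)
  s0 <- spec$segmentStart; sEnd <- s0 + spec$segmentLength - 1L
  pick <- function(from, to) {
    if (from < 1L || to > n) return(NA_character_)
    km <- substr(spec$sequence, from, to)
    if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", km)) NA_character_ else km
  }
  list(segmentStart = s0, segmentEnd = sEnd,
       segmentLength = spec$segmentLength, nChains = spec$nChains,
       prefix = pick(s0 - 2L, s0 + 2L),
       suffix = pick(sEnd - 2L, sEnd + 2L))
}

#' Write the ground-truth sidecar of a synthetic sheet
#'
#' JSON companion to a written synthetic structure, recording the planted
#' segment range and expected boundary k-mers.
#'
#' @param spec a [sheetSpec()].
#' @param path output JSON path.
#' @export
writeGroundTruth <- function(spec, path) {
  jsonlite::write_json(sheetGroundTruth(spec), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

.DECOY_SEQ <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

.decoySeq <- function(n) paste(rep_len(.DECOY_SEQ, n), collapse = "")

.decoyChain <- function(xyz, sequence) {
  n <- nrow(xyz)
  aa <- strsplit(sequence, "")[[1L]]
  data.frame(resno = seq_len(n), ins = "", resid = unname(.AA123[aa]),
             aa = aa, x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
             stringsAsFactors = FALSE)
}

#' Generate a negative-control structure
#'
#' Each decoy violates exactly one constraint of the parallel-sheet filter
#' and must yield an empty [findParallelPairs()] result:
#' \describe{
#'   \item{helix}{a single-chain ideal alpha helix (rise 1.5 A/residue,
#'     radius 2.3 A, 100 degrees/residue) -- fails the separate-chain rule
#'     (and is far from straight).}
#'   \item{hairpin}{one chain folding back on itself with its two arms at
#'     strand spacing -- the classic case the separate-chain rule excludes.}
#'   \item{far_pair}{two straight parallel strands at 20 A -- outside the
#'     distance band.}
#'   \item{curved_pair}{two long concentric arcs at constant 4.8 A radial
#'     separation; every window long enough to satisfy coverage is too
#'     curved for the straightness threshold.}
#'   \item{antiparallel_pair}{two straight strands side by side with the
#'     second chain running C- to N-terminal -- opposite direction
#'     vectors.}
#' }
#'
#' @param kind decoy class, see above.
#' @param seed RNG seed for the optional noise.
#' @param noiseSD per-coordinate Gaussian noise, Angstrom.
#' @return a [ProteinStructure-class] (single model).
#' @seealso [rejectionReason()] reports the violated constraint.
#' @export
generateDecoy <- function(kind = c("helix", "hairpin", "far_pair",
                                   "curved_pair", "antiparallel_pair"),
                          seed = 1L, noiseSD = 0) {
  kind <- match.arg(kind)
  chains <- switch(kind,
    helix = {
      n <- 30L; i <- seq_len(n)
      ang <- (i - 1L) * 100 * pi / 180
      list(A = cbind(1.5 * (i - 1L), 2.3 * cos(ang), 2.3 * sin(ang)))
    },
    hairpin = {
      arm <- 8L
      out <- cbind(3.4 * (seq_len(arm) - 1L), 0, 0)
      turnX <- 3.4 * (arm - 1L)
      turn <- rbind(c(turnX + 2.4, 0, 1.6), c(turnX + 2.4, 0, 3.2))
      back <- cbind(3.4 * ((arm:1) - 1L), 0, 4.8)
      list(A = rbind(out, turn, back))
    },
    far_pair = {
      n <- 10L
      a <- cbind(3.4 * (seq_len(n) - 1L), 0, 0)
      list(A = a, B = sweep(a, 2L, c(0, 0, 20), "+"))
    },
    curved_pair = {
      n <- 61L
      theta <- (seq_len(n) - 1L) * 0.25
      list(A = cbind(12.2 * cos(theta), 12.2 * sin(theta), 0),
           B = cbind(17.0 * cos(theta), 17.0 * sin(theta), 0))
    },
    antiparallel_pair = {
      n <- 10L
      a <- cbind(3.4 * (seq_len(n) - 1L), 0, 0)
      b <- cbind(3.4 * (n - seq_len(n)), 0, 4.8)
      list(A = a, B = b)
    })
  .withSeed(seed, {
    model <- lapply(chains, function(xyz) {
      if (noiseSD > 0)
        xyz <- xyz + .smoothNoise(nrow(xyz), noiseSD)
      .decoyChain(xyz, .decoySeq(nrow(xyz)))
    })
    ProteinStructure(paste0("DECOY", toupper(gsub("_", "", kind))), "NMR",
                     models = list(model))
  })
}
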