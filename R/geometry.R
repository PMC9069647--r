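#' Per-position C-alpha distance profile of two residue runs
#'
#' Element \code{k} is the Euclidean distance between the k-th C-alpha of
#' each run (index-registered pairing, the cross-beta in-register geometry).
#'
#' @param segA,segB numeric matrices with 3 columns (x, y, z) and the same
#'   number of rows.
#' @return numeric vector of distances in Angstrom.
#' @examples
#' a <- cbind(seq(0, 20.4, by = 3.4), 0, 0)
#' distanceProfile(a, sweep(a, 2, c(4.8, 0, 0), "+"))
#' @export
distanceProfile <- function(segA, segB) {
  segA <- .asXYZ(segA); segB <- .asXYZ(segB)
  if (nrow(segA) != nrow(segB))
    stop("runs must have equal length (", nrow(segA), " vs ", nrow(segB), ")")
  if (nrow(segA) < 1L) stop("runs must contain at least one position")
  sqrt(rowSums((segA - segB)^2))
}

.asXYZ <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) != 3L) stop("coordinate run must have 3 columns")
  storage.mode(m) <- "double"
  m
}

#' Straightness of a C-alpha run
#'
#' End-to-end Euclidean distance divided by the contour length (sum of
#' consecutive C-alpha distances). Equals 1 for collinear equally spaced
#' points and decreases with curvature; helical and strongly bent runs fall
#' below the default 0.9 acceptance threshold. This ratio is the package's
#' operational form of the curvature exclusion.
#'
#' @param seg numeric matrix with 3 columns and at least 2 rows.
#' @return a value in [0, 1].
#' @examples
#' straightness(cbind(seq(0, 17, by = 3.4), 0, 0))  # collinear: 1
#' @export
straightness <- function(seg) {
  seg <- .asXYZ(seg)
  n <- nrow(seg)
  if (n < 2L) stop("straightness needs a run of length >= 2")
  steps <- sqrt(rowSums((seg[-1L, , drop = FALSE] - seg[-n, , drop = FALSE])^2))
  contour <- sum(steps)
  if (contour == 0) return(0)
  sqrt(sum((seg[n, ] - seg[1L, ])^2)) / contour
}

#' Chain-coverage criterion for a detected segment
#'
#' A segment pair of length L covers its parent chain when L over the
#' resolved (C-alpha bearing) chain length reaches \code{coverageMin}
#' (default 1/7). The criterion passes when at least one parent chain is
#' covered; with \code{coverageBoth} in the parameters, both must be.
#'
#' @param segLength segment length in residues.
#' @param resolvedA,resolvedB resolved lengths of the two parent chains.
#' @param params a [GeometryParams-class].
#' @return logical.
#' @examples
#' coverageFilter(2, 14, 14)    # 2/14 == 1/7: inclusive boundary, TRUE
#' coverageFilter(10, 80, 80)   # 0.125 < 1/7: FALSE
#' @export
coverageFilter <- function(segLength, resolvedA, resolvedB,
                           params = GeometryParams()) {
  ca <- segLength / resolvedA >= params@coverageMin
  cb <- segLength / resolvedB >= params@coverageMin
  if (params@coverageBoth) ca && cb else ca || cb
}

## Per-chain geometry cache: coordinates, eligibility (has CA), and a break
## flag between consecutive residues (author-number gap or long CA-CA step).
.chainGeom <- function(chain, params) {
  n <- nrow(chain)
  xyz <- as.matrix(chain[, c("x", "y", "z")])
  storage.mode(xyz) <- "double"
  eligible <- !is.na(xyz[, 1L])
  breakAfter <- logical(max(n - 1L, 0L))
  if (n > 1L) {
    gap <- diff(chain$resno)
    breakAfter <- gap > 1L | gap < 0L
    step <- sqrt(rowSums((xyz[-1L, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
    long <- !is.na(step) & step > params@maxGapDistance
    breakAfter <- breakAfter | long
  }
  list(xyz = xyz, eligible = eligible, breakAfter = breakAfter,
       resolved = sum(eligible), n = n)
}

## contiguous index stretches along one registration diagonal
.diagonalStretches <- function(gA, gB, offset, minLen) {
  kLo <- max(1L, 1L - offset)
  kHi <- min(gA$n, gB$n - offset)
  if (kHi - kLo + 1L < minLen) return(list())
  ks <- kLo:kHi
  ok <- gA$eligible[ks] & gB$eligible[ks + offset]
  if (!any(ok)) return(list())
  ## connected to the next position unless a break intervenes on either chain
  conn <- ok[-length(ok)] & ok[-1L] &
    !gA$breakAfter[ks[-length(ks)]] & !gB$breakAfter[ks[-length(ks)] + offset]
  grp <- cumsum(c(TRUE, !conn))
  sp <- split(ks, grp)
  Filter(function(v) length(v) >= minLen &&
           all(gA$eligible[v] & gB$eligible[v + offset]), sp)
}

## All windows of one stretch: validity matrix V[s, L] and summary stats.
.stretchWindows <- function(gA, gB, ks, offset, params) {
  n <- length(ks)
  A <- gA$xyz[ks, , drop = FALSE]
  B <- gB$xyz[ks + offset, , drop = FALSE]
  d <- sqrt(rowSums((A - B)^2))
  bad0 <- c(0, cumsum(d < params@dMin | d > params@dMax))
  ## centring the profile before the prefix sums avoids the catastrophic
  ## cancellation of the one-pass variance on near-constant profiles
  dc <- d - mean(d)
  S1 <- c(0, cumsum(dc)); S2 <- c(0, cumsum(dc^2))
  S1raw <- c(0, cumsum(d))
  stepA <- c(0, cumsum(sqrt(rowSums((A[-1L, , drop = FALSE] - A[-n, , drop = FALSE])^2))))
  stepB <- c(0, cumsum(sqrt(rowSums((B[-1L, , drop = FALSE] - B[-n, , drop = FALSE])^2))))
  minL <- params@minSegmentLength
  V <- matrix(FALSE, n, n)  # V[s, L]
  stats <- list()
  for (L in minL:n) {
    s <- seq_len(n - L + 1L); e <- s + L - 1L
    okd <- (bad0[e + 1L] - bad0[s]) == 0
    muc <- (S1[e + 1L] - S1[s]) / L
    mu <- (S1raw[e + 1L] - S1raw[s]) / L
    va <- pmax((S2[e + 1L] - S2[s]) / L - muc^2, 0)
    sdv <- sqrt(va)
    vA <- A[e, , drop = FALSE] - A[s, , drop = FALSE]
    vB <- B[e, , drop = FALSE] - B[s, , drop = FALSE]
    e2eA <- sqrt(rowSums(vA^2)); e2eB <- sqrt(rowSums(vB^2))
    ctA <- stepA[e] - stepA[s]; ctB <- stepB[e] - stepB[s]
    strA <- ifelse(ctA > 0, e2eA / ctA, 0)
    strB <- ifelse(ctB > 0, e2eB / ctB, 0)
    dn <- e2eA * e2eB
    dot <- ifelse(dn > 0, rowSums(vA * vB) / dn, -1)
    covA <- L / gA$resolved; covB <- L / gB$resolved
    covOK <- if (params@coverageBoth) covA >= params@coverageMin & covB >= params@coverageMin
             else covA >= params@coverageMin | covB >= params@coverageMin
    val <- okd & sdv < params@sigmaMax &
      strA >= params@straightnessMin & strB >= params@straightnessMin &
      dot >= params@parallelDotMin & covOK
    V[cbind(s, L)] <- val
    stats[[L]] <- list(mu = mu, sdv = sdv, strA = strA, strB = strB,
                       covA = covA, covB = covB, d = d)
  }
  list(V = V, stats = stats, n = n, ks = ks, d = d)
}

#' Detect parallel beta-sheet segment pairs
#'
#' Enumerates all maximal index-registered residue-run pairs on distinct
#' chains of one model that satisfy the geometric amyloid filter (see
#' [GeometryParams-class]): per-position C-alpha distances within the band,
#' low distance variance, both runs straight, same direction, and chain
#' coverage. A pair is maximal when it cannot be extended by one residue at
#' either end without violating a constraint. Runs never span a chain break
#' (author-number gap or consecutive C-alpha step above
#' \code{maxGapDistance}).
#'
#' @param x a [ProteinStructure-class].
#' @param params a [GeometryParams-class].
#' @param model 1-based model index.
#' @return a data.frame with one row per maximal pair, sorted by
#'   \code{(chain_a, start_a, chain_b, start_b)}: chain ids, 1-based start
#'   indices into the chains' residue tables, author residue-number ranges,
#'   length, mean and standard deviation of the distance profile,
#'   straightness and coverage of both runs, and the distance profile itself
#'   as a list column. Zero rows when nothing passes.
#' @examples
#' sheet <- generateParallelSheet(sheetSpec("GAQKLVFFAEDGA", 4, 7))
#' findParallelPairs(sheet)[, c("chain_a", "chain_b", "start_a", "length")]
#' @export
findParallelPairs <- function(x, params = GeometryParams(), model = 1L) {
  stopifnot(is(x, "ProteinStructure"), is(params, "GeometryParams"))
  validObject(params)
  empty <- data.frame(entry = character(), model = integer(),
                      chain_a = character(), start_a = integer(),
                      end_a = integer(), chain_b = character(),
                      start_b = integer(), end_b = integer(),
                      length = integer(), mean_distance = numeric(),
                      distance_sd = numeric(), straightness_a = numeric(),
                      straightness_b = numeric(), coverage_a = numeric(),
                      coverage_b = numeric(), resno_a_start = integer(),
                      resno_a_end = integer(), resno_b_start = integer(),
                      resno_b_end = integer(), stringsAsFactors = FALSE)
  empty$distances <- list()
  if (nModels(x) < model) return(empty)
  chains <- x@models[[model]]
  if (length(chains) < 2L) return(empty)
  ids <- names(chains)
  geoms <- lapply(chains, .chainGeom, params = params)
  offsets <- seq.int(-params@offsetScan, params@offsetScan)
  rows <- list()
  for (a in seq_len(length(chains) - 1L)) for (b in (a + 1L):length(chains)) {
    gA <- geoms[[a]]; gB <- geoms[[b]]
    if (gA$resolved == 0L || gB$resolved == 0L) next
    for (f in offsets) {
      for (ks in .diagonalStretches(gA, gB, f, params@minSegmentLength)) {
        sw <- .stretchWindows(gA, gB, ks, f, params)
        n <- sw$n; V <- sw$V
        for (L in params@minSegmentLength:n) {
          for (s in which(V[, L])) {
            extLeft <- s > 1L && L < n && V[s - 1L, L + 1L]
            extRight <- L < n && s + L <= n && V[s, L + 1L]
            if (extLeft || extRight) next
            st <- sw$stats[[L]]
            kA <- ks[s]; kB <- ks[s] + f
            chA <- chains[[a]]; chB <- chains[[b]]
            ## exact two-pass moments for the reported window
            dwin <- sw$d[s:(s + L - 1L)]
            row <- data.frame(
              entry = x@entryID, model = as.integer(model),
              chain_a = ids[a], start_a = kA, end_a = kA + L - 1L,
              chain_b = ids[b], start_b = kB, end_b = kB + L - 1L,
              length = as.integer(L),
              mean_distance = mean(dwin),
              distance_sd = sqrt(mean((dwin - mean(dwin))^2)),
              straightness_a = st$strA[s], straightness_b = st$strB[s],
              coverage_a = st$covA, coverage_b = st$covB,
              resno_a_start = chA$resno[kA], resno_a_end = chA$resno[kA + L - 1L],
              resno_b_start = chB$resno[kB], resno_b_end = chB$resno[kB + L - 1L],
              stringsAsFactors = FALSE)
            row$distances <- list(sw$d[s:(s + L - 1L)])
            rows[[length(rows) + 1L]] <- row
          }
        }
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$chain_a, out$start_a, out$chain_b, out$start_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Why a structure yields no parallel segment pair
#'
#' Diagnostic companion to [findParallelPairs()] for negative controls: when
#' no pair passes, reports the first violated constraint of the best
#' candidate (the longest index-registered common stretch over all
#' distinct-chain pairs). Constraints are examined in the fixed order
#' direction, distance band, distance variance, straightness, coverage --
#' direction first, because with in-register pairing an anti-parallel
#' arrangement violates the distance constraints as a side effect of its
#' reversed direction, and the orientation is the informative diagnosis.
#'
#' @inheritParams findParallelPairs
#' @return one of \code{"none"} (pairs were found), \code{"separate_chains"}
#'   (fewer than two chains with a long-enough common stretch),
#'   \code{"direction"}, \code{"distance_band"}, \code{"distance_sd"},
#'   \code{"straightness"}, \code{"coverage"}.
#' @export
rejectionReason <- function(x, params = GeometryParams(), model = 1L) {
  if (nrow(findParallelPairs(x, params, model))) return("none")
  if (nModels(x) < model) return("separate_chains")
  chains <- x@models[[model]]
  if (length(chains) < 2L) return("separate_chains")
  geoms <- lapply(chains, .chainGeom, params = params)
  offsets <- seq.int(-params@offsetScan, params@offsetScan)
  best <- NULL; bestLen <- 0L
  for (a in seq_len(length(chains) - 1L)) for (b in (a + 1L):length(chains)) {
    for (f in offsets) {
      for (ks in .diagonalStretches(geoms[[a]], geoms[[b]], f,
                                    params@minSegmentLength)) {
        if (length(ks) > bestLen) {
          bestLen <- length(ks)
          best <- list(gA = geoms[[a]], gB = geoms[[b]], ks = ks, f = f)
        }
      }
    }
  }
  if (is.null(best)) return("separate_chains")
  A <- best$gA$xyz[best$ks, , drop = FALSE]
  B <- best$gB$xyz[best$ks + best$f, , drop = FALSE]
  n <- nrow(A)
  vA <- A[n, ] - A[1L, ]; vB <- B[n, ] - B[1L, ]
  dn <- sqrt(sum(vA^2)) * sqrt(sum(vB^2))
  dot <- if (dn > 0) sum(vA * vB) / dn else -1
  if (dot < params@parallelDotMin) return("direction")
  d <- distanceProfile(A, B)
  if (any(d < params@dMin | d > params@dMax)) return("distance_band")
  if (sqrt(mean(d^2) - mean(d)^2) >= params@sigmaMax) return("distance_sd")
  if (straightness(A) < params@straightnessMin ||
      straightness(B) < params@straightnessMin) return("straightness")
  "coverage"
}
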