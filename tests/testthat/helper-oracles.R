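## Independent oracles and fixture builders. Everything here is deliberately
## naive (plain loops, direct formulas) so it cannot share a defect with the
## package implementation.

## a bare chain table from a coordinate matrix
makeChain <- function(xyz, resno = seq_len(nrow(xyz)), aa = NULL) {
  n <- nrow(xyz)
  if (is.null(aa)) aa <- rep_len(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n)
  resid <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
             H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
             P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
             W = "TRP", Y = "TYR")[aa]
  resid[is.na(resid)] <- "UNK"
  data.frame(resno = as.integer(resno), ins = "", resid = unname(resid),
             aa = aa, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

makeStructure <- function(chains, entryID = "TEST", methodClass = "NMR") {
  ProteinStructure(entryID, methodClass, models = list(chains))
}

## ---- brute-force parallel-pair enumeration ------------------------------
## Direct restatement of the detection contract: loop over every distinct
## chain pair, every registration offset, every (startA, length) window;
## check each constraint with naive arithmetic; keep windows whose one-step
## extensions are invalid.

bfWindowValid <- function(chA, chB, sA, sB, L, params) {
  nA <- nrow(chA); nB <- nrow(chB)
  if (sA < 1 || sB < 1 || sA + L - 1 > nA || sB + L - 1 > nB) return(FALSE)
  ia <- sA:(sA + L - 1); ib <- sB:(sB + L - 1)
  A <- as.matrix(chA[ia, c("x", "y", "z")])
  B <- as.matrix(chB[ib, c("x", "y", "z")])
  if (any(is.na(A)) || any(is.na(B))) return(FALSE)
  ## no chain break inside either window
  brk <- function(ch, idx) {
    for (j in seq_len(length(idx) - 1)) {
      if (ch$resno[idx[j + 1]] - ch$resno[idx[j]] > 1) return(TRUE)
      if (ch$resno[idx[j + 1]] - ch$resno[idx[j]] < 0) return(TRUE)
      p <- as.numeric(ch[idx[j], c("x", "y", "z")])
      q <- as.numeric(ch[idx[j + 1], c("x", "y", "z")])
      if (anyNA(p) || anyNA(q)) return(TRUE)
      if (sqrt(sum((q - p)^2)) > params@maxGapDistance) return(TRUE)
    }
    FALSE
  }
  if (L > 1 && (brk(chA, ia) || brk(chB, ib))) return(FALSE)
  d <- numeric(L)
  for (k in 1:L) d[k] <- sqrt(sum((A[k, ] - B[k, ])^2))
  if (any(d < params@dMin) || any(d > params@dMax)) return(FALSE)
  if (sqrt(sum((d - mean(d))^2) / L) >= params@sigmaMax) return(FALSE)
  str1 <- function(M) {
    ct <- 0
    for (k in seq_len(nrow(M) - 1)) ct <- ct + sqrt(sum((M[k + 1, ] - M[k, ])^2))
    if (ct == 0) return(0)
    sqrt(sum((M[nrow(M), ] - M[1, ])^2)) / ct
  }
  if (str1(A) < params@straightnessMin || str1(B) < params@straightnessMin)
    return(FALSE)
  vA <- A[L, ] - A[1, ]; vB <- B[L, ] - B[1, ]
  den <- sqrt(sum(vA^2)) * sqrt(sum(vB^2))
  dt <- if (den > 0) sum(vA * vB) / den else -1
  if (dt < params@parallelDotMin) return(FALSE)
  covA <- L / sum(!is.na(chA$x)); covB <- L / sum(!is.na(chB$x))
  if (params@coverageBoth) covA >= params@coverageMin && covB >= params@coverageMin
  else covA >= params@coverageMin || covB >= params@coverageMin
}

bfPairs <- function(structure, params = GeometryParams(), model = 1) {
  chains <- structure@models[[model]]
  ids <- names(chains)
  out <- NULL
  if (length(chains) >= 2)
    for (a in 1:(length(chains) - 1)) for (b in (a + 1):length(chains)) {
      chA <- chains[[a]]; chB <- chains[[b]]
      for (f in seq.int(-params@offsetScan, params@offsetScan)) {
        for (sA in seq_len(nrow(chA))) {
          sB <- sA + f
          for (L in params@minSegmentLength:nrow(chA)) {
            if (!bfWindowValid(chA, chB, sA, sB, L, params)) next
            if (bfWindowValid(chA, chB, sA - 1, sB - 1, L + 1, params)) next
            if (bfWindowValid(chA, chB, sA, sB, L + 1, params)) next
            out <- rbind(out, data.frame(
              chain_a = ids[a], start_a = sA, chain_b = ids[b], start_b = sB,
              length = L, stringsAsFactors = FALSE))
          }
        }
      }
    }
  if (is.null(out))
    return(data.frame(chain_a = character(), start_a = integer(),
                      chain_b = character(), start_b = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  out <- out[order(out$chain_a, out$start_a, out$chain_b, out$start_b), ]
  rownames(out) <- NULL
  out
}

## ---- naive exact-substring scan -----------------------------------------
naiveScan <- function(kmer, sequence) {
  hits <- integer()
  w <- nchar(kmer)
  if (nchar(sequence) >= w)
    for (i in 1:(nchar(sequence) - w + 1))
      if (substr(sequence, i, i + w - 1) == kmer) hits <- c(hits, i)
  hits
}

## ---- random small structures for oracle-equivalence sweeps ---------------
## Mix of geometries so that accepted pairs, near-misses and rejections all
## occur: random walks, noisy in-register strand pairs, and hybrids.
randomSmallStructure <- function(seed) {
  set.seed(seed)
  n <- sample(4:15, 1)
  kind <- sample(c("walk", "sheet", "mixed"), 1)
  mk <- function() {
    if (kind == "walk") {
      steps <- matrix(rnorm(3 * (n - 1)), ncol = 3)
      steps <- steps / sqrt(rowSums(steps^2)) * runif(n - 1, 3.0, 4.2)
      apply(rbind(rnorm(3, sd = 4), steps), 2, cumsum)
    } else {
      base <- cbind(3.4 * (seq_len(n) - 1), 0, 0)
      base + matrix(rnorm(3 * n, sd = runif(1, 0.1, 1.2)), ncol = 3)
    }
  }
  a <- mk()
  b <- if (kind == "mixed") {
    steps <- matrix(rnorm(3 * (n - 1)), ncol = 3)
    steps <- steps / sqrt(rowSums(steps^2)) * runif(n - 1, 3.0, 4.2)
    apply(rbind(rnorm(3, sd = 4), steps), 2, cumsum)
  } else {
    sweep(mk(), 2, c(0, runif(1, -2, 2), runif(1, 3.5, 17)), "+")
  }
  makeStructure(list(A = makeChain(a), B = makeChain(b)))
}
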