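## Boundary k-mers: the XXYYY construction. A prefix is the two residues
## immediately N-terminal to a detected parallel segment followed by the
## segment's first three residues; a suffix is the mirror at the C-terminal
## boundary (last three segment residues plus the two following).

.kmerOK <- function(letters) all(letters %in% .AA1)

#' Extract one boundary k-mer of a detected segment
#'
#' Builds the length-5 boundary string of a segment on one chain. For
#' \code{side = "prefix"}: residues at \code{start-2, start-1} (the XX
#' flank, not part of the sheet) followed by the segment's first three
#' residues (YYY). For \code{side = "suffix"}: the segment's last three
#' residues followed by the two residues after the segment end. Returns
#' \code{NULL} when fewer than two flank residues exist, when an
#' author-numbering break intervenes anywhere in the five positions, or when
#' any of the five letters is not one of the 20 standard residues.
#'
#' @param chain a chain data.frame (see [ProteinStructure-class]).
#' @param start 1-based index of the segment start in the chain's residue
#'   table.
#' @param length segment length in residues (>= 3).
#' @param side \code{"prefix"} or \code{"suffix"}.
#' @return \code{NULL}, or a one-row data.frame with the k-mer, the side,
#'   and the author residue numbers of the two flank and three core
#'   positions.
#' @examples
#' ch <- data.frame(resno = 13:22, ins = "",
#'                  resid = c("HIS","HIS","GLN","LYS","LEU","VAL","PHE","PHE","ALA","GLU"),
#'                  aa = c("H","H","Q","K","L","V","F","F","A","E"),
#'                  x = 0, y = 0, z = 0)
#' extractBoundaryKmer(ch, start = 5, length = 5, side = "prefix")  # QKLVF
#' @export
extractBoundaryKmer <- function(chain, start, length, side = c("prefix", "suffix")) {
  side <- match.arg(side)
  stopifnot(is.data.frame(chain), length >= 3L)
  n <- nrow(chain)
  idx <- if (side == "prefix") (start - 2L):(start + 2L)
         else (start + length - 3L):(start + length + 1L)
  if (idx[1L] < 1L || idx[5L] > n) return(NULL)
  gaps <- diff(chain$resno[idx])
  if (any(gaps > 1L | gaps < 0L)) return(NULL)
  letters <- chain$aa[idx]
  if (!.kmerOK(letters)) return(NULL)
  data.frame(kmer = paste(letters, collapse = ""), side = side,
             flank1 = chain$resno[idx[if (side == "prefix") 1L else 4L]],
             flank2 = chain$resno[idx[if (side == "prefix") 2L else 5L]],
             core1 = chain$resno[idx[if (side == "prefix") 3L else 1L]],
             core2 = chain$resno[idx[if (side == "prefix") 4L else 2L]],
             core3 = chain$resno[idx[if (side == "prefix") 5L else 3L]],
             stringsAsFactors = FALSE)
}

#' Boundary k-mers of all detected segment pairs of a structure
#'
#' Applies [extractBoundaryKmer()] to both chains of every detected pair,
#' for the requested sides, carrying full provenance (entry, model, chain,
#' positions, source segment, method class). Occurrences are kept with
#' multiplicity: the same 5-mer arising on both chains of one pair, in
#' several pairs, or in several models yields one record each.
#'
#' @param x the [ProteinStructure-class] the pairs were detected in.
#' @param pairs result of [findParallelPairs()] on \code{x} (any subset of
#'   its rows).
#' @param sides character vector among \code{"prefix"}, \code{"suffix"}.
#' @return data.frame with columns \code{kmer, side, entry, model, chain,
#'   which_chain, flank1, flank2, core1, core2, core3, segment,
#'   method_class}; zero rows when nothing is extractable.
#' @seealso [tallyKmers()]
#' @export
boundaryKmers <- function(x, pairs, sides = c("prefix", "suffix")) {
  stopifnot(is(x, "ProteinStructure"), is.data.frame(pairs))
  sides <- match.arg(sides, several.ok = TRUE)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    segid <- sprintf("%s:m%d:%s%d-%s%d:L%d", p$entry, p$model, p$chain_a,
                     p$start_a, p$chain_b, p$start_b, p$length)
    for (wc in c("a", "b")) {
      cid <- p[[paste0("chain_", wc)]]
      chain <- x@models[[p$model]][[cid]]
      st <- p[[paste0("start_", wc)]]
      for (sd in sides) {
        km <- extractBoundaryKmer(chain, st, p$length, sd)
        if (is.null(km)) next
        km$entry <- p$entry; km$model <- p$model; km$chain <- cid
        km$which_chain <- wc; km$segment <- segid
        km$method_class <- x@methodClass
        rows[[length(rows) + 1L]] <- km
      }
    }
  }
  if (!length(rows))
    return(data.frame(kmer = character(), side = character(),
                      flank1 = integer(), flank2 = integer(),
                      core1 = integer(), core2 = integer(), core3 = integer(),
                      entry = character(), model = integer(),
                      chain = character(), which_chain = character(),
                      segment = character(), method_class = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tally boundary k-mers with raw multiplicities
#'
#' Groups k-mer records by (k-mer, side, method class) and counts raw,
#' uncorrected occurrences -- repeated appearances within one entry, chain,
#' or model each count once, and no homology correction is applied. The
#' contributing entries are listed alongside.
#'
#' @param kmers data.frame from [boundaryKmers()] (possibly concatenated
#'   over many structures).
#' @return data.frame with columns \code{kmer, side, method_class, count,
#'   n_entries, entries} (comma-separated sorted unique entry ids), sorted
#'   by decreasing count then k-mer.
#' @seealso [topKmers()]
#' @export
tallyKmers <- function(kmers) {
  stopifnot(is.data.frame(kmers))
  empty <- data.frame(kmer = character(), side = character(),
                      method_class = character(), count = integer(),
                      n_entries = integer(), entries = character(),
                      stringsAsFactors = FALSE)
  if (nrow(kmers) == 0L) return(empty)
  key <- paste(kmers$kmer, kmers$side, kmers$method_class, sep = "\r")
  sp <- split(seq_len(nrow(kmers)), key)
  out <- do.call(rbind, lapply(sp, function(ii) {
    ent <- sort(unique(kmers$entry[ii]))
    data.frame(kmer = kmers$kmer[ii[1L]], side = kmers$side[ii[1L]],
               method_class = kmers$method_class[ii[1L]],
               count = length(ii), n_entries = length(ent),
               entries = paste(ent, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$count, out$kmer, out$side, out$method_class), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Most frequent boundary k-mers
#'
#' Filters a tally table to one side and/or method class and returns the
#' first \code{k} rows by decreasing count, ties broken lexicographically by
#' k-mer. Asking for more rows than exist returns all of them.
#'
#' @param table result of [tallyKmers()].
#' @param side optional filter: \code{"prefix"} or \code{"suffix"}.
#' @param methodClass optional filter: \code{"NMR"}, \code{"XRAY"},
#'   \code{"OTHER"}.
#' @param k number of rows (>= 1).
#' @return the selected rows of \code{table}.
#' @export
topKmers <- function(table, side = NULL, methodClass = NULL, k = 4L) {
  stopifnot(is.data.frame(table), k >= 1L)
  if (!is.null(side)) table <- table[table$side == side, , drop = FALSE]
  if (!is.null(methodClass))
    table <- table[table$method_class == methodClass, , drop = FALSE]
  table <- table[order(-table$count, table$kmer), , drop = FALSE]
  out <- utils::head(table, k)
  rownames(out) <- NULL
  out
}
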