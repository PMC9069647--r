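## Exact k-mer search over protein sequence collections.

## Normalise the accepted collection shapes to data.frame(id, chain, sequence)
.asCollection <- function(collection) {
  if (is(collection, "AAStringSet") || is(collection, "XStringSet")) {
    nm <- names(collection)
    if (is.null(nm)) nm <- as.character(seq_along(collection))
    nm <- vapply(strsplit(nm, "\\s+"), `[`, character(1), 1L)
    m <- regmatches(nm, regexec("^(.+)_([^_]+)$", nm))
    id <- vapply(seq_along(nm), function(i)
      if (length(m[[i]])) m[[i]][2L] else nm[i], character(1))
    chain <- vapply(seq_along(nm), function(i)
      if (length(m[[i]])) m[[i]][3L] else "", character(1))
    return(data.frame(id = id, chain = chain,
                      sequence = as.character(collection),
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(collection)) {
    stopifnot(all(c("id", "sequence") %in% names(collection)))
    if (is.null(collection$chain)) collection$chain <- ""
    return(collection[, c("id", "chain", "sequence")])
  }
  if (is.character(collection)) {
    nm <- names(collection)
    if (is.null(nm)) nm <- as.character(seq_along(collection))
    return(data.frame(id = nm, chain = "", sequence = unname(collection),
                      stringsAsFactors = FALSE))
  }
  stop("unsupported collection type: ", class(collection)[1L])
}

#' Read a protein sequence collection from FASTA
#'
#' Reads a multi-record FASTA file; headers shaped like PDB per-chain
#' identifiers (\code{id_chain}, as in \code{pdb_seqres.txt}) are split into
#' entry and chain, anything else becomes the record id with a blank chain.
#'
#' @param path FASTA file.
#' @return data.frame with columns \code{id, chain, sequence}.
#' @export
readSequenceCollection <- function(path) {
  .asCollection(Biostrings::readAAStringSet(path))
}

#' Find exact occurrences of a k-mer in a sequence collection
#'
#' Reports every exact, possibly overlapping occurrence of \code{kmer} in
#' every sequence of the collection. Matching is literal after uppercasing;
#' \code{X} positions in target sequences never match a standard-residue
#' k-mer. No structural information is used -- this is the pure
#' sequence-level survey step.
#'
#' @param kmer non-empty string of uppercase amino-acid letters.
#' @param collection a named \code{AAStringSet}, a data.frame with columns
#'   \code{id}, optional \code{chain}, \code{sequence}, or a named character
#'   vector.
#' @return data.frame sorted by \code{(source_id, chain_id, position)} with
#'   columns \code{kmer, source_id, chain_id, position} (1-based start) and
#'   \code{context} (up to 11 residues centred on the match).
#' @examples
#' searchKmer("AAAAA", c(s1 = "AAAAAA"))  # overlapping hits at 1 and 2
#' @export
searchKmer <- function(kmer, collection) {
  stopifnot(is.character(kmer), length(kmer) == 1L)
  if (!nzchar(kmer) || !grepl("^[A-Za-z]+$", kmer))
    stop("kmer must be a non-empty string of amino-acid letters")
  kmer <- toupper(kmer)
  coll <- .asCollection(collection)
  empty <- data.frame(kmer = character(), source_id = character(),
                      chain_id = character(), position = integer(),
                      context = character(), stringsAsFactors = FALSE)
  if (nrow(coll) == 0L) return(empty)
  seqs <- toupper(coll$sequence)
  subject <- Biostrings::AAStringSet(seqs)
  mi <- Biostrings::vmatchPattern(kmer, subject, fixed = TRUE)
  starts <- IRanges::start(mi)
  rows <- lapply(seq_len(nrow(coll)), function(i) {
    st <- starts[[i]]
    if (!length(st)) return(NULL)
    n <- nchar(seqs[i]); w <- nchar(kmer)
    ctx <- substring(seqs[i], pmax(1L, st - 3L), pmin(n, st + w + 2L))
    data.frame(kmer = kmer, source_id = coll$id[i], chain_id = coll$chain[i],
               position = st, context = ctx, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$source_id, out$chain_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Survey several k-mers against a sequence collection
#'
#' One row per k-mer with the number of hits (overlaps counted), the number
#' of distinct source records hit, and the sorted source list.
#'
#' @param kmers character vector of k-mers.
#' @param collection as in [searchKmer()].
#' @return data.frame with columns \code{kmer, n_hits, n_sources, sources},
#'   in the input k-mer order.
#' @export
batchKmerReport <- function(kmers, collection) {
  stopifnot(is.character(kmers))
  if (!length(kmers))
    return(data.frame(kmer = character(), n_hits = integer(),
                      n_sources = integer(), sources = character(),
                      stringsAsFactors = FALSE))
  rows <- lapply(kmers, function(k) {
    hits <- searchKmer(k, collection)
    src <- sort(unique(hits$source_id))
    data.frame(kmer = toupper(k), n_hits = nrow(hits),
               n_sources = length(src), sources = paste(src, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
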