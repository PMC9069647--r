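#' Classify the experimental method of an entry
#'
#' Case-insensitive mapping of the raw method text (PDB \code{EXPDTA} record
#' or mmCIF \code{_exptl.method}) onto the three classes used to partition
#' the boundary-prefix count tables: any NMR variant (solution or solid
#' state) is \code{"NMR"}, X-ray diffraction is \code{"XRAY"}, and
#' everything else -- electron microscopy, neutron diffraction, models,
#' missing metadata -- is \code{"OTHER"}.
#'
#' @param rawMethodText character scalar (may be empty or NA).
#' @return one of \code{"NMR"}, \code{"XRAY"}, \code{"OTHER"}.
#' @examples
#' classifyMethod("SOLID-STATE NMR")
#' classifyMethod("X-RAY DIFFRACTION")
#' classifyMethod("ELECTRON MICROSCOPY")
#' @export
classifyMethod <- function(rawMethodText) {
  if (length(rawMethodText) == 0L || is.na(rawMethodText)) return("OTHER")
  up <- toupper(rawMethodText)
  if (grepl("NMR", up)) return("NMR")
  if (grepl("X-RAY DIFFRACTION", up, fixed = TRUE)) return("XRAY")
  "OTHER"
}

.guessFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
}

## Entry id declared inside the file: PDB HEADER idCode (columns 63-66) or
## the mmCIF data_ block / _entry.id. Empty string when absent.
.fileEntryID <- function(path, format) {
  lines <- tryCatch(readLines(path, n = 50L, warn = FALSE),
                    error = function(e) character())
  if (format == "pdb") {
    hit <- grep("^HEADER", lines, value = TRUE)
    if (!length(hit)) return("")
    return(trimws(substr(hit[1L], 63L, 66L)))
  }
  hit <- grep("^\\s*_entry\\.id\\s+\\S", lines, value = TRUE)
  if (length(hit)) return(trimws(sub("^\\s*_entry\\.id\\s*", "", hit[1L])))
  hit <- grep("^data_", lines, value = TRUE)
  if (length(hit)) return(sub("^data_", "", hit[1L]))
  ""
}

## Raw method text out of the source file (bio3d does not expose it).
.rawMethodText <- function(path, format) {
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) character())
  if (format == "pdb") {
    hit <- grep("^EXPDTA", lines, value = TRUE)
    if (!length(hit)) return("")
    return(trimws(paste(substring(hit, 11L), collapse = "; ")))
  }
  ## mmCIF: inline value, quoted value, or value on the following line
  i <- grep("^\\s*_exptl\\.method", lines)
  if (!length(i)) return("")
  val <- sub("^\\s*_exptl\\.method\\s*", "", lines[i[1L]])
  if (!nzchar(val) && i[1L] < length(lines)) val <- lines[i[1L] + 1L]
  gsub("^['\"]|['\"]$", "", trimws(val))
}

## Pick one CA row per residue: highest occupancy, ties by altloc identifier.
.pickCA <- function(occ, alt) {
  alt[is.na(alt)] <- ""
  ord <- order(-occ, alt)
  ord[1L]
}

#' Read a protein structure from a PDB or mmCIF file
#'
#' Parses the coordinate section into a [ProteinStructure-class]: every chain
#' of every model as an author-ordered residue table with one C-alpha
#' position per residue. Alternate locations are resolved to the conformer
#' with the highest occupancy (ties by altloc identifier); HETATM records are
#' dropped except selenomethionine (\code{MSE}), which stays in the chain;
#' residues without a C-alpha remain in the sequence with an NA position.
#' All models of a multi-model (NMR) file are retained.
#'
#' @param path path to a structure file.
#' @param format \code{"auto"} (by extension), \code{"pdb"} or \code{"cif"}.
#' @param entryID identifier to store; default the file base name without
#'   extension, uppercased when it looks like a 4-character PDB code.
#' @param mseToMet map MSE to \code{M} (default) instead of \code{X}.
#' @return a [ProteinStructure-class]. A file with no parsable residues
#'   yields an empty structure (one model, zero chains) with a warning.
#' @seealso [writeStructurePDB()], [deriveSequence()], [classifyMethod()]
#' @export
readStructure <- function(path, format = c("auto", "pdb", "cif"),
                          entryID = NULL, mseToMet = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- .guessFormat(path)
  if (is.null(entryID)) {
    entryID <- .fileEntryID(path, format)
    if (!nzchar(entryID))
      entryID <- tools::file_path_sans_ext(basename(path))
    if (grepl("^[0-9][A-Za-z0-9]{3}$", entryID)) entryID <- toupper(entryID)
  }
  mclass <- classifyMethod(.rawMethodText(path, format))

  parsed <- tryCatch(
    if (format == "cif")
      suppressWarnings(bio3d::read.cif(path, multi = TRUE, verbose = FALSE))
    else
      suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                       verbose = FALSE)),
    error = function(e) stop("failed to parse '", path, "' as ", format, ": ",
                             conditionMessage(e), call. = FALSE))

  atoms <- parsed$atom
  keep <- atoms$type == "ATOM" | (atoms$type == "HETATM" & atoms$resid == "MSE")
  atoms <- atoms[keep, , drop = FALSE]
  if (nrow(atoms) == 0L) {
    warning("no parsable residues in '", path, "'")
    return(ProteinStructure(entryID, mclass, models = list(structure(list(),
                                                                     names = character()))))
  }
  rowid <- which(keep)  # row index into the full atom table = xyz column block

  atoms$chain[is.na(atoms$chain) | !nzchar(atoms$chain)] <- "_"
  ins <- atoms$insert; ins[is.na(ins)] <- ""
  occ <- atoms$o; occ[is.na(occ)] <- 1
  reskey <- paste(atoms$chain, atoms$resno, ins, sep = "\r")

  ## one record per residue, in file order
  first <- !duplicated(reskey)
  res <- data.frame(chain = atoms$chain[first], resno = atoms$resno[first],
                    ins = ins[first], resid = atoms$resid[first],
                    stringsAsFactors = FALSE)
  res$aa <- aaThreeToOne(res$resid, mseToMet = mseToMet)

  ## resolve the CA atom row (into the original atom table) per residue
  isCA <- atoms$elety == "CA"
  caRow <- rep(NA_integer_, nrow(res))
  if (any(isCA)) {
    caIdx <- split(which(isCA), reskey[isCA])
    sel <- vapply(caIdx, function(ii)
      ii[.pickCA(occ[ii], atoms$alt[ii])], integer(1))
    caRow[match(names(caIdx), reskey[first])] <- rowid[sel]
  }

  ## xyz: one row per model, 3 columns per atom of the full table
  xyz <- parsed$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (ncol(xyz) != 3L * nrow(parsed$atom)) {
    ## models disagree in atom content; keep the first model only
    warning("models of '", path, "' differ in atom records; keeping model 1")
    flat <- as.vector(t(xyz))  # back to file order
    xyz <- matrix(flat[seq_len(3L * nrow(parsed$atom))], nrow = 1L)
  }
  nModels <- nrow(xyz)

  ## author ordering within chains; chains keep file order
  chainsInOrder <- unique(res$chain)
  models <- vector("list", nModels)
  for (m in seq_len(nModels)) {
    model <- list()
    for (cid in chainsInOrder) {
      ri <- which(res$chain == cid)
      ri <- ri[order(res$resno[ri], res$ins[ri])]
      ca <- caRow[ri]
      has <- !is.na(ca)
      cx <- cy <- cz <- rep(NA_real_, length(ri))
      if (any(has)) {
        cx[has] <- xyz[m, 3L * ca[has] - 2L]
        cy[has] <- xyz[m, 3L * ca[has] - 1L]
        cz[has] <- xyz[m, 3L * ca[has]]
      }
      model[[cid]] <- data.frame(resno = res$resno[ri], ins = res$ins[ri],
                                 resid = res$resid[ri], aa = res$aa[ri],
                                 x = cx, y = cy, z = cz,
                                 stringsAsFactors = FALSE)
    }
    models[[m]] <- model
  }

  seqres <- list()
  if (!is.null(parsed$seqres) && length(parsed$seqres)) {
    sr <- split(unname(parsed$seqres), names(parsed$seqres))
    seqres <- lapply(sr, function(v)
      paste(aaThreeToOne(v, mseToMet = mseToMet), collapse = ""))
  }

  ProteinStructure(entryID, mclass, models = models, seqres = seqres)
}

#' Derive the one-letter sequence of a chain
#'
#' Concatenates the one-letter codes of all residues of a chain in author
#' (N- to C-terminal) order, including residues without a resolved C-alpha.
#'
#' @param chain a chain data.frame as stored in a [ProteinStructure-class].
#' @return a character scalar (empty string for an empty chain).
#' @examples
#' ch <- data.frame(resno = 1:3, ins = "", resid = c("GLY", "GLU", "TYR"),
#'                  aa = c("G", "E", "Y"), x = 0, y = 0, z = 0)
#' deriveSequence(ch)
#' @export
deriveSequence <- function(chain) {
  stopifnot(is.data.frame(chain))
  if (nrow(chain) == 0L) return("")
  paste(chain$aa, collapse = "")
}

#' Sequences of all chains of a structure
#'
#' @param x a [ProteinStructure-class].
#' @param model model index (for ATOM-derived sequences).
#' @param use \code{"atom"} (default): sequences derived from the residues
#'   present in the coordinate section; \code{"seqres"}: SEQRES-declared
#'   sequences where available (chains without SEQRES fall back to ATOM).
#' @return a named \code{Biostrings::AAStringSet}; names are
#'   \code{entryID_chainID}.
#' @export
structureSequences <- function(x, model = 1L, use = c("atom", "seqres")) {
  use <- match.arg(use)
  stopifnot(is(x, "ProteinStructure"))
  chains <- if (nModels(x) >= model) x@models[[model]] else list()
  seqs <- vapply(chains, deriveSequence, character(1))
  if (use == "seqres" && length(x@seqres)) {
    hit <- intersect(names(seqs), names(x@seqres))
    seqs[hit] <- unlist(x@seqres[hit])
  }
  if (!length(seqs)) return(Biostrings::AAStringSet())
  out <- Biostrings::AAStringSet(unlist(seqs))
  names(out) <- paste(x@entryID, names(seqs), sep = "_")
  out
}

#' Export structure sequences as FASTA
#'
#' Writes one record per chain with headers \code{>entryID_chainID}.
#'
#' @inheritParams structureSequences
#' @param path output file.
#' @export
writeStructureFasta <- function(x, path, model = 1L, use = c("atom", "seqres")) {
  Biostrings::writeXStringSet(structureSequences(x, model, use), path)
  invisible(path)
}

.EXPDTA <- c(NMR = "SOLID-STATE NMR", XRAY = "X-RAY DIFFRACTION",
             OTHER = "THEORETICAL MODEL")

#' Write a structure as a fixed-column PDB file
#'
#' Emits standard \code{ATOM} records for the C-alpha trace of every model
#' (with \code{MODEL}/\code{ENDMDL} framing when there is more than one), a
#' \code{HEADER} line carrying the entry identifier, and an \code{EXPDTA}
#' line consistent with the structure's method class. Every residue must
#' have a resolved C-alpha. Chain identifiers wider than the single PDB
#' chain-id column raise an error rather than being truncated.
#'
#' @param x a [ProteinStructure-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso [readStructure()] -- a written file re-parses to the same
#'   residues and coordinates within PDB precision (1e-3 Angstrom).
#' @export
writeStructurePDB <- function(x, path) {
  stopifnot(is(x, "ProteinStructure"))
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot write '", path, "': ", conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  ## the HEADER idCode field holds 4 characters; longer synthetic labels are
  ## omitted there and recovered from the file name on re-parse
  id4 <- if (nchar(x@entryID) <= 4L) x@entryID else ""
  out <- c(sprintf("HEADER    %-40s%-9s   %-4s", "CROSS-BETA MODEL", "", id4),
           sprintf("EXPDTA    %s", .EXPDTA[[x@methodClass]]))
  multi <- nModels(x) > 1L
  for (m in seq_len(nModels(x))) {
    if (multi) out <- c(out, sprintf("MODEL     %4d", m))
    ser <- 0L
    for (cid in names(x@models[[m]])) {
      if (nchar(cid) != 1L)
        stop("chain id '", cid, "' does not fit the PDB chain-id column")
      ch <- x@models[[m]][[cid]]
      if (nrow(ch) && anyNA(ch$x))
        stop("chain ", cid, " has residues without a C-alpha position")
      if (nrow(ch) && any(ch$resno > 9999L | ch$resno < -999L))
        stop("residue numbers outside the PDB resSeq column range")
      for (i in seq_len(nrow(ch))) {
        ser <- ser + 1L
        out <- c(out, sprintf(
          "ATOM  %5d  CA  %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          ser, ch$resid[i], cid, ch$resno[i],
          if (nzchar(ch$ins[i])) ch$ins[i] else " ",
          ch$x[i], ch$y[i], ch$z[i], 1, 0))
      }
      if (nrow(ch)) out <- c(out, "TER")
    }
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, con, sep = "\n")
  invisible(path)
}
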