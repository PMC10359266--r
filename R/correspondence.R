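#' Pairwise global sequence alignment and residue correspondence
#'
#' Aligns two amino-acid sequences by Needleman-Wunsch global alignment with
#' BLOSUM62 scoring and affine gap penalties, and reports percent identity and
#' percent similarity over aligned (both non-gap) columns. Similarity follows
#' the usual convention: an aligned pair is similar if its substitution score
#' is positive.
#'
#' @param seqA,seqB Amino-acid sequences: single strings, or named character
#'   vectors of one-letter codes (e.g. from [structure_sequence()], in which
#'   case the names -- author residue numbers -- label the alignment pairs).
#' @param gap_open,gap_extend Affine gap penalties (positive numbers).
#' @param submat Substitution matrix name, default `"BLOSUM62"`.
#' @param end_gap_free If `TRUE`, terminal gaps are not penalised (overlap
#'   alignment).
#' @return Object of class `residue_map`: list with `pairs` (data frame of
#'   aligned non-gap columns: `posA`, `posB`, `labelA`, `labelB`, `aaA`,
#'   `aaB`, `identical`, `similar`), `identity_pct`, `similarity_pct`,
#'   `score`, and the gapped alignment strings `alnA`, `alnB`.
#' @export
align_sequences <- function(seqA, seqB, gap_open = 10, gap_extend = 0.5,
                            submat = "BLOSUM62", end_gap_free = FALSE) {
  labA <- .seq_labels(seqA); labB <- .seq_labels(seqB)
  sA <- .seq_string(seqA);   sB <- .seq_string(seqB)
  for (s in c(sA, sB)) {
    if (nchar(s) == 0L) stop("empty sequence")
    if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", s))
      stop("non-amino-acid characters in sequence: ",
           gsub("[ACDEFGHIKLMNPQRSTVWY]", "", s))
  }
  mat <- .get_submat(submat)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sA), Biostrings::AAString(sB),
    substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend,
    type = if (end_gap_free) "overlap" else "global")
  a1 <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  a2 <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  posA <- cumsum(a1 != "-"); posB <- cumsum(a2 != "-")
  both <- a1 != "-" & a2 != "-"
  pairs <- data.frame(
    posA = posA[both], posB = posB[both],
    labelA = labA[posA[both]], labelB = labB[posB[both]],
    aaA = a1[both], aaB = a2[both], stringsAsFactors = FALSE)
  pairs$identical <- pairs$aaA == pairs$aaB
  pairs$similar <- mat[cbind(pairs$aaA, pairs$aaB)] > 0
  out <- list(
    pairs = pairs,
    identity_pct   = 100 * mean(pairs$identical),
    similarity_pct = 100 * mean(pairs$similar),
    score = Biostrings::score(aln),
    alnA = paste(a1, collapse = ""), alnB = paste(a2, collapse = ""))
  class(out) <- "residue_map"
  out
}

.seq_string <- function(s) {
  if (length(s) > 1L) paste(toupper(s), collapse = "") else toupper(s)
}
.seq_labels <- function(s) {
  if (length(s) > 1L && !is.null(names(s))) names(s)
  else as.character(seq_len(if (length(s) > 1L) length(s) else nchar(s)))
}
.get_submat <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' @export
print.residue_map <- function(x, ...) {
  cat(sprintf("residue_map: %d aligned pairs, identity %.1f%%, similarity %.1f%%\n",
              nrow(x$pairs), x$identity_pct, x$similarity_pct))
  if (!is.null(x$unmatchedA))
    cat(sprintf("  unmatched: %d in A, %d in B\n",
                length(x$unmatchedA), length(x$unmatchedB)))
  invisible(x)
}

#' Restrict a sequence correspondence to residues modeled in both structures
#'
#' Takes an alignment whose pair labels are author residue numbers and keeps
#' only pairs where both residues are present (modeled) in the respective
#' structures. Unmatched modeled residues are listed.
#'
#' @param map A `residue_map` from [align_sequences()] on sequences labelled
#'   with author residue numbers.
#' @param sA,sB `pore_structure` objects.
#' @param chainA,chainB Chain identifiers; default first protein chain.
#' @return A `residue_map` whose `pairs` gain residue-key columns `keyA`,
#'   `keyB` and resno columns `resnoA`, `resnoB`, plus `unmatchedA`,
#'   `unmatchedB` (residue keys modeled in one structure only).
#' @export
map_residues <- function(map, sA, sB, chainA = NULL, chainB = NULL) {
  rtA <- .protein_residues(sA, chainA)
  rtB <- .protein_residues(sB, chainB)
  p <- map$pairs
  p$resnoA <- suppressWarnings(as.integer(p$labelA))
  p$resnoB <- suppressWarnings(as.integer(p$labelB))
  iA <- match(p$resnoA, rtA$resno)
  iB <- match(p$resnoB, rtB$resno)
  keep <- !is.na(iA) & !is.na(iB)
  if (!any(keep)) stop("no aligned residue pair is modeled in both structures")
  p <- p[keep, , drop = FALSE]
  p$keyA <- rtA$key[iA[keep]]
  p$keyB <- rtB$key[iB[keep]]
  out <- map
  out$pairs <- p
  out$identity_pct <- 100 * mean(p$identical)
  out$similarity_pct <- 100 * mean(p$similar)
  out$unmatchedA <- setdiff(rtA$key, p$keyA)
  out$unmatchedB <- setdiff(rtB$key, p$keyB)
  out
}

.protein_residues <- function(s, chain = NULL) {
  rt <- residue_table(s)
  rt <- rt[rt$comp %in% .STD_AA, ]
  if (nrow(rt) == 0L) stop("no protein residues in structure ", s$id)
  if (is.null(chain)) chain <- rt$chain[1L]
  rt <- rt[rt$chain == chain, ]
  rt[order(rt$resno, rt$icode), ]
}

#' Residue correspondence between two structures in one step
#'
#' Convenience wrapper: extracts the chain sequences, aligns them globally and
#' restricts the correspondence to modeled residues.
#'
#' @inheritParams map_residues
#' @param ... Passed to [align_sequences()].
#' @return A `residue_map`, see [map_residues()].
#' @export
structure_map <- function(sA, sB, chainA = NULL, chainB = NULL, ...) {
  map <- align_sequences(structure_sequence(sA, chainA),
                         structure_sequence(sB, chainB), ...)
  map_residues(map, sA, sB, chainA, chainB)
}

#' Write a residue map as TSV
#'
#' @param map A `residue_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_residue_map <- function(map, path) {
  write.table(map$pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
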