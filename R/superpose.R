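#' Kabsch least-squares superposition
#'
#' Computes the proper rotation and translation minimising the RMSD between
#' two paired coordinate sets, via SVD of the cross-covariance matrix with the
#' usual determinant correction so that the rotation is never a reflection.
#'
#' @param P,Q Numeric n x 3 matrices of paired coordinates (P is moved onto Q).
#' @return Object of class `pore_superposition`: list with `rotation` (3 x 3,
#'   det +1), `translation` (length-3), `rmsd` (Angstrom) and `n_atoms`.
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) stop("coordinate sets differ in size")
  if (nrow(P) < 3L) stop("need at least 3 points")
  if (!all(is.finite(P)) || !all(is.finite(Q))) stop("non-finite coordinates")
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  if (qr(Pc)$rank < 2L || qr(Qc)$rank < 2L)
    stop("degenerate (collinear) point set")
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rmsd <- sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  structure(list(rotation = R, translation = as.numeric(qc - R %*% pc),
                 rmsd = rmsd, n_atoms = nrow(P)),
            class = "pore_superposition")
}

#' @export
print.pore_superposition <- function(x, ...) {
  cat(sprintf("pore_superposition: %d atoms, rmsd %.3f A\n", x$n_atoms, x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param sp A `pore_superposition`.
#' @param X n x 3 coordinate matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(sp, X) {
  X <- as.matrix(X)
  sweep(X %*% t(sp$rotation), 2, -sp$translation)
}

#' RMSD between unfitted coordinate sets
#'
#' Plain root-mean-square deviation in the given (fixed) frame, with no
#' refitting.
#'
#' @param P,Q Numeric n x 3 matrices.
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) stop("coordinate sets differ in size")
  sqrt(mean(rowSums((P - Q)^2)))
}

# paired coordinates for mapped residues under an atom selection
paired_coords <- function(sA, sB, map, selection = c("CA", "heavy")) {
  selection <- match.arg(selection)
  aA <- sA$atoms; aB <- sB$atoms
  kA <- res_key(aA$chain, aA$resno, aA$icode, aA$comp)
  kB <- res_key(aB$chain, aB$resno, aB$icode, aB$comp)
  P <- list(); Q <- list()
  for (i in seq_len(nrow(map$pairs))) {
    ra <- aA[kA == map$pairs$keyA[i], ]
    rb <- aB[kB == map$pairs$keyB[i], ]
    if (selection == "CA") {
      ra <- ra[ra$name == "CA", ]; rb <- rb[rb$name == "CA", ]
      common <- if (nrow(ra) && nrow(rb)) "CA" else character()
    } else {
      ra <- ra[ra$element != "H", ]; rb <- rb[rb$element != "H", ]
      common <- intersect(ra$name, rb$name)
    }
    if (!length(common)) next
    P[[length(P) + 1L]] <- as.matrix(ra[match(common, ra$name), c("x", "y", "z")])
    Q[[length(Q) + 1L]] <- as.matrix(rb[match(common, rb$name), c("x", "y", "z")])
  }
  if (!length(P)) stop("empty atom selection over the residue map")
  list(P = do.call(rbind, P), Q = do.call(rbind, Q))
}

#' Superpose two structures over a residue correspondence
#'
#' @param sA,sB `pore_structure` objects.
#' @param map A `residue_map` (see [structure_map()]).
#' @param selection `"CA"` (alpha carbons) or `"heavy"` (all shared heavy
#'   atoms of mapped residues).
#' @return A `pore_superposition` mapping A onto B, with `selection` recorded.
#' @export
superpose_structures <- function(sA, sB, map, selection = c("CA", "heavy")) {
  selection <- match.arg(selection)
  pq <- paired_coords(sA, sB, map, selection)
  sp <- kabsch_superpose(pq$P, pq$Q)
  sp$selection <- selection
  sp
}

#' RMSD between mapped residues of two structures
#'
#' Superposes on the selection and returns the optimal RMSD.
#'
#' @inheritParams superpose_structures
#' @return RMSD in Angstrom.
#' @export
paired_rmsd <- function(sA, sB, map, selection = c("CA", "heavy")) {
  superpose_structures(sA, sB, map, selection)$rmsd
}

#' Displacement of one atom between mapped residues
#'
#' Distance between a named atom of a residue in structure A and the same atom
#' of the corresponding residue in structure B, after moving A into B's frame.
#' The default frame is the whole-map C-alpha superposition.
#'
#' @inheritParams superpose_structures
#' @param resno Author residue number (in structure A's numbering).
#' @param atom_name Atom name, default `"CA"`.
#' @param frame A `pore_superposition`; default computed from `map` with
#'   C-alpha selection.
#' @return Displacement in Angstrom.
#' @export
residue_displacement <- function(sA, sB, map, resno, atom_name = "CA",
                                 frame = NULL) {
  if (is.null(frame)) frame <- superpose_structures(sA, sB, map, "CA")
  i <- match(resno, map$pairs$resnoA)
  if (is.na(i)) stop("residue ", resno, " not in the residue map")
  xa <- .atom_xyz(sA, map$pairs$keyA[i], atom_name)
  xb <- .atom_xyz(sB, map$pairs$keyB[i], atom_name)
  xa2 <- apply_superposition(frame, matrix(xa, 1))
  sqrt(sum((xa2 - xb)^2))
}

.atom_xyz <- function(s, key, atom_name) {
  a <- s$atoms
  k <- res_key(a$chain, a$resno, a$icode, a$comp)
  i <- which(k == key & a$name == atom_name)
  if (!length(i)) stop("atom ", atom_name, " not found in residue ", key,
                       " of ", s$id)
  as.numeric(a[i[1L], c("x", "y", "z")])
}
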