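# Shared fixtures and independent oracles for the test suite.

# minimal hand-built structure: two residues with one named heteroatom each,
# placed exactly `d` apart, plus CA anchors
two_residue_structure <- function(compA, atomA, elemA, compB, atomB, elemB, d,
                                  hetB = FALSE) {
  atoms <- data.frame(
    serial = 1:4,
    name = c("CA", atomA, "CA", atomB),
    element = c("C", elemA, "C", elemB),
    x = c(0, 1.5, d + 3, 1.5 + d),
    y = 0, z = 0,
    occ = 1, altloc = "",
    chain = "A", resno = c(1L, 1L, 2L, 2L), icode = "",
    comp = c(compA, compA, compB, compB),
    hetero = c(FALSE, FALSE, hetB, hetB),
    stringsAsFactors = FALSE)
  poregraph:::.new_structure("pair", atoms)
}

# random proper rotation from a uniform axis and angle
random_rotation <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# numeric-minimization oracle for the optimal superposition RMSD:
# parameterise rotation by a Rodrigues vector, minimise with multi-start BFGS
oracle_min_rmsd <- function(P, Q, n_starts = 8) {
  rodrigues <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    ax <- v / th
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  obj <- function(par) {
    R <- rodrigues(par[1:3])
    moved <- sweep(P %*% t(R), 2, -par[4:6])
    sqrt(mean(rowSums((moved - Q)^2)))
  }
  best <- Inf
  for (k in seq_len(n_starts)) {
    p0 <- c(stats::runif(3, -pi, pi), colMeans(Q) - colMeans(P))
    fit <- stats::optim(p0, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    best <- min(best, fit$value)
  }
  best
}

# exhaustive enumeration of global alignments with affine gaps:
# every monotone path of moves M (pair), X (gap in B), Y (gap in A); a gap run
# of length L costs gap_open + gap_ext * L (the pairwiseAlignment convention)
oracle_align_score <- function(sA, sB, mat, gap_open = 10, gap_ext = 0.5) {
  a <- strsplit(sA, "")[[1]]; b <- strsplit(sB, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, last) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, score); return(invisible())
    }
    if (i <= length(a) && j <= length(b))
      rec(i + 1, j + 1, score + mat[a[i], b[j]], "M")
    if (i <= length(a))
      rec(i + 1, j, score - gap_ext - if (last != "X") gap_open else 0, "X")
    if (j <= length(b))
      rec(i, j + 1, score - gap_ext - if (last != "Y") gap_open else 0, "Y")
  }
  rec(1, 1, 0, "M")
  best
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

# random fixture spec with k planted bonds on well-separated helix rungs
random_planted_spec <- function(seed, k = NULL, decoys = list()) {
  base <- fixture_spec(seed = seed)
  set.seed(seed)
  if (is.null(k)) k <- sample(0:5, 1)
  rungs <- seq(2, base$residues_per_helix - 1, by = 3)
  stopifnot(k <= length(rungs))
  rungs <- sort(sample(rungs, k))
  helices <- sample(base$n_helices - 1L, k, replace = TRUE)
  plants <- data.frame(
    res_a = vapply(seq_len(k), function(i)
      fixture_residue(base, helices[i], rungs[i]), integer(1)),
    res_b = vapply(seq_len(k), function(i)
      fixture_residue(base, helices[i] + 1L, rungs[i]), integer(1)),
    distance = round(stats::runif(k, 2.6, 3.9), 2),
    water = if (k) stats::runif(k) < 0.4 else logical(0))
  fixture_spec(seed = seed, planted_hbonds = plants, decoys = decoys)
}
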