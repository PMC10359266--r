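#' Default donor/acceptor table for distance-criterion H-bond detection
#'
#' Side-chain polar heteroatoms of the 20 standard amino acids, the water
#' oxygen (donor and acceptor), the Met thioether sulfur (weak acceptor; the
#' reason the default cutoff extends to 4.0 Angstrom), both His ring nitrogens
#' as donor and acceptor (protonation unknown in the models), and the
#' retinylidene Schiff-base nitrogen (Lys NZ, or NZ of a fused retinal-lysine
#' component) as donor. Backbone N/O are excluded: the graphs are side-chain
#' H-bond graphs.
#'
#' @return Data frame with columns `comp`, `atom`, `role`
#'   (`donor`/`acceptor`/`both`).
#' @export
donor_acceptor_table <- function() {
  t <- rbind(
    c("SER", "OG",  "both"),
    c("THR", "OG1", "both"),
    c("TYR", "OH",  "both"),
    c("ASN", "OD1", "acceptor"), c("ASN", "ND2", "donor"),
    c("GLN", "OE1", "acceptor"), c("GLN", "NE2", "donor"),
    c("ASP", "OD1", "acceptor"), c("ASP", "OD2", "acceptor"),
    c("GLU", "OE1", "acceptor"), c("GLU", "OE2", "acceptor"),
    c("LYS", "NZ",  "donor"),
    c("ARG", "NE",  "donor"), c("ARG", "NH1", "donor"), c("ARG", "NH2", "donor"),
    c("HIS", "ND1", "both"), c("HIS", "NE2", "both"),
    c("TRP", "NE1", "donor"),
    c("CYS", "SG",  "both"),
    c("MET", "SD",  "acceptor"),
    c("HOH", "O",   "both"), c("DOD", "O", "both"), c("WAT", "O", "both"),
    c("LYR", "NZ",  "donor"))
  data.frame(comp = t[, 1], atom = t[, 2], role = t[, 3],
             stringsAsFactors = FALSE)
}

# polar atoms of a structure annotated with residue key and H-bonding role
.polar_atoms <- function(s, table = donor_acceptor_table()) {
  a <- s$atoms
  i <- match(paste(a$comp, a$name), paste(table$comp, table$atom))
  sel <- which(!is.na(i))
  cbind(a[sel, c("name", "x", "y", "z", "comp", "chain", "resno", "icode")],
        key = res_key(a$chain[sel], a$resno[sel], a$icode[sel], a$comp[sel]),
        role = table$role[i[sel]])
}

.role_pair_ok <- function(r1, r2) {
  (r1 %in% c("donor", "both") & r2 %in% c("acceptor", "both")) |
  (r2 %in% c("donor", "both") & r1 %in% c("acceptor", "both"))
}

.hbond_frame <- function(pa, i, j, cutoff) {
  d <- sqrt((pa$x[i] - pa$x[j])^2 + (pa$y[i] - pa$y[j])^2 + (pa$z[i] - pa$z[j])^2)
  keep <- d > 0 & d <= cutoff & pa$key[i] != pa$key[j] &
    .role_pair_ok(pa$role[i], pa$role[j])
  i <- i[keep]; j <- j[keep]; d <- d[keep]
  # canonical atom-pair order for determinism
  swap <- paste(pa$key[i], pa$name[i]) > paste(pa$key[j], pa$name[j])
  ii <- ifelse(swap, j, i); jj <- ifelse(swap, i, j)
  out <- data.frame(
    key_a = pa$key[ii], atom_a = pa$name[ii],
    key_b = pa$key[jj], atom_b = pa$name[jj],
    distance = d,
    strength = ifelse(d <= 3.5, "strong", "weak"),
    stringsAsFactors = FALSE)
  out <- out[!duplicated(paste(out$key_a, out$atom_a, out$key_b, out$atom_b)), ]
  out[order(out$key_a, out$atom_a, out$key_b, out$atom_b), ]
}

#' Detect hydrogen bonds by the heteroatom distance criterion
#'
#' A bond is any donor/acceptor heteroatom pair from the table, in different
#' residues, within `cutoff` Angstrom. No angle term and no hydrogens: the
#' criterion is donor-acceptor heteroatom distance only, appropriate for
#' models without modeled hydrogens. Pairs at or below 3.5 Angstrom are
#' classed `strong`, the rest `weak`.
#'
#' @param s A `pore_structure`.
#' @param cutoff Distance cutoff in Angstrom, default 4.0 (must be in (0, 5]).
#' @param table Donor/acceptor table, see [donor_acceptor_table()].
#' @param method `"grid"` (cell-list neighbor search, default) or
#'   `"all_pairs"` (exhaustive; same result, used as internal cross-check).
#' @return Data frame of class `hbond_list`: columns `key_a`, `atom_a`,
#'   `key_b`, `atom_b`, `distance`, `strength`, sorted canonically.
#' @export
detect_hbonds <- function(s, cutoff = 4.0, table = donor_acceptor_table(),
                          method = c("grid", "all_pairs")) {
  method <- match.arg(method)
  stopifnot(cutoff > 0, cutoff <= 5)
  pa <- .polar_atoms(s, table)
  if (nrow(pa) < 2L) {
    out <- .hbond_frame(pa, integer(), integer(), cutoff)
  } else if (method == "all_pairs") {
    idx <- which(upper.tri(matrix(0, nrow(pa), nrow(pa))), arr.ind = TRUE)
    out <- .hbond_frame(pa, idx[, 1], idx[, 2], cutoff)
  } else {
    cell <- floor(cbind(pa$x, pa$y, pa$z) / cutoff)
    ckey <- paste(cell[, 1], cell[, 2], cell[, 3])
    members <- split(seq_len(nrow(pa)), ckey)
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    I <- integer(); J <- integer()
    for (ck in names(members)) {
      ci <- as.integer(strsplit(ck, " ")[[1L]])
      mi <- members[[ck]]
      nb <- unlist(members[paste(ci[1] + offs[, 1], ci[2] + offs[, 2],
                                 ci[3] + offs[, 3])], use.names = FALSE)
      if (is.null(nb)) nb <- integer()
      pairs <- expand.grid(i = mi, j = nb)
      pairs <- pairs[pairs$i < pairs$j, , drop = FALSE]
      I <- c(I, pairs$i); J <- c(J, pairs$j)
    }
    out <- .hbond_frame(pa, I, J, cutoff)
  }
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  class(out) <- c("hbond_list", "data.frame")
  out
}

#' Build a residue-level H-bond graph
#'
#' Nodes are H-bonding side chains (one node per residue), the retinal Schiff
#' base, and water molecules; edges are detected H-bonds collapsed to unique
#' node pairs (minimum distance kept; an edge is `strong` if any contributing
#' atom pair is at or below 3.5 Angstrom).
#'
#' @param hbonds An `hbond_list` from [detect_hbonds()] on `s`.
#' @param s The `pore_structure` the bonds were detected in.
#' @param water_policy `"include_water_water"` (default; water-water edges
#'   kept) or `"exclude_water_water"`.
#' @return Object of class `hbond_graph`: list with `nodes` (data frame:
#'   `key`, `type` in water/sidechain, `comp`, `chain`, `resno`), `edges`
#'   (data frame: `key_a`, `key_b`, `distance`, `strength`), `cutoff`,
#'   `water_policy`.
#' @export
build_graph <- function(hbonds, s,
                        water_policy = c("include_water_water",
                                         "exclude_water_water")) {
  water_policy <- match.arg(water_policy)
  cls <- classify_entities(s, warn = FALSE)
  ntype <- function(k) ifelse(cls[k] == "water", "water", "sidechain")
  e <- as.data.frame(hbonds)
  if (nrow(e)) {
    pair <- paste(e$key_a, e$key_b)
    agg_d <- tapply(e$distance, pair, min)
    first <- e[!duplicated(pair), c("key_a", "key_b")]
    first <- first[match(names(agg_d), paste(first$key_a, first$key_b)), ]
    edges <- data.frame(key_a = first$key_a, key_b = first$key_b,
                        distance = as.numeric(agg_d),
                        strength = ifelse(agg_d <= 3.5, "strong", "weak"),
                        stringsAsFactors = FALSE)
    if (water_policy == "exclude_water_water") {
      ww <- ntype(edges$key_a) == "water" & ntype(edges$key_b) == "water"
      edges <- edges[!ww, , drop = FALSE]
    }
    edges <- edges[order(edges$key_a, edges$key_b), ]
  } else {
    edges <- data.frame(key_a = character(), key_b = character(),
                        distance = numeric(), strength = character(),
                        stringsAsFactors = FALSE)
  }
  keys <- sort(unique(c(edges$key_a, edges$key_b)))
  rt <- residue_table(s)
  i <- match(keys, rt$key)
  nodes <- data.frame(key = keys, type = unname(ntype(keys)),
                      comp = rt$comp[i], chain = rt$chain[i],
                      resno = rt$resno[i], stringsAsFactors = FALSE)
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 cutoff = attr(hbonds, "cutoff"), water_policy = water_policy),
            class = "hbond_graph")
}

#' @export
print.hbond_graph <- function(x, ...) {
  s <- summarize_graph(x)
  cat(sprintf("hbond_graph: %d nodes, %d edges (%d water-mediated, %d strong), cutoff %.1f A\n",
              nrow(x$nodes), s["total_edges"], s["water_mediated_edges"],
              s["strong_edges"], x$cutoff))
  invisible(x)
}

#' Summary statistics of an H-bond graph
#'
#' @param g An `hbond_graph`.
#' @return Named integer vector: `total_edges`, `water_mediated_edges` (edges
#'   with exactly one water endpoint), `water_water_edges`,
#'   `sidechain_sidechain_edges`, `strong_edges`.
#' @export
summarize_graph <- function(g) {
  tA <- g$nodes$type[match(g$edges$key_a, g$nodes$key)]
  tB <- g$nodes$type[match(g$edges$key_b, g$nodes$key)]
  nw <- (tA == "water") + (tB == "water")
  c(total_edges = nrow(g$edges),
    water_mediated_edges = sum(nw == 1L),
    water_water_edges = sum(nw == 2L),
    sidechain_sidechain_edges = sum(nw == 0L),
    strong_edges = sum(g$edges$strength == "strong"))
}

#' Conserved/difference H-bond graph of two structures
#'
#' Partitions the edges of two H-bond graphs, built with the same cutoff and
#' donor/acceptor table, into those conserved in both structures under the
#' residue correspondence and those unique to either. Waters have no canonical
#' correspondence across structures, so every edge involving a water is
#' structure-specific (unique); conserved edges connect amino-acid/Schiff-base
#' nodes only.
#'
#' @param gA,gB `hbond_graph` objects.
#' @param map A `residue_map` whose pairs carry `keyA`/`keyB` residue keys
#'   (see [structure_map()]).
#' @return Object of class `difference_graph`: list with edge data frames
#'   `conserved` (keys in both structures' naming), `unique_A`, `unique_B`,
#'   and `nodes` (per-node `shared`/`unique` class for both graphs).
#' @export
difference_graph <- function(gA, gB, map) {
  if (is.null(map$pairs) || nrow(map$pairs) == 0L) stop("empty residue map")
  a2b <- setNames(map$pairs$keyB, map$pairs$keyA)
  typeA <- setNames(gA$nodes$type, gA$nodes$key)
  typeB <- setNames(gB$nodes$type, gB$nodes$key)
  eA <- gA$edges; eB <- gB$edges
  mapped_a <- unname(a2b[eA$key_a]); mapped_b <- unname(a2b[eA$key_b])
  mappable <- !is.na(mapped_a) & !is.na(mapped_b) &
    typeA[eA$key_a] != "water" & typeA[eA$key_b] != "water"
  # candidate conserved edge in B's keyspace, canonical order
  ca <- pmin(mapped_a, mapped_b); cb <- pmax(mapped_a, mapped_b)
  inB <- paste(ca, cb) %in% paste(pmin(eB$key_a, eB$key_b),
                                  pmax(eB$key_a, eB$key_b))
  cons <- mappable & inB
  conserved <- cbind(eA[cons, , drop = FALSE],
                     keyB_a = ca[cons], keyB_b = cb[cons])
  consB <- paste(pmin(eB$key_a, eB$key_b), pmax(eB$key_a, eB$key_b)) %in%
    paste(conserved$keyB_a, conserved$keyB_b)
  sharedA <- unique(c(conserved$key_a, conserved$key_b))
  sharedB <- unique(c(conserved$keyB_a, conserved$keyB_b))
  node_frame <- function(tag, n, shared) {
    if (nrow(n) == 0L) return(NULL)
    data.frame(structure = tag, key = n$key, type = n$type,
               class = ifelse(n$key %in% shared, "shared", "unique"),
               stringsAsFactors = FALSE)
  }
  nodes <- rbind(node_frame("A", gA$nodes, sharedA),
                 node_frame("B", gB$nodes, sharedB))
  rownames(conserved) <- NULL
  structure(list(conserved = conserved,
                 unique_A = eA[!cons, , drop = FALSE],
                 unique_B = eB[!consB, , drop = FALSE],
                 nodes = nodes),
            class = "difference_graph")
}

#' @export
print.difference_graph <- function(x, ...) {
  cat(sprintf("difference_graph: %d conserved, %d unique to A, %d unique to B\n",
              nrow(x$conserved), nrow(x$unique_A), nrow(x$unique_B)))
  invisible(x)
}

#' Project an H-bond graph onto the membrane normal and plane
#'
#' Per node: `z` is the C-alpha z coordinate of the residue (water nodes use
#' their oxygen position), assuming the structure is oriented with the
#' membrane normal on z; `x` is the first principal component of the node
#' (x, y) membrane-plane positions. Sign convention: the node with the
#' largest absolute PC-1 score is given a positive score.
#'
#' @param g An `hbond_graph`.
#' @param s The `pore_structure` the graph was built from.
#' @return Data frame: `key`, `x` (PC-1 score, Angstrom), `z` (Angstrom).
#' @export
project_graph <- function(g, s) {
  if (nrow(g$nodes) < 2L) stop("need at least 2 nodes to project")
  a <- s$atoms
  akey <- res_key(a$chain, a$resno, a$icode, a$comp)
  pos <- t(vapply(seq_len(nrow(g$nodes)), function(i) {
    k <- g$nodes$key[i]
    sel <- a[akey == k, ]
    ref <- if (g$nodes$type[i] == "water") sel[sel$name == "O", ]
           else sel[sel$name == "CA", ]
    if (nrow(ref) == 0L) ref <- sel[1L, ]
    as.numeric(ref[1L, c("x", "y", "z")])
  }, numeric(3)))
  pc <- prcomp(pos[, 1:2], center = TRUE, scale. = FALSE)
  x <- pc$x[, 1L]
  if (x[which.max(abs(x))] < 0) x <- -x
  data.frame(key = g$nodes$key, x = unname(x), z = pos[, 3],
             stringsAsFactors = FALSE)
}

#' Minimum side-chain heteroatom distance between two residues
#'
#' Minimum pairwise distance between chosen atoms of two residues, by default
#' their side-chain polar heteroatoms from the donor/acceptor table. This is
#' the quantity behind printed key-residue distances such as an Asp
#' carboxylate to Arg guanidinium separation.
#'
#' @param s A `pore_structure`.
#' @param resA,resB Author residue numbers, or residue keys
#'   (`chain:resno:COMP`).
#' @param atoms_a,atoms_b Optional character vectors of atom names for each
#'   residue; default: polar heteroatoms from [donor_acceptor_table()].
#' @return Minimum distance in Angstrom.
#' @export
min_sidechain_distance <- function(s, resA, resB, atoms_a = NULL,
                                   atoms_b = NULL) {
  ka <- .find_res(s, resA); kb <- .find_res(s, resB)
  if (ka == kb) stop("resA and resB are the same residue")
  xa <- .res_atoms(s, ka, atoms_a)
  xb <- .res_atoms(s, kb, atoms_b)
  if (nrow(xa) == 0L || nrow(xb) == 0L)
    stop("empty atom selection for ", if (nrow(xa) == 0L) ka else kb)
  A <- as.matrix(xa[, c("x", "y", "z")]); B <- as.matrix(xb[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

.find_res <- function(s, res) {
  rt <- residue_table(s)
  if (is.character(res) && res %in% rt$key) return(res)
  i <- which(rt$resno == as.integer(res) & !rt$hetero)
  if (!length(i)) i <- which(rt$resno == as.integer(res))
  if (!length(i)) stop("residue ", res, " not found in ", s$id)
  rt$key[i[1L]]
}

.res_atoms <- function(s, key, atom_names = NULL) {
  a <- s$atoms
  sel <- a[res_key(a$chain, a$resno, a$icode, a$comp) == key, ]
  if (is.null(atom_names)) {
    tab <- donor_acceptor_table()
    sel <- sel[paste(sel$comp, sel$name) %in% paste(tab$comp, tab$atom), ]
  } else {
    sel <- sel[sel$name %in% atom_names, ]
  }
  sel
}

#' Convert an H-bond graph to an igraph object
#'
#' @param g An `hbond_graph`.
#' @return An undirected `igraph` graph with node attribute `type` and edge
#'   attributes `distance`, `strength`.
#' @export
as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    d = data.frame(from = g$edges$key_a, to = g$edges$key_b,
                   distance = g$edges$distance, strength = g$edges$strength),
    directed = FALSE, vertices = g$nodes)
}

#' Write an H-bond graph as GraphML or JSON edge list
#'
#' @param g An `hbond_graph`.
#' @param path Output path.
#' @param format `"graphml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(g, path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(g), path, format = "graphml")
  } else {
    jsonlite::write_json(list(nodes = g$nodes, edges = g$edges,
                              cutoff = g$cutoff, water_policy = g$water_policy),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Plot an H-bond graph in the membrane projection
#'
#' Waters in red, amino-acid nodes in grey; strong edges thicker.
#'
#' @param x An `hbond_graph`.
#' @param s The `pore_structure` it was built from.
#' @param ... Passed to [graphics::plot.default()].
#' @return The projection data frame, invisibly.
#' @method plot hbond_graph
#' @export
plot.hbond_graph <- function(x, s, ...) {
  pr <- project_graph(x, s)
  xy <- pr[match(c(x$edges$key_a, x$edges$key_b), pr$key), ]
  n <- nrow(x$edges)
  graphics::plot(pr$x, pr$z, type = "n", xlab = "membrane plane (PC1, A)",
                 ylab = "membrane normal z (A)", ...)
  if (n) graphics::segments(xy$x[1:n], xy$z[1:n], xy$x[(n + 1):(2 * n)],
                            xy$z[(n + 1):(2 * n)], col = "steelblue",
                            lwd = ifelse(x$edges$strength == "strong", 2.5, 1))
  w <- x$nodes$type == "water"
  graphics::points(pr$x[!w], pr$z[!w], pch = 19, col = "grey40")
  graphics::points(pr$x[w], pr$z[w], pch = 19, col = "firebrick")
  invisible(pr)
}
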