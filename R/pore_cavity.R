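#' Van der Waals radii table
#'
#' Standard element radii (Bondi-type set) used when casting a structure onto
#' a grid. Unknown elements fall back to 1.7 Angstrom (carbon).
#'
#' @return Named numeric vector, Angstrom.
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
    NA. = 2.27, K = 2.75, MG = 1.73, CA = 2.31, ZN = 1.39, FE = 1.40)
}

.element_radius <- function(el) {
  r <- vdw_radii()
  key <- toupper(el)
  key[key == "NA"] <- "NA."
  out <- unname(r[key])
  out[is.na(out)] <- 1.70
  out
}

# zero-based voxel coordinates of linear indices
.vox_ijk <- function(idx, dims) {
  nxy <- dims[1L] * dims[2L]
  k <- (idx - 1L) %/% nxy
  r <- (idx - 1L) %% nxy
  cbind(i = r %% dims[1L], j = r %/% dims[1L], k = k)
}

.vox_center <- function(g, idx) {
  ijk <- .vox_ijk(idx, g$dim)
  sweep(ijk * g$spacing, 2, -g$origin)
}

.vox_index <- function(g, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  ijk <- round(sweep(xyz, 2, g$origin) / g$spacing)
  bad <- ijk < 0 | sweep(ijk, 2, g$dim - 1L) > 0
  idx <- as.integer(ijk[, 1] + g$dim[1L] * (ijk[, 2] + g$dim[2L] * ijk[, 3]) + 1)
  idx[rowSums(bad) > 0] <- NA_integer_
  idx
}

# 6-connected neighbors of a set of linear indices, clipped at the box
.neighbors6 <- function(idx, dims) {
  ijk <- .vox_ijk(idx, dims)
  nx <- dims[1L]; nxy <- dims[1L] * dims[2L]
  c(idx[ijk[, "i"] > 0L] - 1L,
    idx[ijk[, "i"] < dims[1L] - 1L] + 1L,
    idx[ijk[, "j"] > 0L] - nx,
    idx[ijk[, "j"] < dims[2L] - 1L] + nx,
    idx[ijk[, "k"] > 0L] - nxy,
    idx[ijk[, "k"] < dims[3L] - 1L] + nxy)
}

# label connected components of a mask (6-connectivity); one shared label
# array, so total work is linear in the masked voxel count
.label_components <- function(mask, dims) {
  labels <- integer(length(mask))
  remaining <- which(mask)
  lab <- 0L
  for (v in remaining) {
    if (labels[v] > 0L) next
    lab <- lab + 1L
    labels[v] <- lab
    frontier <- v
    while (length(frontier)) {
      nb <- unique(.neighbors6(frontier, dims))
      nb <- nb[mask[nb] & labels[nb] == 0L]
      labels[nb] <- lab
      frontier <- nb
    }
  }
  labels
}

# vectorized frontier flood fill over a logical mask (6-connectivity)
.flood6 <- function(mask, start, dims) {
  visited <- logical(length(mask))
  frontier <- unique(start[mask[start]])
  visited[frontier] <- TRUE
  while (length(frontier)) {
    nb <- unique(.neighbors6(frontier, dims))
    nb <- nb[mask[nb] & !visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  visited
}

#' Cast a structure onto a boolean occupancy grid
#'
#' Marks each voxel as protein if its center lies within the van der Waals
#' radius of any atom. The grid covers the structure's bounding box plus
#' `padding` Angstrom of free space on every side, so the box boundary is
#' always in bulk solvent.
#'
#' @param s A `pore_structure`.
#' @param spacing Grid spacing in Angstrom, default 0.5 (must be in
#'   (0.1, 2]).
#' @param padding Free margin around the structure, Angstrom.
#' @param radii Optional function or named vector overriding [vdw_radii()].
#' @return Object of class `cavity_grid`: list with `origin` (xyz of voxel
#'   (0,0,0) center), `spacing`, `dim` (3 integers), `occupied` (logical
#'   vector, length prod(dim), column-major), `atoms` (matrix x, y, z, r).
#' @export
rasterize <- function(s, spacing = 0.5, padding = 4, radii = NULL) {
  stopifnot(spacing > 0.1, spacing <= 2)
  a <- s$atoms
  if (nrow(a) == 0L) stop("empty structure")
  r <- if (is.null(radii)) .element_radius(a$element) else radii[a$element]
  atoms <- cbind(x = a$x, y = a$y, z = a$z, r = r)
  lo <- apply(atoms[, 1:3, drop = FALSE], 2, min) - padding
  hi <- apply(atoms[, 1:3, drop = FALSE], 2, max) + padding
  # snap the origin to the spacing lattice so voxel centers fall on round
  # coordinates (a grid translated by less than one voxel is identical)
  lo <- floor(lo / spacing) * spacing
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  g <- list(origin = as.numeric(lo), spacing = spacing, dim = dims,
            occupied = logical(prod(dims)), atoms = atoms)
  class(g) <- "cavity_grid"
  nx <- dims[1L]; nxy <- dims[1L] * dims[2L]
  for (n in seq_len(nrow(atoms))) {
    p <- atoms[n, 1:3]; ra <- atoms[n, 4]
    ijk0 <- pmax(ceiling((p - ra - lo) / spacing), 0)
    ijk1 <- pmin(floor((p + ra - lo) / spacing), dims - 1L)
    if (any(ijk0 > ijk1)) next
    gi <- ijk0[1]:ijk1[1]; gj <- ijk0[2]:ijk1[2]; gk <- ijk0[3]:ijk1[3]
    dx2 <- (lo[1] + gi * spacing - p[1])^2
    dy2 <- (lo[2] + gj * spacing - p[2])^2
    dz2 <- (lo[3] + gk * spacing - p[3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    hit <- which(d2 <= ra^2, arr.ind = TRUE)
    if (nrow(hit)) {
      idx <- (gi[hit[, 1]]) + nx * (gj[hit[, 2]]) + nxy * (gk[hit[, 3]]) + 1L
      g$occupied[idx] <- TRUE
    }
  }
  g
}

#' @export
print.cavity_grid <- function(x, ...) {
  cat(sprintf("cavity_grid: %d x %d x %d voxels at %.2f A (%d occupied, %d atoms)\n",
              x$dim[1], x$dim[2], x$dim[3], x$spacing, sum(x$occupied),
              nrow(x$atoms)))
  invisible(x)
}

#' Clearance field of a grid
#'
#' For every voxel, the distance from the voxel center to the nearest atom
#' surface (distance to atom center minus its van der Waals radius), capped
#' at `max_clearance`. Negative inside atoms. Computed exactly, per voxel,
#' over all atoms within reach of the cap.
#'
#' @param g A `cavity_grid`.
#' @param max_clearance Cap in Angstrom; clearances at or above the cap are
#'   reported as the cap (only clearances up to the largest probe of interest
#'   matter).
#' @return Numeric vector, length `prod(g$dim)`, Angstrom.
#' @export
clearance_field <- function(g, max_clearance = 6) {
  dims <- g$dim
  nx <- dims[1L]; nxy <- dims[1L] * dims[2L]
  lo <- g$origin; spacing <- g$spacing
  cf <- rep(max_clearance, prod(dims))
  for (n in seq_len(nrow(g$atoms))) {
    p <- g$atoms[n, 1:3]; ra <- g$atoms[n, 4]
    reach <- ra + max_clearance
    ijk0 <- pmax(ceiling((p - reach - lo) / spacing), 0)
    ijk1 <- pmin(floor((p + reach - lo) / spacing), dims - 1L)
    if (any(ijk0 > ijk1)) next
    gi <- ijk0[1]:ijk1[1]; gj <- ijk0[2]:ijk1[2]; gk <- ijk0[3]:ijk1[3]
    dx2 <- (lo[1] + gi * spacing - p[1])^2
    dy2 <- (lo[2] + gj * spacing - p[2])^2
    dz2 <- (lo[3] + gk * spacing - p[3])^2
    d <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+")) - ra
    idx <- as.integer(outer(outer(gi, nx * gj, "+"), nxy * gk, "+")) + 1L
    cf[idx] <- pmin(cf[idx], as.numeric(d))
  }
  cf
}

.boundary_idx <- function(dims) {
  ijk <- .vox_ijk(seq_len(prod(dims)), dims)
  which(ijk[, 1] == 0L | ijk[, 1] == dims[1L] - 1L |
        ijk[, 2] == 0L | ijk[, 2] == dims[2L] - 1L |
        ijk[, 3] == 0L | ijk[, 3] == dims[3L] - 1L)
}

# logical OR-dilation of `src` by a Euclidean ball of `radius` Angstrom
.dilate_ball <- function(src, g, radius) {
  dims <- g$dim
  rv <- floor(radius / g$spacing)
  if (rv < 1) return(src)
  offs <- as.matrix(expand.grid(i = -rv:rv, j = -rv:rv, k = -rv:rv))
  offs <- offs[sqrt(rowSums(offs^2)) * g$spacing <= radius, , drop = FALSE]
  ar <- array(src, dim = dims)
  out <- array(FALSE, dim = dims)
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  for (m in seq_len(nrow(offs))) {
    di <- offs[m, 1]; dj <- offs[m, 2]; dk <- offs[m, 3]
    ti <- (1 + max(di, 0)):(nx + min(di, 0))
    tj <- (1 + max(dj, 0)):(ny + min(dj, 0))
    tk <- (1 + max(dk, 0)):(nz + min(dk, 0))
    out[ti, tj, tk] <- out[ti, tj, tk] | ar[ti - di, tj - dj, tk - dk]
  }
  as.logical(out)
}

#' Detect interior cavities by probe-based flood fill
#'
#' Bulk solvent is the free region reachable from the box boundary by a
#' sphere of radius `probe`: the free space is eroded to voxels with
#' clearance at least `probe`, flood-filled from the boundary, and dilated
#' back by the probe radius within the free space. The remaining free
#' connected components are interior cavities, with volumes estimated as
#' voxel count times spacing cubed.
#'
#' @param g A `cavity_grid`.
#' @param probe Surface probe radius, Angstrom, default 1.4 (water).
#' @param clearance Optional precomputed [clearance_field()].
#' @param min_volume Minimum cavity volume, cubic Angstrom. Grid casting
#'   leaves tiny free crevices between atom spheres on the molecular surface
#'   that the probe cannot reach; components smaller than roughly one water
#'   volume (the default, 10 cubic Angstrom) are discarded as casting noise.
#' @return Object of class `cavity_set`: list with `labels` (integer vector,
#'   0 = not a cavity, i = cavity i, ordered by decreasing volume), `volumes`
#'   (numeric, cubic Angstrom), `bulk` (logical vector), `probe`, `grid`.
#' @export
find_cavities <- function(g, probe = 1.4, clearance = NULL, min_volume = 10) {
  if (is.null(clearance)) clearance <- clearance_field(g, max_clearance = probe + 2)
  free <- !g$occupied
  core <- free & clearance >= probe
  bulk_core <- .flood6(core, .boundary_idx(g$dim), g$dim)
  # dilate by the probe plus half a voxel diagonal: a probe sphere centered
  # anywhere inside a core voxel must reclaim the voxels it touches
  bulk <- .dilate_ball(bulk_core, g, probe + g$spacing * sqrt(3) / 2) & free
  interior <- free & !bulk
  raw <- .label_components(interior, g$dim)
  sizes <- tabulate(raw)
  keep <- which(sizes * g$spacing^3 >= min_volume)
  comp_min <- vapply(keep, function(l) which.max(raw == l), integer(1))
  ord <- keep[order(-sizes[keep], comp_min)]
  relabel <- integer(max(raw, 1L))
  relabel[ord] <- seq_along(ord)
  labels <- integer(length(raw))
  labels[raw > 0L] <- relabel[raw[raw > 0L]]
  structure(list(labels = labels,
                 volumes = sizes[ord] * g$spacing^3,
                 bulk = bulk, probe = probe, grid = g),
            class = "cavity_set")
}

#' @export
print.cavity_set <- function(x, ...) {
  cat(sprintf("cavity_set: %d cavities at probe %.2f A\n",
              length(x$volumes), x$probe))
  if (length(x$volumes))
    cat("  volumes (A^3):", paste(sprintf("%.1f", x$volumes), collapse = ", "),
        "\n")
  invisible(x)
}

#' Cavity voxels as a dummy-atom structure
#'
#' Emits one dummy oxygen pseudo-atom per cavity voxel center (the HOLLOW
#' convention), suitable for writing with [write_structure()] and visual
#' inspection of cavity shapes.
#'
#' @param cav A `cavity_set`.
#' @param which Cavity index (default all cavities).
#' @return A `pore_structure` with one `DUM` residue per voxel.
#' @export
cavity_dummy_atoms <- function(cav, which = NULL) {
  sel <- if (is.null(which)) cav$labels > 0L else cav$labels %in% which
  idx <- base::which(sel)
  xyz <- .vox_center(cav$grid, idx)
  n <- length(idx)
  atoms <- data.frame(
    serial = seq_len(n), name = "O", element = "O",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occ = 1, altloc = "", chain = "X", resno = seq_len(n), icode = "",
    comp = "DUM", hetero = TRUE, stringsAsFactors = FALSE)
  .new_structure("cavities", atoms)
}

#' Widest-bottleneck tunnel search from a seed point
#'
#' Finds the path from the seed to bulk solvent (the box boundary) that
#' maximises the minimum clearance along the path (bottleneck shortest path
#' over the clearance field, 6-connected grid). The maximal feasible
#' threshold is located by bisection over the sorted clearance values, with
#' a flood-fill connectivity check at each candidate; the reported path is
#' the breadth-first (shortest, deterministic) path at that threshold. A
#' tunnel admits the probe when the bottleneck radius is at least the probe
#' radius.
#'
#' @param g A `cavity_grid`.
#' @param seed xyz coordinates (Angstrom) of a point in free space.
#' @param probe Probe radius, Angstrom, default 0.9.
#' @param clearance Optional precomputed [clearance_field()]; its cap bounds
#'   the largest reportable bottleneck.
#' @return Object of class `pore_tunnel`: list with `found` (bottleneck at
#'   least probe), `reaches_bulk`, `bottleneck_radius` (Angstrom; `NA` if the
#'   seed's free region never reaches the boundary), `probe`, `seed`, `path`
#'   (matrix of voxel centers, seed to bulk; `NULL` if unreachable).
#' @export
tunnel_search <- function(g, seed, probe = 0.9, clearance = NULL) {
  if (is.null(clearance)) clearance <- clearance_field(g)
  vi <- .vox_index(g, seed)
  if (is.na(vi)) stop("seed lies outside the grid")
  if (g$occupied[vi]) stop("seed lies inside the protein")
  free <- !g$occupied
  boundary <- .boundary_idx(g$dim)
  # bisection over achievable thresholds for seed-to-boundary connectivity
  cand <- sort(unique(clearance[free & clearance <= clearance[vi]]))
  connected_at <- function(t) {
    vis <- .flood6(free & clearance >= t, boundary, g$dim)
    vis[vi]
  }
  if (!length(cand) || !connected_at(cand[1L])) {
    out <- list(found = FALSE, reaches_bulk = FALSE,
                bottleneck_radius = NA_real_, probe = probe,
                seed = seed, path = NULL)
    class(out) <- "pore_tunnel"
    return(out)
  }
  lo <- 1L; hi <- length(cand)
  while (lo < hi) {             # invariant: connected at cand[lo]
    mid <- lo + (hi - lo + 1L) %/% 2L
    if (connected_at(cand[mid])) lo <- mid else hi <- mid - 1L
  }
  thr <- cand[lo]
  # shortest path at the bottleneck threshold, BFS with parent tracking
  mask <- free & clearance >= thr
  parent <- integer(length(mask))
  visited <- logical(length(mask))
  frontier <- vi
  visited[vi] <- TRUE
  goal <- NA_integer_
  is_b <- logical(length(mask)); is_b[boundary] <- TRUE
  if (is_b[vi]) goal <- vi
  nx <- g$dim[1L]; nxy <- g$dim[1L] * g$dim[2L]
  while (is.na(goal) && length(frontier)) {
    ijk <- .vox_ijk(frontier, g$dim)
    moves <- list(list(ijk[, 1] > 0L, -1L),
                  list(ijk[, 1] < g$dim[1L] - 1L, 1L),
                  list(ijk[, 2] > 0L, -nx),
                  list(ijk[, 2] < g$dim[2L] - 1L, nx),
                  list(ijk[, 3] > 0L, -nxy),
                  list(ijk[, 3] < g$dim[3L] - 1L, nxy))
    src <- unlist(lapply(moves, function(m) frontier[m[[1]]]))
    nb_all <- unlist(lapply(moves, function(m) frontier[m[[1]]] + m[[2]]))
    ok <- mask[nb_all] & !visited[nb_all]
    nb <- nb_all[ok]; src <- src[ok]
    first <- !duplicated(nb)
    nb <- nb[first]; src <- src[first]
    visited[nb] <- TRUE
    parent[nb] <- src
    hit <- nb[is_b[nb]]
    if (length(hit)) goal <- hit[1L]
    frontier <- nb
  }
  path <- NULL
  if (!is.na(goal)) {
    p <- goal
    path_idx <- p
    while (p != vi) { p <- parent[p]; path_idx <- c(p, path_idx) }
    path <- .vox_center(g, path_idx)
    thr <- min(clearance[path_idx])
  }
  out <- list(found = thr >= probe, reaches_bulk = TRUE,
              bottleneck_radius = thr, probe = probe, seed = seed,
              path = path)
  class(out) <- "pore_tunnel"
  out
}

#' @export
print.pore_tunnel <- function(x, ...) {
  if (!x$reaches_bulk) {
    cat("pore_tunnel: seed region sealed off from bulk\n")
  } else {
    cat(sprintf("pore_tunnel: bottleneck %.2f A, probe %.2f A -> %s\n",
                x$bottleneck_radius, x$probe,
                if (x$found) "tunnel found" else "no tunnel at this probe"))
  }
  invisible(x)
}

#' Seed point for the ion-pathway tunnel comparison
#'
#' Midpoint between the retinal Schiff-base nitrogen (NZ of the retinal-
#' bound lysine) and the centroid of the C-alpha atoms of the extracellular
#' aromatic cluster, computed from coordinates with no manual input.
#'
#' @param s A `pore_structure`.
#' @param lysine Author residue number of the retinal-binding lysine.
#' @param cluster Author residue numbers of the aromatic cluster.
#' @return xyz vector, Angstrom.
#' @export
conduction_seed <- function(s, lysine = 233, cluster = c(102, 210, 221, 222)) {
  a <- s$atoms
  nz <- a[a$resno == lysine & a$name == "NZ" & a$comp %in% c("LYS", "LYR"), ]
  if (nrow(nz) == 0L) stop("Schiff-base lysine NZ not found at residue ", lysine)
  ca <- a[a$resno %in% cluster & a$name == "CA" & !a$hetero, ]
  if (nrow(ca) == 0L) stop("no aromatic-cluster C-alpha atoms found")
  (as.numeric(nz[1L, c("x", "y", "z")]) +
     colMeans(ca[, c("x", "y", "z")])) / 2
}

#' Write cavity volumes as TSV
#'
#' @param cav A `cavity_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cavities <- function(cav, path) {
  write.table(data.frame(cavity = seq_along(cav$volumes),
                         volume_A3 = cav$volumes),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
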