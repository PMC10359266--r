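# --- tiny explicit linear-congruential generator -----------------------------
# Fixture generation never touches R's global RNG stream: placement draws come
# from this named generator seeded in the FixtureSpec (Numerical Recipes
# constants, 32-bit).
.rng_new <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$state <- as.numeric(seed %% 2^31)
  e
}
.rng_unif <- function(rng, n = 1L, min = 0, max = 1) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    rng$state <- (1664525 * rng$state + 1013904223) %% 2^32
    out[i] <- rng$state / 2^32
  }
  min + out * (max - min)
}

.HELIX_RISE <- 1.5     # Angstrom per residue along the axis
.HELIX_TWIST <- 100    # degrees per residue
.HELIX_CA_R <- 2.3     # CA radius around the helix axis
.BG_COMPS <- c("ALA", "LEU", "VAL", "GLY", "ILE")  # apolar background

#' Specification of a synthetic test fixture
#'
#' Describes a small alpha-helical bundle with planted side-chain/water
#' hydrogen bonds at known distances and decoy entities, from which
#' [make_fixture()] builds a deterministic structure plus its truth record.
#'
#' @param seed Integer seed for the fixture's own (local) random generator.
#' @param n_helices Number of parallel helices in the bundle (even numbers
#'   allow balanced planted displacements in [make_paralog_pair()]).
#' @param residues_per_helix Residues per helix; 18 gives exactly five full
#'   helical turns so ring offsets cancel.
#' @param bundle_radius Distance of each helix axis from the bundle axis, A.
#' @param planted_hbonds Data frame with columns `res_a`, `res_b` (global
#'   residue indices), `distance` (A, in (2.4, 4.5)) and `water` (logical:
#'   `TRUE` plants a residue-water bond using `res_b` only as a direction).
#' @param decoys Named list of counts: `waters`, `ions`, `sterols`,
#'   `phospholipids` placed outside the bundle.
#' @param id Structure identifier.
#' @return Object of class `fixture_spec` (a validated list).
#' @export
fixture_spec <- function(seed = 1L, n_helices = 4L, residues_per_helix = 18L,
                         bundle_radius = 8, planted_hbonds = NULL,
                         decoys = list(), id = "fixture") {
  if (is.null(planted_hbonds)) {
    planted_hbonds <- data.frame(res_a = integer(), res_b = integer(),
                                 distance = numeric(), water = logical())
  }
  if (is.null(planted_hbonds$water)) planted_hbonds$water <- FALSE
  stopifnot(n_helices >= 2L, residues_per_helix >= 4L)
  if (nrow(planted_hbonds)) {
    nres <- n_helices * residues_per_helix
    if (any(planted_hbonds$res_a < 1 | planted_hbonds$res_a > nres |
            planted_hbonds$res_b < 1 | planted_hbonds$res_b > nres))
      stop("planted residue index out of range")
    if (any(planted_hbonds$distance <= 2.4 | planted_hbonds$distance >= 4.5))
      stop("planted distances must lie in (2.4, 4.5) Angstrom")
    used <- c(planted_hbonds$res_a,
              planted_hbonds$res_b[!planted_hbonds$water])
    if (anyDuplicated(used))
      stop("a residue may participate in at most one planted bond")
  }
  dec <- list(waters = 0L, ions = 0L, sterols = 0L, phospholipids = 0L)
  dec[names(decoys)] <- decoys
  structure(list(seed = as.integer(seed), n_helices = as.integer(n_helices),
                 residues_per_helix = as.integer(residues_per_helix),
                 bundle_radius = bundle_radius,
                 planted_hbonds = planted_hbonds, decoys = dec, id = id),
            class = "fixture_spec")
}

#' Global residue index of a helix rung
#'
#' @param spec A `fixture_spec`.
#' @param helix Helix number (1-based).
#' @param rung Residue position within the helix (1-based).
#' @return Integer residue number.
#' @export
fixture_residue <- function(spec, helix, rung) {
  stopifnot(helix >= 1, helix <= spec$n_helices,
            rung >= 1, rung <= spec$residues_per_helix)
  as.integer((helix - 1L) * spec$residues_per_helix + rung)
}

# CA coordinates of the full bundle; one row per residue, bundle axis on z
.bundle_ca <- function(spec) {
  nres <- spec$n_helices * spec$residues_per_helix
  out <- matrix(0, nres, 3)
  for (h in seq_len(spec$n_helices)) {
    ang0 <- 2 * pi * (h - 1) / spec$n_helices
    cx <- spec$bundle_radius * cos(ang0)
    cy <- spec$bundle_radius * sin(ang0)
    for (r in seq_len(spec$residues_per_helix)) {
      i <- (h - 1L) * spec$residues_per_helix + r
      a <- (ang0 * 180 / pi + (r - 1) * .HELIX_TWIST) * pi / 180
      out[i, ] <- c(cx + .HELIX_CA_R * cos(a), cy + .HELIX_CA_R * sin(a),
                    (r - 1) * .HELIX_RISE)
    }
  }
  out
}

#' Build a synthetic fixture structure with planted truth
#'
#' Constructs an ideal-geometry parallel helix bundle (C-alpha trace with
#' minimal side chains: only atoms the donor/acceptor table needs), places
#' each planted hydrogen bond so its heteroatom distance matches the target
#' exactly, adds decoy entities well away from the bundle, and verifies that
#' no unplanted polar-atom pair falls inside the detection window (such a
#' clash is an error naming the offending pair). Identical specs yield
#' byte-identical PDB output.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional output directory: writes `<id>.pdb` and
#'   `<id>_truth.json`.
#' @return List with `structure` (a `pore_structure`), `truth` (planted bonds,
#'   expected graph counts, entity counts), and, if `dir` was given, `path`
#'   and `truth_path`.
#' @export
make_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  rng <- .rng_new(spec$seed)
  nres <- spec$n_helices * spec$residues_per_helix
  comps <- rep_len(.BG_COMPS, nres)
  ca <- .bundle_ca(spec)

  rows <- list()
  add_atom <- function(name, element, xyz, resno, comp, hetero = FALSE,
                       chain = "A") {
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = 0L, name = name, element = element,
      x = xyz[1], y = xyz[2], z = xyz[3], occ = 1, altloc = "",
      chain = chain, resno = as.integer(resno), icode = "", comp = comp,
      hetero = hetero, stringsAsFactors = FALSE)
  }

  ph <- spec$planted_hbonds
  planted_atoms <- list()  # expected polar-pair exceptions
  nwater <- 0L
  for (i in seq_len(nrow(ph))) {
    a <- ph$res_a[i]; b <- ph$res_b[i]; d <- ph$distance[i]
    u <- ca[b, ] - ca[a, ]
    nu <- sqrt(sum(u^2))
    if (nu < 1e-6) stop("planted pair ", a, "-", b, " is degenerate")
    u <- u / nu
    comps[a] <- "SER"
    if (ph$water[i]) {
      og <- ca[a, ] + 1.8 * u
      w <- og + d * u
      nwater <- nwater + 1L
      wres <- 1000L + nwater
      planted_atoms[[i]] <- list(a = a, b = paste0("W", wres), og = og, w = w)
    } else {
      comps[b] <- "SER"
      m <- (ca[a, ] + ca[b, ]) / 2
      planted_atoms[[i]] <- list(a = a, b = b,
                                 og = m - u * d / 2, og_b = m + u * d / 2)
    }
  }

  for (r in seq_len(nres)) add_atom("CA", "C", ca[r, ], r, comps[r])
  nwater <- 0L
  for (i in seq_len(nrow(ph))) {
    pa <- planted_atoms[[i]]
    add_atom("OG", "O", pa$og, pa$a, "SER")
    if (ph$water[i]) {
      nwater <- nwater + 1L
      add_atom("O", "O", pa$w, 1000L + nwater, "HOH", hetero = TRUE,
               chain = "W")
    } else {
      add_atom("OG", "O", pa$og_b, pa$b, "SER")
    }
  }

  # decoys on a wide ring outside the bundle, rejection-placed for separation
  zr <- range(ca[, 3])
  placed <- matrix(numeric(0), 0, 3)
  place_decoy <- function() {
    for (try in 1:200) {
      ang <- .rng_unif(rng, 1, 0, 2 * pi)
      rad <- spec$bundle_radius + .rng_unif(rng, 1, 10, 16)
      z <- .rng_unif(rng, 1, zr[1], zr[2])
      p <- c(rad * cos(ang), rad * sin(ang), z)
      if (nrow(placed) == 0 ||
          min(sqrt(rowSums(sweep(placed, 2, p)^2))) > 6) {
        placed <<- rbind(placed, p)
        return(p)
      }
    }
    stop("could not place decoy entity without clashes")
  }
  dec <- spec$decoys
  hres <- 2000L
  for (i in seq_len(dec$waters)) {
    hres <- hres + 1L
    add_atom("O", "O", place_decoy(), hres, "HOH", hetero = TRUE, chain = "W")
  }
  for (i in seq_len(dec$ions)) {
    hres <- hres + 1L
    add_atom("NA", "NA", place_decoy(), hres, "NA", hetero = TRUE, chain = "I")
  }
  for (i in seq_len(dec$sterols)) {
    hres <- hres + 1L
    p <- place_decoy()
    for (k in 0:2) add_atom(paste0("C", k + 1), "C", p + c(0, 0, k * 1.5),
                            hres, "CLR", hetero = TRUE, chain = "L")
  }
  for (i in seq_len(dec$phospholipids)) {
    hres <- hres + 1L
    p <- place_decoy()
    add_atom("P", "P", p, hres, "PEE", hetero = TRUE, chain = "L")
    for (k in 1:2) add_atom(paste0("C", k), "C", p + c(0, 0, k * 1.5),
                            hres, "PEE", hetero = TRUE, chain = "L")
  }

  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  s <- .new_structure(spec$id, atoms, assembly = c(A = 1L))
  .check_unplanted(s, ph, window = 4.2)

  truth <- list(
    planted = ph,
    n_bonds = nrow(ph),
    n_water_mediated = sum(ph$water),
    n_sidechain_sidechain = sum(!ph$water),
    n_strong = sum(ph$distance <= 3.5),
    entities = c(water = dec$waters + sum(ph$water), monatomic_ion = dec$ions,
                 sterol = dec$sterols, phospholipid = dec$phospholipids))
  out <- list(structure = s, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$path <- write_structure(s, file.path(dir, paste0(spec$id, ".pdb")))
    out$truth_path <- file.path(dir, paste0(spec$id, "_truth.json"))
    jsonlite::write_json(truth, out$truth_path, auto_unbox = TRUE, digits = NA)
  }
  out
}

# every polar-atom pair not planted must sit outside the detection window
.check_unplanted <- function(s, ph, window = 4.2) {
  hb <- detect_hbonds(s, cutoff = min(window, 5), method = "all_pairs")
  rt <- residue_table(s)
  key_of <- function(res) {
    if (grepl("^W", res)) {
      wres <- as.integer(sub("^W", "", res))
      rt$key[rt$resno == wres & rt$comp == "HOH"]
    } else rt$key[rt$resno == as.integer(res) & !rt$hetero]
  }
  expected <- character()
  nwater <- 0L
  for (i in seq_len(nrow(ph))) {
    ka <- key_of(ph$res_a[i])
    kb <- if (ph$water[i]) { nwater <- nwater + 1L; key_of(paste0("W", 1000L + nwater)) }
          else key_of(ph$res_b[i])
    expected <- c(expected, paste(sort(c(ka, kb)), collapse = "~"))
  }
  got <- paste(pmin(hb$key_a, hb$key_b), pmax(hb$key_a, hb$key_b), sep = "~")
  stray <- setdiff(got, expected)
  if (length(stray))
    stop("infeasible placement: unplanted polar contact ", stray[1L])
  invisible(TRUE)
}

#' Build a paralog pair of fixtures with planted differences
#'
#' Structure A is [make_fixture()] of the spec. Structure B differs only by
#' the listed residue substitutions (side chains rebuilt minimally) and an
#' optional planted helix displacement. The displacement shifts the helix
#' containing the named residue radially by the stated amount and the
#' diametrically opposite helix by the same amount in the opposite direction,
#' so the whole-bundle C-alpha superposition frame stays exactly at identity
#' and the planted shift is recovered at face value.
#'
#' @param spec A [fixture_spec()] (needs an even `n_helices` when a
#'   displacement is planted).
#' @param mutations Optional data frame with columns `resno`, `to` (3-letter
#'   component code). Mutating a residue that carries a planted bond, or one
#'   that does not exist, is an error.
#' @param displacement Optional `list(resno =, dist =)`: rigid radial shift,
#'   Angstrom, of the helix containing `resno`.
#' @param dir Optional output directory (writes both PDBs and the truth JSON).
#' @return List with `A`, `B` (`pore_structure`), `truth` (mutations,
#'   displacement, expected identity percentage).
#' @export
make_paralog_pair <- function(spec, mutations = NULL, displacement = NULL,
                              dir = NULL) {
  fa <- make_fixture(spec)
  A <- fa$structure
  atoms <- A$atoms
  nres <- spec$n_helices * spec$residues_per_helix

  if (!is.null(mutations) && nrow(mutations)) {
    ph <- spec$planted_hbonds
    protected <- c(ph$res_a, ph$res_b[!ph$water])
    for (i in seq_len(nrow(mutations))) {
      rn <- mutations$resno[i]; to <- toupper(mutations$to[i])
      if (rn < 1 || rn > nres) stop("mutation at unmodeled residue ", rn)
      if (rn %in% protected)
        stop("cannot mutate residue ", rn, ": it carries a planted bond")
      sel <- atoms$resno == rn & !atoms$hetero
      atoms <- atoms[!(sel & atoms$name != "CA"), ]
      atoms$comp[atoms$resno == rn & !atoms$hetero] <- to
      tab <- donor_acceptor_table()
      pol <- tab[tab$comp == to, ]
      if (nrow(pol)) {
        # one representative polar atom, radially outward from the bundle axis
        cai <- which(atoms$resno == rn & !atoms$hetero & atoms$name == "CA")
        p <- as.numeric(atoms[cai, c("x", "y", "z")])
        u <- c(p[1], p[2], 0); u <- u / sqrt(sum(u^2))
        q <- p + 1.5 * u
        atoms <- rbind(atoms, within(atoms[cai, ], {
          name <- pol$atom[1L]; element <- substr(pol$atom[1L], 1, 1)
          x <- q[1]; y <- q[2]; z <- q[3]
        }))
      }
    }
  }

  disp_truth <- NULL
  if (!is.null(displacement)) {
    if (spec$n_helices %% 2L != 0L)
      stop("balanced displacement needs an even number of helices")
    rn <- displacement$resno; d <- displacement$dist
    if (rn < 1 || rn > nres) stop("displacement at unmodeled residue ", rn)
    h <- (rn - 1L) %/% spec$residues_per_helix + 1L
    h_op <- (h - 1L + spec$n_helices / 2L) %% spec$n_helices + 1L
    shift_helix <- function(atoms, hh, vec) {
      rr <- ((hh - 1L) * spec$residues_per_helix + 1L):(hh * spec$residues_per_helix)
      sel <- atoms$resno %in% rr & !atoms$hetero
      atoms$x[sel] <- atoms$x[sel] + vec[1]
      atoms$y[sel] <- atoms$y[sel] + vec[2]
      atoms
    }
    ang0 <- 2 * pi * (h - 1) / spec$n_helices
    u <- c(cos(ang0), sin(ang0))
    atoms <- shift_helix(atoms, h, d * u)
    atoms <- shift_helix(atoms, h_op, -d * u)
    disp_truth <- list(resno = rn, dist = d, helix = h, opposite_helix = h_op)
  }

  atoms$serial <- seq_len(nrow(atoms))
  B <- .new_structure(paste0(spec$id, "_B"), atoms, assembly = A$assembly)
  n_mut <- if (is.null(mutations)) 0L else nrow(mutations)
  truth <- c(fa$truth, list(
    mutations = mutations, displacement = disp_truth,
    identity_pct = 100 * (nres - n_mut) / nres))
  out <- list(A = A, B = B, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$path_A <- write_structure(A, file.path(dir, paste0(spec$id, "_A.pdb")))
    out$path_B <- write_structure(B, file.path(dir, paste0(spec$id, "_B.pdb")))
    out$truth_path <- file.path(dir, paste0(spec$id, "_pair_truth.json"))
    jsonlite::write_json(truth, out$truth_path, auto_unbox = TRUE, digits = NA)
  }
  out
}

# points roughly evenly spread on a unit sphere (golden-spiral lattice)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Hollow-shell structure with a known interior cavity
#'
#' Carbon pseudo-atoms on a sphere whose interior free region has the stated
#' radius (atom centers sit at `radius` + the carbon van der Waals radius).
#' With a pinhole, shell atoms near the +z pole are removed and replaced by a
#' ring whose aperture has the stated free radius, so a probe larger than the
#' pinhole cannot enter but a smaller one can.
#'
#' @param radius Interior cavity radius, Angstrom.
#' @param pinhole_radius Optional free radius of a pole aperture, Angstrom.
#' @param atom_spacing Approximate spacing of shell atoms, Angstrom.
#' @return A `pore_structure` of `SHL` pseudo-residues.
#' @export
make_shell_fixture <- function(radius = 6, pinhole_radius = NULL,
                               atom_spacing = 1.0) {
  rc <- 1.70                      # carbon vdW radius
  rs <- radius + rc               # shell of atom centers
  n <- max(20L, ceiling(4 * pi * rs^2 / atom_spacing^2))
  pts <- .sphere_points(n) * rs
  if (!is.null(pinhole_radius)) {
    ap <- pinhole_radius + rc     # aperture ring radius (atom centers)
    lat <- sqrt(pts[, 1]^2 + pts[, 2]^2)
    drop <- pts[, 3] > 0 & lat < ap + atom_spacing
    pts <- pts[!drop, , drop = FALSE]
    nring <- max(8L, ceiling(2 * pi * ap / (atom_spacing / 2)))
    th <- 2 * pi * (seq_len(nring) - 1) / nring
    zr <- sqrt(max(rs^2 - ap^2, 0))
    ring <- cbind(ap * cos(th), ap * sin(th), zr)
    # a short collar so the aperture is a channel, not a knife edge
    collar <- rbind(ring, sweep(ring, 2, c(0, 0, 1.0), "+"))
    pts <- rbind(pts, collar)
  }
  n <- nrow(pts)
  atoms <- data.frame(
    serial = seq_len(n), name = "C", element = "C",
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    occ = 1, altloc = "", chain = "X", resno = seq_len(n), icode = "",
    comp = "SHL", hetero = TRUE, stringsAsFactors = FALSE)
  .new_structure("shell", atoms)
}

#' Slab with an open cylindrical channel
#'
#' A dense atom slab pierced by a straight channel of known free radius along
#' z, for tunnel-search calibration: the bottleneck radius of a path through
#' the channel equals the channel radius up to grid resolution.
#'
#' @param radius Free channel radius, Angstrom.
#' @param thickness Slab thickness, Angstrom.
#' @param halfwidth Lateral half-extent of the slab, Angstrom.
#' @param lattice Atom lattice spacing, Angstrom.
#' @return A `pore_structure` of `SHL` pseudo-atoms.
#' @export
make_channel_slab <- function(radius = 2, thickness = 8, halfwidth = 10,
                              lattice = 1.0) {
  rc <- 1.70
  gx <- seq(-halfwidth, halfwidth, by = lattice)
  gz <- seq(0, thickness, by = lattice)
  pts <- as.matrix(expand.grid(x = gx, y = gx, z = gz))
  lat <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  pts <- pts[lat >= radius + rc, , drop = FALSE]
  n <- nrow(pts)
  atoms <- data.frame(
    serial = seq_len(n), name = "C", element = "C",
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    occ = 1, altloc = "", chain = "X", resno = seq_len(n), icode = "",
    comp = "SHL", hetero = TRUE, stringsAsFactors = FALSE)
  .new_structure("slab", atoms)
}
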