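test_that("a single atom occupies a sphere of voxels within 10% of its volume", {
  atoms <- data.frame(serial = 1L, name = "C", element = "C", x = 0, y = 0,
                      z = 0, occ = 1, altloc = "", chain = "A", resno = 1L,
                      icode = "", comp = "SHL", hetero = TRUE,
                      stringsAsFactors = FALSE)
  s <- poregraph:::.new_structure("one", atoms)
  g <- rasterize(s, spacing = 0.5, padding = 3)
  vol <- sum(g$occupied) * 0.5^3
  expect_equal(vol, 4 / 3 * pi * 1.7^3, tolerance = 0.1)
  # padding region stays free
  expect_false(any(g$occupied[poregraph:::.boundary_idx(g$dim)]))
})

test_that("occupancy of overlapping atoms is the per-voxel union", {
  atoms <- data.frame(serial = 1:2, name = "C", element = "C",
                      x = c(0, 1.2), y = 0, z = 0, occ = 1, altloc = "",
                      chain = "A", resno = 1:2, icode = "", comp = "SHL",
                      hetero = TRUE, stringsAsFactors = FALSE)
  s <- poregraph:::.new_structure("two", atoms)
  g <- rasterize(s, spacing = 0.5, padding = 2)
  centers <- poregraph:::.vox_center(g, seq_len(prod(g$dim)))
  oracle <- rowSums(sweep(centers, 2, c(0, 0, 0))^2) <= 1.7^2 |
            rowSums(sweep(centers, 2, c(1.2, 0, 0))^2) <= 1.7^2
  expect_equal(g$occupied, oracle)
})

test_that("clearance field equals per-voxel nearest-atom brute force", {
  s <- make_shell_fixture(radius = 3, atom_spacing = 1.5)
  g <- rasterize(s, spacing = 1.0, padding = 2)
  cf <- clearance_field(g, max_clearance = 4)
  centers <- poregraph:::.vox_center(g, seq_len(prod(g$dim)))
  a <- g$atoms
  brute <- vapply(seq_len(nrow(centers)), function(i) {
    min(sqrt(colSums((t(a[, 1:3]) - centers[i, ])^2)) - a[, 4])
  }, numeric(1))
  expect_equal(cf, pmin(brute, 4), tolerance = 1e-9)
})

test_that("a solid slab has no cavities and a hollow shell exactly one", {
  slab <- make_channel_slab(radius = -2, thickness = 5, halfwidth = 6)
  g <- rasterize(slab, spacing = 0.5)
  expect_equal(length(find_cavities(g)$volumes), 0L)

  sh <- make_shell_fixture(radius = 6)
  gs <- rasterize(sh, spacing = 0.5)
  cav <- find_cavities(gs)
  expect_equal(length(cav$volumes), 1L)
  expect_equal(cav$volumes[1], 4 / 3 * pi * 6^3, tolerance = 0.1)
})

test_that("cavity volume converges when the grid spacing halves", {
  sh <- make_shell_fixture(radius = 6)
  v1 <- find_cavities(rasterize(sh, spacing = 0.5))$volumes[1]
  v2 <- find_cavities(rasterize(sh, spacing = 0.25))$volumes[1]
  expect_lt(abs(v2 - v1) / v1, 0.05)
})

test_that("a pinhole smaller than the probe keeps the cavity sealed", {
  sh <- make_shell_fixture(radius = 6, pinhole_radius = 1.0)
  g <- rasterize(sh, spacing = 0.5)
  cf <- clearance_field(g)
  big <- find_cavities(g, probe = 1.4, clearance = cf)
  expect_gte(length(big$volumes), 1L)
  expect_equal(max(big$volumes), 4 / 3 * pi * 6^3, tolerance = 0.1)
  small <- find_cavities(g, probe = 0.9, clearance = cf)
  # probe 0.9 passes the 1.0 A pinhole: the interior joins bulk solvent
  expect_true(length(small$volumes) == 0L ||
              max(small$volumes) < 0.5 * max(big$volumes))
})

test_that("tunnel bottleneck matches a constructed channel radius", {
  sl <- make_channel_slab(radius = 2)
  g <- rasterize(sl, spacing = 0.5)
  tun <- tunnel_search(g, c(0, 0, 4), probe = 0.9)
  expect_true(tun$found)
  expect_equal(tun$bottleneck_radius, 2, tolerance = 0.5)
  expect_true(all(abs(diff(tun$path[, 1])) <= 0.5 + 1e-9))  # grid-neighbor path
})

test_that("tunnel detection is monotone in the probe radius", {
  sh <- make_shell_fixture(radius = 6, pinhole_radius = 1.0)
  g <- rasterize(sh, spacing = 0.5)
  cf <- clearance_field(g)
  probes <- c(0.5, 0.7, 0.9, 1.1, 1.4)
  found <- vapply(probes, function(p)
    tunnel_search(g, c(0, 0, 0), probe = p, clearance = cf)$found, logical(1))
  expect_false(is.unsorted(rev(found)))      # once lost, never regained
  expect_true(found[3])                      # 0.9 passes the 1.0 A pinhole
  expect_false(found[5])                     # 1.4 does not
})

test_that("a sealed cavity yields no tunnel and bad seeds error", {
  sh <- make_shell_fixture(radius = 6)
  g <- rasterize(sh, spacing = 0.5)
  tun <- tunnel_search(g, c(0, 0, 0), probe = 0.9)
  expect_false(tun$found)
  expect_false(tun$reaches_bulk)
  expect_error(tunnel_search(g, c(0, 0, 7.7), probe = 0.9), "inside the protein")
  expect_error(tunnel_search(g, c(1e4, 0, 0), probe = 0.9), "outside the grid")
})

test_that("dummy-atom output has exactly one atom per cavity voxel", {
  sh <- make_shell_fixture(radius = 4)
  g <- rasterize(sh, spacing = 0.5)
  cav <- find_cavities(g)
  dum <- cavity_dummy_atoms(cav, which = 1)
  expect_equal(nrow(dum$atoms), sum(cav$labels == 1L))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(dum, f)
  reparsed <- parse_structure(f)
  expect_equal(nrow(reparsed$atoms), sum(cav$labels == 1L))
})
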