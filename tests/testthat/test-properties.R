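# Electrostatic, hydrophobicity and concaveness channels, and patch-channel
# encoding.

test_that("screened Coulomb potential behaves like a monopole", {
  st <- atom_structure(c(0, 0, 0), resname = "LYS", name = "NZ",
                       element = "N")
  pts <- cbind(seq(2, 10, 0.5), 0, 0)
  v <- electrostatic_potential(st, pts)
  expect_true(all(v > 0))
  expect_true(all(diff(v) < 0))            # decreasing with distance
  # epsilon(r) = 4r: one +1 charge gives 1 / (4 r^2)
  expect_equal(v, 1 / (4 * pts[, 1]^2), tolerance = 1e-12)
})

test_that("potential is antisymmetric for a mirror charge pair", {
  st <- structure(list(protein = data.frame(
    name = c("NZ", "OD1"), element = c("N", "O"),
    resname = c("LYS", "ASP"), resseq = 1:2, icode = " ", chain = "A",
    x = c(0, 0), y = c(0, 0), z = c(2, -2), stringsAsFactors = FALSE),
    ligands = list()), class = "complex_structure")
  q <- c(1, -1)
  pts <- matrix(rnorm(60), ncol = 3)
  mirrored <- pts
  mirrored[, 3] <- -mirrored[, 3]
  v1 <- electrostatic_potential(st, pts, charges = q)
  v2 <- electrostatic_potential(st, mirrored, charges = q)
  expect_equal(v1, -v2, tolerance = 1e-9)
})

test_that("three-atom potential equals the hand-summed Coulomb terms", {
  xyz <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0))
  st <- atom_structure(xyz)
  q <- c(0.4, -0.4, 1.0)
  pts <- rbind(c(1, 1, 1), c(-2, 0.5, 3))
  v <- electrostatic_potential(st, pts, charges = q)
  oracle <- sapply(seq_len(nrow(pts)), function(i) {
    s <- 0
    for (a in 1:3) {
      r2 <- sum((pts[i, ] - xyz[a, ])^2)
      s <- s + q[a] / (4 * max(r2, 0.25))
    }
    s
  })
  expect_equal(v, oracle, tolerance = 1e-12)
})

test_that("charge table covers the ionizable side chains", {
  st <- structure(list(protein = data.frame(
    name = c("N", "O", "OD1", "NZ", "NH1", "CB", "XX"),
    element = c("N", "O", "O", "N", "N", "C", "C"),
    resname = c("ALA", "ALA", "ASP", "LYS", "ARG", "ALA", "FOO"),
    resseq = 1:7, icode = " ", chain = "A",
    x = 1:7, y = 0, z = 0, stringsAsFactors = FALSE),
    ligands = list()), class = "complex_structure")
  expect_warning(q <- atom_charges(st), "FOO")
  expect_equal(unname(q), c(0.4, -0.4, -0.5, 1.0, 0.5, 0, 0))
})

test_that("hydrophobicity carries the nearest residue's index", {
  st <- structure(list(protein = data.frame(
    name = c("CA", "CA"), element = c("C", "C"),
    resname = c("ILE", "ARG"), resseq = 1:2, icode = " ", chain = "A",
    x = c(0, 10), y = 0, z = 0, stringsAsFactors = FALSE),
    ligands = list()), class = "complex_structure")
  pts <- cbind(c(1, 4, 6, 9), 0, 0)
  h <- hydrophobicity(st, pts)
  # brute-force nearest-residue scan: ILE = 4.5, ARG = -4.5
  expect_equal(h, c(4.5, 4.5, -4.5, -4.5))

  # all-glycine protein: constant channel
  stg <- atom_structure(rbind(c(0, 0, 0), c(5, 0, 0)), resname = "GLY")
  expect_equal(hydrophobicity(stg, pts), rep(-0.4, 4))

  # nonstandard residues warn and map to zero
  stx <- atom_structure(c(0, 0, 0), resname = "XXX")
  expect_warning(hx <- hydrophobicity(stx, pts), "XXX")
  expect_equal(hx, rep(0, 4))
})

test_that("concaveness approaches 1/2 on a flat slab and is lower in a pit", {
  slab <- atom_structure(as.matrix(expand.grid(x = seq(-10, 10, 1.5),
                                               y = seq(-10, 10, 1.5),
                                               z = c(0, -1.5))))
  surf <- compute_surface(slab, spacing = 0.8)
  # pick central top-face points
  top <- which(surf$points[, 3] > 1 & abs(surf$points[, 1]) < 3 &
                 abs(surf$points[, 2]) < 3)
  v <- concaveness(surf, top[1:5], n_rays = 128L)
  expect_true(all(abs(v - 0.5) < 0.12))

  # deep pocket point (cavity floor) scores below the slab value
  spec <- fixture_spec(seed = 3L, noise_sigma = 0)
  cx <- make_synthetic_complex(spec, 1L, 1L)
  psurf <- compute_surface(cx, spacing = 0.8)
  pidx <- extract_pocket(psurf, cx$ligands[[1]], 4.5)
  deep <- pidx[which.min(psurf$points[pidx, 3])]
  vd <- concaveness(psurf, deep, n_rays = 128L)
  expect_lt(vd, min(v))

  expect_error(concaveness(surf, top[1], n_rays = 16L), "at least 32")
})

test_that("concaveness equals an independent ray-march oracle", {
  slab <- atom_structure(as.matrix(expand.grid(x = seq(-6, 6, 1.5),
                                               y = seq(-6, 6, 1.5),
                                               z = 0)))
  surf <- compute_surface(slab, spacing = 0.8)
  pts_idx <- c(10L, 25L, 40L)
  got <- concaveness(surf, pts_idx, n_rays = 64L, offset = 1.0)

  # naive reimplementation: plain loops over rays and steps
  occ <- surf$occupancy$phi < 0
  ax <- surf$occupancy$axes
  sp <- surf$occupancy$spacing
  nv <- dim(occ)
  lo <- sapply(ax, `[`, 1)
  hi <- sapply(ax, function(a) a[length(a)])
  dirs <- patchsurf:::.sphere_directions(64L)
  tsteps <- seq(sp, sqrt(sum((hi - lo)^2)), by = sp)
  for (k in seq_along(pts_idx)) {
    p0 <- surf$points[pts_idx[k], ] + 1.0 * surf$normals[pts_idx[k], ]
    c0 <- round((p0 - lo) / sp) + 1
    escaped <- 0L
    for (r in 1:64) {
      blocked <- FALSE
      for (t in tsteps) {
        ijk <- c0 + round(dirs[r, ] * t / sp)
        if (any(ijk < 1) || any(ijk > nv)) next
        if (occ[ijk[1], ijk[2], ijk[3]]) { blocked <- TRUE; break }
      }
      if (!blocked) escaped <- escaped + 1L
    }
    expect_identical(got[k], escaped / 64)
  }
})

test_that("patch channels encode to the contracted lengths", {
  set.seed(31)
  pts <- matrix(rnorm(120, sd = 2), ncol = 3)
  vals <- rnorm(40)

  shape <- encode_patch_channel(pts, rep(1, 40), signed = FALSE, dim = 32)
  expect_length(shape, 72L)
  ele <- encode_patch_channel(pts, vals, signed = TRUE, dim = 32)
  expect_length(ele, 144L)

  # strictly positive signed channel: empty negative half
  pos <- encode_patch_channel(pts, abs(vals) + 0.1, signed = TRUE, dim = 32)
  expect_true(all(pos[73:144] == 0))
  expect_gt(sum(pos[1:72]), 0)

  # negating the channel swaps the two halves exactly
  neg <- encode_patch_channel(pts, -(abs(vals) + 0.1), signed = TRUE,
                              dim = 32)
  expect_identical(neg[73:144], pos[1:72])
  expect_identical(neg[1:72], pos[73:144])
})

test_that("per-point value import matches by nearest neighbor", {
  surf <- list(points = rbind(c(0, 0, 0), c(5, 0, 0), c(90, 0, 0)))
  path <- tempfile()
  writeLines(c("0.1 0 0 2.5", "5.2 0.1 0 -1.0"), path)
  v <- import_point_values(surf, path, tolerance = 0.5)
  expect_equal(v[1:2], c(2.5, -1.0))
  expect_true(is.na(v[3]))
  unlink(path)
})
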