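# Independent oracles and small builders shared across the test files.
# Every oracle here is a deliberately naive implementation kept separate
# from the code paths it checks.

unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n > 0) v / n else v
}

# rotation matrix about an arbitrary axis (Rodrigues)
rotation_matrix <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
}

# brute-force Zernike moment: direct voxel-by-voxel numerical integration
# using the spherical-coordinate evaluation route (independent of the
# geometric-moment pathway)
brute_force_moments <- function(grid, order) {
  d <- grid$dim
  ax <- (seq_len(d) - (d + 1) / 2) * (2 / d)
  pts <- as.matrix(expand.grid(ax, ax, ax))
  f <- as.vector(grid$values)
  dV <- (2 / d)^3
  rows <- list()
  for (n in 0:order) for (l in seq(n %% 2, n, by = 2)) for (m in -l:l) {
    z <- patchsurf:::.zernike_eval_spherical(n, l, m, pts)
    rows[[length(rows) + 1L]] <- data.frame(
      n = n, l = l, m = m, omega = 3 / (4 * pi) * sum(f * Conj(z)) * dV)
  }
  do.call(rbind, rows)
}

# minimum-cost assignment by explicit enumeration of all permutations
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  best <- NULL
  best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), p)])
    if (cc < best_cost) {
      best_cost <- cc
      best <- p
    }
  }
  list(assignment = best, cost = best_cost)
}

# count-and-divide enrichment factor
brute_force_ef <- function(ranking, correct, x) {
  n_top <- ceiling(x / 100 * length(ranking))
  hits <- sum(ranking[seq_len(n_top)] %in% correct)
  total <- sum(ranking %in% correct)
  (hits / n_top) / (total / length(ranking))
}

# toy pocket whose patches carry prescribed descriptors (for matching and
# retrieval tests that do not need the geometry pipeline)
toy_patch <- function(shape, hyd = NULL, ele = NULL, conc = NULL,
                      weights = c(shape = 0.25, hyd = 0.25, ele = 0.25,
                                  conc = 0.25),
                      anchor_name = "C1", anchor_atom = 1L) {
  len <- length(shape)
  if (is.null(hyd)) hyd <- rep(0, 2 * len)
  if (is.null(ele)) ele <- rep(0, 2 * len)
  if (is.null(conc)) conc <- rep(0, len)
  structure(list(anchor_atom = anchor_atom, anchor_name = anchor_name,
                 point_idx = NULL, points = NULL, property_values = NULL,
                 descriptors = list(shape = shape, hyd = hyd, ele = ele,
                                    conc = conc),
                 weights = weights),
            class = "surface_patch")
}

toy_pocket <- function(patch_shapes, source_id = "toy", ligand_code = "LIG",
                       order = 15L, ...) {
  patches <- lapply(seq_along(patch_shapes), function(i) {
    toy_patch(patch_shapes[[i]], anchor_name = sprintf("C%d", i),
              anchor_atom = i, ...)
  })
  structure(list(source_id = source_id, ligand_code = ligand_code,
                 patches = patches, order = order),
            class = "pocket")
}

toy_database <- function(pockets, order = 15L, threshold = 0.2) {
  structure(list(entries = pockets,
                 index = patchsurf:::.build_index(pockets),
                 metadata = list(order = order, threshold = threshold),
                 drop_log = data.frame(structure = character(0),
                                       ligand = character(0),
                                       reason = character(0),
                                       stringsAsFactors = FALSE)),
            class = "pocket_database")
}

# hand-written PDB fixture: two-residue protein chain plus one 8-atom
# hetero group and two waters
fixture_pdb_lines <- function() {
  c(
    "HEADER    TEST FIXTURE",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       1.988  -0.773  -1.199  1.00  0.00           C",
    "ATOM      6  N   ILE A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      7  CA  ILE A   2       3.979   2.842   0.000  1.00  0.00           C",
    "ATOM      8  CB  ILE A   2       5.505   2.689   0.000  1.00  0.00           C",
    "HETATM    9  C1  XYZ A 101       8.000   0.000   0.000  1.00  0.00           C",
    "HETATM   10  C2  XYZ A 101       9.200   0.700   0.000  1.00  0.00           C",
    "HETATM   11  O1  XYZ A 101      10.100  -0.200   0.300  1.00  0.00           O",
    "HETATM   12  N1  XYZ A 101       8.300   1.500  -0.800  1.00  0.00           N",
    "HETATM   13  C3  XYZ A 101       7.100   1.100   0.900  1.00  0.00           C",
    "HETATM   14  C4  XYZ A 101       9.900   1.800   0.900  1.00  0.00           C",
    "HETATM   15  O2  XYZ A 101       7.500  -1.200  -0.500  1.00  0.00           O",
    "HETATM   16  C5  XYZ A 101      10.700   0.900  -0.900  1.00  0.00           C",
    "HETATM   17  O   HOH A 201      15.000  15.000  15.000  1.00  0.00           O",
    "HETATM   18  O   HOH A 202      16.000  16.000  16.000  1.00  0.00           O",
    "END"
  )
}

# single-atom structure builder (for surface and property tests)
atom_structure <- function(xyz, element = "C", resname = "ALA",
                           name = "CA") {
  xyz <- matrix(xyz, ncol = 3L)
  n <- nrow(xyz)
  structure(list(
    protein = data.frame(
      name = rep_len(name, n), element = rep_len(element, n),
      resname = rep_len(resname, n), resseq = seq_len(n), icode = " ",
      chain = "A", x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
      stringsAsFactors = FALSE),
    ligands = list()
  ), class = "complex_structure")
}

simple_ligand <- function(xyz, element = "C", het_code = "LIG") {
  xyz <- matrix(xyz, ncol = 3L)
  ligand_record(het_code = het_code, atoms = data.frame(
    name = sprintf("%s%d", rep_len(element, nrow(xyz)), seq_len(nrow(xyz))),
    element = rep_len(element, nrow(xyz)),
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], stringsAsFactors = FALSE))
}
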