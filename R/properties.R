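# Physicochemical channels evaluated on surface points: electrostatic
# potential (screened Coulomb over a bundled partial-charge table),
# hydrophobicity (Kyte-Doolittle index of the nearest residue), and
# concaveness (ray-based visibility against the occupancy grid).

# Simplified per-atom partial charges (units of e).  Ionizable side chains
# carry full formal charges spread over their terminal atoms; the backbone
# carbonyl/amide dipole is represented by +/- 0.4.  This is a deliberately
# coarse, fully documented stand-in for solver-grade electrostatics; an
# import path for precomputed potentials exists in `import_point_values()`.
.backbone_charges <- c(N = 0.4, O = -0.4)
.sidechain_charges <- list(
  ASP = c(OD1 = -0.5, OD2 = -0.5),
  GLU = c(OE1 = -0.5, OE2 = -0.5),
  LYS = c(NZ = 1.0),
  ARG = c(NH1 = 0.5, NH2 = 0.5),
  HIS = c(ND1 = 0.25, NE2 = 0.25)
)

.standard_residues <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

# Kyte-Doolittle hydropathy index per residue
.kyte_doolittle <- c(
  ILE = 4.5, VAL = 4.2, LEU = 3.8, PHE = 2.8, CYS = 2.5, MET = 1.9,
  ALA = 1.8, GLY = -0.4, THR = -0.7, SER = -0.8, TRP = -0.9, TYR = -1.3,
  PRO = -1.6, HIS = -3.2, GLU = -3.5, GLN = -3.5, ASP = -3.5, ASN = -3.5,
  LYS = -3.9, ARG = -4.5
)

#' Partial charges for protein atoms
#'
#' Assigns charges from the bundled simplified table: backbone amide
#' nitrogen +0.4, carbonyl oxygen -0.4, and formal side-chain charges on
#' the terminal atoms of ASP, GLU, LYS, ARG and (partially protonated) HIS.
#' Atoms of residues outside the 20 standard amino acids get charge 0 with
#' a warning.
#'
#' @param structure A `complex_structure`.
#' @return Numeric charge per protein atom (units of e).
#' @export
atom_charges <- function(structure) {
  p <- structure$protein
  q <- numeric(nrow(p))
  unknown <- setdiff(unique(p$resname), .standard_residues)
  if (length(unknown) > 0L) {
    warning("nonstandard residue(s) assigned zero charge: ",
            paste(unknown, collapse = ", "))
  }
  std <- p$resname %in% .standard_residues
  bb <- std & p$name %in% names(.backbone_charges)
  q[bb] <- .backbone_charges[p$name[bb]]
  for (res in names(.sidechain_charges)) {
    tab <- .sidechain_charges[[res]]
    sel <- p$resname == res & p$name %in% names(tab)
    q[sel] <- tab[p$name[sel]]
  }
  q
}

#' Screened Coulomb electrostatic potential at surface points
#'
#' Computes `sum_i q_i / (eps(r_i) * r_i)` over the protein atoms with the
#' distance-dependent dielectric `eps(r) = 4 r`, i.e. each atom contributes
#' `q_i / (4 r_i^2)`.  Distances are clamped below at 0.5 Angstrom to keep
#' the sum finite for degenerate geometries.
#'
#' @param structure A `complex_structure`.
#' @param points Numeric matrix (n x 3) of evaluation coordinates.
#' @param charges Optional charge vector; defaults to [atom_charges()].
#' @return Signed potential per point (arbitrary units of e/Angstrom^2).
#' @export
electrostatic_potential <- function(structure, points, charges = NULL) {
  if (is.null(charges)) charges <- atom_charges(structure)
  xyz <- .protein_xyz(structure)
  stopifnot(length(charges) == nrow(xyz))
  pts <- as.matrix(points)
  out <- numeric(nrow(pts))
  nz <- which(charges != 0)
  for (i in nz) {
    d2 <- (pts[, 1L] - xyz[i, 1L])^2 + (pts[, 2L] - xyz[i, 2L])^2 +
      (pts[, 3L] - xyz[i, 3L])^2
    d2 <- pmax(d2, 0.25)
    out <- out + charges[i] / (4 * d2)
  }
  out
}

#' Hydrophobicity of surface points
#'
#' Each point carries the Kyte-Doolittle hydropathy index of its nearest
#' protein residue (nearest atom's residue).  Nonstandard residues map to 0
#' with a warning.
#'
#' @param structure A `complex_structure`.
#' @param points Numeric matrix (n x 3).
#' @return Signed hydropathy per point.
#' @export
hydrophobicity <- function(structure, points) {
  xyz <- .protein_xyz(structure)
  pts <- as.matrix(points)
  d2 <- outer(rowSums(pts^2), rowSums(xyz^2), "+") - 2 * pts %*% t(xyz)
  nearest <- apply(d2, 1L, which.min)
  res <- structure$protein$resname[nearest]
  kd <- .kyte_doolittle[res]
  if (anyNA(kd)) {
    warning("nonstandard residue(s) assigned hydrophobicity 0: ",
            paste(unique(res[is.na(kd)]), collapse = ", "))
    kd[is.na(kd)] <- 0
  }
  unname(kd)
}

# deterministic near-uniform directions on the sphere (golden-angle spiral)
.sphere_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Concaveness (visibility) of surface points
#'
#' For each point, casts `n_rays` near-uniform ray directions from a start
#' position offset along the surface normal and reports the fraction of rays
#' that escape to the grid boundary without entering protein-occupied
#' voxels.  Values near 1 mark exposed convex points; deep cavity points
#' score low.
#'
#' @param surface A `surface` (carries the occupancy grid).
#' @param point_idx Indices of surface points to evaluate (default all).
#' @param n_rays Number of ray directions, at least 32 (default 128).
#' @param offset Start offset along the normal in Angstrom (default 1.0).
#' @param step Ray march step in Angstrom (default the grid spacing).
#' @return Numeric vector in [0, 1], one value per requested point.
#' @export
concaveness <- function(surface, point_idx = NULL, n_rays = 128L,
                        offset = 1.0, step = NULL) {
  if (n_rays < 32L) stop("`n_rays` must be at least 32")
  if (is.null(point_idx)) point_idx <- seq_len(nrow(surface$points))
  # blocking volume = protein interior (inside the SES), not the
  # probe-expanded solvent-accessible volume: ray start points sit only
  # `offset` above the SES and must begin in free space
  occ <- surface$occupancy$phi < 0
  ax <- surface$occupancy$axes
  sp <- surface$occupancy$spacing
  if (is.null(step)) step <- sp
  nv <- dim(occ)
  lo <- vapply(ax, `[[`, 0, 1L)
  hi <- vapply(ax, function(a) a[length(a)], 0)
  dirs <- .sphere_directions(n_rays)
  maxlen <- sqrt(sum((hi - lo)^2))
  tsteps <- seq(step, maxlen, by = step)
  ns <- length(tsteps)
  # voxel-index offsets of every (ray, step) sample relative to the start
  # voxel; precomputed once, so the march is integer arithmetic per point
  ox <- round(outer(dirs[, 1L], tsteps) / sp)
  oy <- round(outer(dirs[, 2L], tsteps) / sp)
  oz <- round(outer(dirs[, 3L], tsteps) / sp)
  out <- numeric(length(point_idx))
  for (j in seq_along(point_idx)) {
    i <- point_idx[j]
    p0 <- surface$points[i, ] + offset * surface$normals[i, ]
    if (any(p0 < lo) || any(p0 > hi)) {
      stop("ray start point lies outside the occupancy grid")
    }
    c0 <- round((p0 - lo) / sp) + 1L
    ix <- ox + c0[1L]; iy <- oy + c0[2L]; iz <- oz + c0[3L]
    inb <- ix >= 1L & ix <= nv[1L] & iy >= 1L & iy <= nv[2L] &
      iz >= 1L & iz <= nv[3L]
    hit <- array(FALSE, dim = c(n_rays, ns))
    hit[inb] <- occ[cbind(ix[inb], iy[inb], iz[inb])]
    out[j] <- mean(rowSums(hit) == 0L)
  }
  out
}

#' Encode one property channel of a patch as a 3D Zernike descriptor
#'
#' Unsigned channels (shape, concaveness) are voxelized directly and yield
#' one descriptor of `descriptor_length(order)` values (72 at order 15).
#' Signed channels (electrostatic potential, hydrophobicity) are split into
#' their positive and negative parts, each encoded separately, and the two
#' descriptors concatenated (144 values at order 15).  All channels of one
#' patch share the same grid geometry, fixed by the patch point cloud.
#'
#' @param points Patch point coordinates (n x 3).
#' @param values Per-point channel values (scalar 1 for the shape channel).
#' @param signed Whether the channel carries sign.
#' @param order Expansion order (default 15).
#' @param dim Grid dimension (default 64).
#' @param ball_fill Unit-ball fill fraction (default 0.7).
#' @param sigma Gaussian footprint width in Angstrom (see
#'   [voxelize_points()]).
#' @param center,scale_radius Optional fixed grid frame (anchor atom and
#'   physical scope radius) shared by all channels of the patch.
#' @return Numeric descriptor vector of length 72 or 144 (at order 15).
#' @export
encode_patch_channel <- function(points, values, signed = FALSE,
                                 order = 15L, dim = 64L, ball_fill = 0.7,
                                 sigma = 0, center = NULL,
                                 scale_radius = NULL) {
  stopifnot(nrow(points) == length(values))
  vox <- function(v) {
    voxelize_points(points, v, dim = dim, ball_fill = ball_fill,
                    sigma = sigma, center = center,
                    scale_radius = scale_radius)
  }
  if (!signed) {
    return(as.numeric(zernike_descriptor(vox(values), order)))
  }
  c(as.numeric(zernike_descriptor(vox(pmax(values, 0)), order)),
    as.numeric(zernike_descriptor(vox(pmax(-values, 0)), order)))
}

#' Import per-point property values from a text file
#'
#' Reads whitespace-delimited `x y z value` rows and matches them to surface
#' points by nearest neighbor within a tolerance, so solver-grade potentials
#' (e.g. Poisson-Boltzmann output) can replace the bundled electrostatics.
#'
#' @param surface A `surface`.
#' @param path Text file with four columns.
#' @param tolerance Maximum match distance in Angstrom (default 0.5).
#' @return Numeric vector, one value per surface point (`NA` where no
#'   imported point lies within tolerance).
#' @export
import_point_values <- function(surface, path, tolerance = 0.5) {
  tab <- utils::read.table(path, col.names = c("x", "y", "z", "value"))
  src <- as.matrix(tab[, 1:3])
  pts <- surface$points
  d2 <- outer(rowSums(pts^2), rowSums(src^2), "+") - 2 * pts %*% t(src)
  nearest <- apply(d2, 1L, which.min)
  best <- sqrt(pmax(d2[cbind(seq_len(nrow(pts)), nearest)], 0))
  out <- tab$value[nearest]
  out[best > tolerance] <- NA_real_
  out
}
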