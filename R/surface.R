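# Molecular surface generation by signed-distance voxelization.
#
# The solvent-excluded surface (SES) is approximated on a regular grid: a
# voxel is "occupied" when its center lies inside any probe-expanded atom
# sphere (the solvent-accessible volume), a depth field is computed inside
# the occupied region, and the isosurface at depth = probe radius is sampled
# by linear interpolation along grid edges.  This reproduces re-entrant
# surface geometry to within the grid spacing and is fully deterministic.

# Signed pseudo-distance field: negative deep inside the protein, zero on
# the SES, positive toward solvent.  `cap` limits how far distances are
# resolved; beyond it the field saturates (only the neighborhood of the
# isosurface matters).
.ses_field <- function(xyz, radii, probe, spacing, pad = NULL) {
  if (is.null(pad)) pad <- max(radii) + probe + 3 * spacing
  lo <- apply(xyz, 2L, min) - pad
  hi <- apply(xyz, 2L, max) + pad
  nv <- pmax(ceiling((hi - lo) / spacing) + 1L, 4L)
  ax <- lapply(1:3, function(k) lo[k] + (seq_len(nv[k]) - 1L) * spacing)

  occ <- array(FALSE, dim = nv)
  for (i in seq_len(nrow(xyz))) {
    R <- radii[i] + probe
    rng <- lapply(1:3, function(k) {
      which(abs(ax[[k]] - xyz[i, k]) <= R + spacing)
    })
    if (any(vapply(rng, length, 1L) == 0L)) next
    dx2 <- outer(ax[[1L]][rng[[1L]]] - xyz[i, 1L], numeric(1), function(a, b) a^2)
    dy2 <- (ax[[2L]][rng[[2L]]] - xyz[i, 2L])^2
    dz2 <- (ax[[3L]][rng[[3L]]] - xyz[i, 3L])^2
    box <- outer(outer(c(dx2), dy2, "+"), dz2, "+") <= R^2
    occ[rng[[1L]], rng[[2L]], rng[[3L]]] <- occ[rng[[1L]], rng[[2L]], rng[[3L]]] | box
  }

  # depth inside the occupied region: distance from an occupied voxel center
  # to the nearest free voxel center, resolved up to `cap`
  cap <- probe + 2 * spacing
  kmax <- ceiling(cap / spacing)
  D <- array(cap, dim = nv)
  D[!occ] <- 0
  free <- !occ
  shift3 <- function(a, s) {
    # shift array by s (voxels), padding with FALSE
    out <- array(FALSE, dim = dim(a))
    src <- lapply(1:3, function(k) {
      i <- seq_len(dim(a)[k]) - s[k]
      i[i >= 1L & i <= dim(a)[k]]
    })
    dst <- lapply(1:3, function(k) {
      i <- seq_len(dim(a)[k])
      i[i - s[k] >= 1L & i - s[k] <= dim(a)[k]]
    })
    out[dst[[1L]], dst[[2L]], dst[[3L]]] <- a[src[[1L]], src[[2L]], src[[3L]]]
    out
  }
  offs <- expand.grid(i = -kmax:kmax, j = -kmax:kmax, k = -kmax:kmax)
  offs$d <- spacing * sqrt(offs$i^2 + offs$j^2 + offs$k^2)
  offs <- offs[offs$d > 0 & offs$d <= cap, , drop = FALSE]
  offs <- offs[order(offs$d), , drop = FALSE]
  for (r in seq_len(nrow(offs))) {
    if (all(D <= offs$d[r])) break
    sh <- shift3(free, c(offs$i[r], offs$j[r], offs$k[r]))
    upd <- occ & sh & (D > offs$d[r])
    D[upd] <- offs$d[r]
  }

  phi <- array(probe + spacing, dim = nv)   # free voxels: shallow positive
  phi[occ] <- probe - D[occ]
  list(phi = phi, axes = ax, spacing = spacing, occ = occ)
}

# sample the phi = 0 isosurface by edge interpolation; returns points and
# normals from the central-difference gradient
.isosurface_points <- function(field) {
  phi <- field$phi
  ax <- field$axes
  sp <- field$spacing
  nv <- dim(phi)
  grad <- function(idx) {
    # central differences, clamped at the grid border
    g <- matrix(0, nrow(idx), 3L)
    for (k in 1:3) {
      up <- idx; up[, k] <- pmin(idx[, k] + 1L, nv[k])
      dn <- idx; dn[, k] <- pmax(idx[, k] - 1L, 1L)
      g[, k] <- (phi[up] - phi[dn]) / ((up[, k] - dn[, k]) * sp)
    }
    g
  }
  pts <- NULL; nrm <- NULL
  for (k in 1:3) {
    a <- seq_len(nv[k] - 1L)
    lowidx <- as.matrix(expand.grid(i = seq_len(nv[1L] - (k == 1L)),
                                    j = seq_len(nv[2L] - (k == 2L)),
                                    kk = seq_len(nv[3L] - (k == 3L))))
    colnames(lowidx) <- NULL
    hi <- lowidx; hi[, k] <- hi[, k] + 1L
    p0 <- phi[lowidx]; p1 <- phi[hi]
    cross <- (p0 < 0 & p1 >= 0) | (p0 >= 0 & p1 < 0)
    if (!any(cross)) next
    lowidx <- lowidx[cross, , drop = FALSE]
    hi <- hi[cross, , drop = FALSE]
    t <- p0[cross] / (p0[cross] - p1[cross])
    xyz0 <- cbind(ax[[1L]][lowidx[, 1L]], ax[[2L]][lowidx[, 2L]],
                  ax[[3L]][lowidx[, 3L]])
    xyz <- xyz0
    xyz[, k] <- xyz[, k] + t * sp
    g0 <- grad(lowidx); g1 <- grad(hi)
    g <- g0 * (1 - t) + g1 * t
    gl <- sqrt(rowSums(g^2))
    ok <- gl > 0
    pts <- rbind(pts, xyz[ok, , drop = FALSE])
    nrm <- rbind(nrm, g[ok, , drop = FALSE] / gl[ok])
  }
  list(points = pts, normals = nrm)
}

#' Compute a molecular surface point cloud
#'
#' Approximates the solvent-excluded surface of the protein atoms by
#' signed-distance voxelization of probe-expanded atom spheres followed by
#' isosurface edge sampling.  Normals come from the distance-field gradient
#' and point away from the protein.  Identical inputs give bit-identical
#' surfaces.
#'
#' @param structure A `complex_structure` (ligand atoms are ignored).
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4).
#' @param spacing Grid spacing in Angstrom (default 0.8).
#' @return A `surface` object: `points` (n x 3), `normals` (n x 3 unit
#'   vectors), `point_area` (per-point area weight), and the occupancy field
#'   used downstream by the concaveness channel.
#' @export
compute_surface <- function(structure, probe_radius = 1.4, spacing = 0.8) {
  if (probe_radius <= 0) stop("`probe_radius` must be positive")
  if (spacing <= 0) stop("`spacing` must be positive")
  xyz <- .protein_xyz(structure)
  if (nrow(xyz) < 1L) stop("structure has no protein atoms")
  radii <- vdw_radius(structure$protein$element)
  field <- .ses_field(xyz, radii, probe_radius, spacing)
  iso <- .isosurface_points(field)
  if (is.null(iso$points)) stop("no surface points produced")
  structure(list(points = iso$points, normals = iso$normals,
                 point_area = rep(spacing^2, nrow(iso$points)),
                 occupancy = field, probe_radius = probe_radius,
                 spacing = spacing),
            class = "surface")
}

#' @export
print.surface <- function(x, ...) {
  cat(sprintf("<surface: %d points, spacing %.2f A>\n",
              nrow(x$points), x$spacing))
  invisible(x)
}

#' Extract the pocket region of a surface around a bound ligand
#'
#' Returns exactly the surface points within `cutoff` of any ligand heavy
#' atom.
#'
#' @param surface A `surface`.
#' @param ligand A `ligand_record`.
#' @param cutoff Distance cutoff in Angstrom (default 4.5).
#' @return Integer vector of surface-point indices.
#' @export
extract_pocket <- function(surface, ligand, cutoff = 4.5) {
  if (cutoff <= 0) stop("`cutoff` must be positive")
  lxyz <- .ligand_heavy_xyz(ligand)
  if (nrow(lxyz) == 0L) stop("ligand has no heavy atoms")
  d2 <- .min_cross_dist2(surface$points, lxyz)
  idx <- which(d2 <= cutoff^2)
  if (length(idx) == 0L) {
    stop("ligand not in contact with surface at this cutoff")
  }
  idx
}

# per-row minimum squared distance from rows of A to rows of B
.min_cross_dist2 <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  cross <- A %*% t(B)
  d2 <- outer(a2, b2, "+") - 2 * cross
  apply(pmax(d2, 0), 1L, min)
}

#' Segment pocket surface points into ligand-atom-anchored patches
#'
#' Each pocket point is assigned to its nearest ligand heavy atom; every
#' nonempty group becomes one patch.  Ties go to the lowest ligand-atom
#' index, so the partition is deterministic.
#'
#' @param surface A `surface`.
#' @param pocket_idx Surface-point indices from [extract_pocket()].
#' @param ligand A `ligand_record`.
#' @return List of patch skeletons: `anchor_atom` (heavy-atom index within
#'   the ligand), `anchor_name`, `point_idx` (surface-point indices) and
#'   `points` (coordinates).
#' @export
segment_patches <- function(surface, pocket_idx, ligand) {
  if (length(pocket_idx) < 1L) stop("pocket has no points")
  lxyz <- .ligand_heavy_xyz(ligand)
  heavy_names <- ligand$atoms$name[!(toupper(ligand$atoms$element) %in%
                                       c("H", "D"))]
  P <- surface$points[pocket_idx, , drop = FALSE]
  d2 <- outer(rowSums(P^2), rowSums(lxyz^2), "+") - 2 * P %*% t(lxyz)
  # which.max on the negated matrix returns the FIRST minimum: ties break
  # toward the lowest atom index
  assign <- apply(d2, 1L, which.min)
  patches <- lapply(sort(unique(assign)), function(a) {
    sel <- assign == a
    list(anchor_atom = a, anchor_name = heavy_names[a],
         point_idx = pocket_idx[sel],
         points = P[sel, , drop = FALSE])
  })
  patches
}
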