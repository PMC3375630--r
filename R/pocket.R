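# Pocket assembly: surface -> pocket region -> anchored patches -> four
# encoded property channels per patch.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the pocket pipeline with its
#' default.  Defaults: Zernike order 15 (72 invariants per unsigned
#' channel), 64^3 encoding grid, patches encoded in a frame centered on
#' their anchor ligand atom with a fixed 6.0 A scope mapped to radius 0.7
#' of the unit ball and a 0.8 A Gaussian point footprint, solvent probe
#' 1.4 A, surface grid spacing 0.5 A, pocket cutoff 4.5 A, database
#' filters at 7 heavy atoms / 4.0 A grouping / 1.4 A covalent / 3.5 A
#' contact, 128 visibility rays offset 1.0 A along the normal, and a
#' patch-distance threshold of 0.2 for matching.
#'
#' @param order Zernike expansion order.
#' @param grid_dim Voxels per axis for descriptor encoding.
#' @param ball_fill Unit-ball fill fraction for descriptor encoding.
#' @param probe_radius Solvent probe radius (Angstrom).
#' @param spacing Surface grid spacing (Angstrom).
#' @param pocket_cutoff Surface-to-ligand cutoff defining the pocket
#'   (Angstrom).
#' @param min_heavy Minimum ligand heavy-atom count.
#' @param group_cutoff Ligand grouping distance (Angstrom).
#' @param covalent_cutoff Covalent-bond filter distance (Angstrom).
#' @param contact_cutoff No-contact filter distance (Angstrom).
#' @param n_rays Ray count for the concaveness channel.
#' @param ray_offset Ray start offset along the normal (Angstrom).
#' @param threshold Patch-distance threshold for matching (`NULL` = none).
#' @param term_weights Coefficients (c1, c2, c3) of the pocket score.
#' @param patch_scope Physical radius (Angstrom) around the anchor atom
#'   mapped to `ball_fill` when encoding a patch; fixes one grid frame for
#'   all channels and all copies of a patch.
#' @param splat_sigma Gaussian footprint width (Angstrom) for patch
#'   voxelization (0 = nearest-voxel marking).
#' @return A `ps_config` list.
#' @export
ps_config <- function(order = 15L, grid_dim = 64L, ball_fill = 0.7,
                      probe_radius = 1.4, spacing = 0.5,
                      pocket_cutoff = 4.5, min_heavy = 7L,
                      group_cutoff = 4.0, covalent_cutoff = 1.4,
                      contact_cutoff = 3.5, n_rays = 128L, ray_offset = 1.0,
                      threshold = 0.2, term_weights = c(1.0, 0.5, 0.5),
                      patch_scope = 6.0, splat_sigma = 0.8) {
  structure(as.list(environment()), class = "ps_config")
}

.channel_names <- c("shape", "hyd", "ele", "conc")
.channel_signed <- c(shape = FALSE, hyd = TRUE, ele = TRUE, conc = FALSE)

#' Build a pocket representation from a complex and one ligand
#'
#' Runs the full per-structure pipeline: molecular surface, pocket region
#' within `pocket_cutoff` of the ligand heavy atoms, nearest-ligand-atom
#' patch segmentation, the four property channels, and one 3D Zernike
#' descriptor per channel per patch.  Patch weights start uniform (0.25
#' each); database construction replaces them with the dispersion-based
#' weights of [compute_weights()].
#'
#' @param structure A `complex_structure`.
#' @param ligand A `ligand_record` (or an index into `structure$ligands`).
#' @param config A [ps_config()].
#' @param source_id Identifier recorded in the pocket (default built from
#'   the ligand).
#' @param surface Optional precomputed [compute_surface()] result, reused
#'   when several ligands of one structure are processed.
#' @return A `pocket` object.
#' @export
build_pocket <- function(structure, ligand, config = ps_config(),
                         source_id = NULL, surface = NULL) {
  if (is.numeric(ligand)) ligand <- structure$ligands[[ligand]]
  stopifnot(inherits(ligand, "ligand_record"))
  if (is.null(source_id)) {
    source_id <- sprintf("%s:%s:%d", ligand$het_code, ligand$chain,
                         ligand$resseq)
  }
  if (is.null(surface)) {
    surface <- compute_surface(structure, config$probe_radius,
                               config$spacing)
  }
  pocket_idx <- extract_pocket(surface, ligand, config$pocket_cutoff)
  skels <- segment_patches(surface, pocket_idx, ligand)

  pts <- surface$points[pocket_idx, , drop = FALSE]
  ele_all <- electrostatic_potential(structure, pts)
  hyd_all <- hydrophobicity(structure, pts)
  conc_all <- concaveness(surface, pocket_idx, n_rays = config$n_rays,
                          offset = config$ray_offset)
  lookup <- stats::setNames(seq_along(pocket_idx), pocket_idx)
  lig_xyz <- .ligand_heavy_xyz(ligand)

  patches <- lapply(skels, function(sk) {
    rows <- lookup[as.character(sk$point_idx)]
    vals <- list(shape = rep(1, length(rows)), hyd = hyd_all[rows],
                 ele = ele_all[rows], conc = conc_all[rows])
    anchor <- as.numeric(lig_xyz[sk$anchor_atom, ])
    desc <- lapply(.channel_names, function(ch) {
      encode_patch_channel(sk$points, vals[[ch]],
                           signed = .channel_signed[[ch]],
                           order = config$order, dim = config$grid_dim,
                           ball_fill = config$ball_fill,
                           sigma = config$splat_sigma, center = anchor,
                           scale_radius = config$patch_scope)
    })
    names(desc) <- .channel_names
    structure(list(anchor_atom = sk$anchor_atom,
                   anchor_name = sk$anchor_name,
                   point_idx = sk$point_idx,
                   points = sk$points,
                   property_values = vals,
                   descriptors = desc,
                   weights = stats::setNames(rep(0.25, 4), .channel_names)),
              class = "surface_patch")
  })
  structure(list(source_id = source_id, ligand_code = ligand$het_code,
                 patches = patches, order = config$order),
            class = "pocket")
}

#' @export
print.pocket <- function(x, ...) {
  cat(sprintf("<pocket %s (ligand %s): %d patches>\n",
              x$source_id, x$ligand_code, length(x$patches)))
  invisible(x)
}

#' @export
print.surface_patch <- function(x, ...) {
  cat(sprintf("<surface_patch anchor %s (#%d): %d points>\n",
              x$anchor_name, x$anchor_atom, nrow(x$points)))
  invisible(x)
}

# stack one channel's descriptors across patches into a matrix
.pocket_channel_matrix <- function(pocket, channel) {
  do.call(rbind, lapply(pocket$patches, function(p) p$descriptors[[channel]]))
}
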