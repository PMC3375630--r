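# Pocket-database construction: the ligand filtering rules, the build
# pipeline, dispersion-based patch weights, and plain-text persistence.

#' Drop ligands with too few heavy atoms
#'
#' Retains exactly the ligands with `heavy_atom_count >= min_heavy`
#' (default 7): small crystallization additives and ions are not
#' informative binding sites.
#'
#' @param ligands List of `ligand_record`.
#' @param min_heavy Minimum heavy-atom count (default 7).
#' @return The retained sublist.
#' @export
filter_small_ligands <- function(ligands, min_heavy = 7L) {
  Filter(function(l) l$heavy_atom_count >= min_heavy, ligands)
}

#' Group ligands that share a binding site
#'
#' Single-linkage connected components under the relation "some pair of
#' atoms, one from each ligand, is closer than `link_cutoff`" (default
#' 4.0 Angstrom).  Each component is treated as one binding site.
#'
#' @param ligands List of `ligand_record`.
#' @param link_cutoff Linking distance in Angstrom.
#' @return List of integer vectors, each the indices of one group.
#' @export
group_ligands <- function(ligands, link_cutoff = 4.0) {
  n <- length(ligands)
  if (n == 0L) stop("at least one ligand is required")
  xyz <- lapply(ligands, function(l) as.matrix(l$atoms[, c("x", "y", "z")]))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    mind2 <- min(.min_cross_dist2(xyz[[i]], xyz[[j]]))
    if (sqrt(mind2) < link_cutoff) {
      parent[find(j)] <- find(i)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  unname(split(seq_len(n), roots))
}

# pool a ligand group into one combined record (heavy atoms anchor patches)
.merge_ligand_group <- function(ligands) {
  if (length(ligands) == 1L) return(ligands[[1L]])
  atoms <- do.call(rbind, lapply(ligands, `[[`, "atoms"))
  codes <- sort(unique(vapply(ligands, `[[`, "", "het_code")))
  ligand_record(het_code = paste(codes, collapse = "+"),
                chain = ligands[[1L]]$chain,
                resseq = ligands[[1L]]$resseq, atoms = atoms)
}

#' Covalent / no-contact filter for a ligand (group)
#'
#' Measures the minimum heavy-atom distance between the ligand group and
#' the protein: below `covalent_cutoff` (1.4 A) the ligand is covalently
#' bound and dropped; above `contact_cutoff` (3.5 A) it is not physically
#' interacting and dropped; otherwise it is kept.
#'
#' @param ligand A `ligand_record` (possibly a merged group).
#' @param structure The `complex_structure` providing protein atoms.
#' @param covalent_cutoff,contact_cutoff Distance bounds in Angstrom.
#' @return List with `keep` (logical), `reason` (`NA`, "covalent" or
#'   "no-contact") and `min_distance`.
#' @export
filter_contacts <- function(ligand, structure, covalent_cutoff = 1.4,
                            contact_cutoff = 3.5) {
  lxyz <- .ligand_heavy_xyz(ligand)
  heavy <- !(toupper(structure$protein$element) %in% c("H", "D"))
  pxyz <- .protein_xyz(structure)[heavy, , drop = FALSE]
  if (nrow(lxyz) == 0L || nrow(pxyz) == 0L) {
    stop("both ligand and protein heavy-atom sets must be nonempty")
  }
  mind <- sqrt(min(.min_cross_dist2(lxyz, pxyz)))
  if (mind < covalent_cutoff) {
    list(keep = FALSE, reason = "covalent", min_distance = mind)
  } else if (mind > contact_cutoff) {
    list(keep = FALSE, reason = "no-contact", min_distance = mind)
  } else {
    list(keep = TRUE, reason = NA_character_, min_distance = mind)
  }
}

#' Build a searchable pocket database from complex structures
#'
#' For each structure: drop small ligands, group the survivors into
#' binding sites, apply the covalent/contact filter per site, and turn
#' each kept site into a pocket (surface, patches, four descriptors per
#' patch).  Afterwards, per-patch property weights are computed from the
#' patches at equivalent positions (same ligand code and anchor atom name)
#' across entries; positions represented only once keep uniform weights.
#'
#' @param structures List of `complex_structure` objects.
#' @param config A [ps_config()].
#' @param ids Optional character IDs, one per structure (defaults to
#'   "S001", ...).
#' @return A `pocket_database`: `entries` (list of pockets), `index`
#'   (ligand code -> entry indices), `metadata`, and `drop_log` (data frame
#'   of dropped ligands with one reason each: small, covalent or
#'   no-contact).
#' @export
build_database <- function(structures, config = ps_config(), ids = NULL) {
  if (length(structures) == 0L) stop("at least one structure is required")
  if (is.null(ids)) ids <- sprintf("S%03d", seq_along(structures))
  entries <- list()
  drop_log <- data.frame(structure = character(0), ligand = character(0),
                         reason = character(0), stringsAsFactors = FALSE)
  note_drop <- function(sid, lig, reason) {
    rbind(drop_log, data.frame(structure = sid, ligand = lig,
                               reason = reason, stringsAsFactors = FALSE))
  }
  for (s in seq_along(structures)) {
    st <- structures[[s]]
    sid <- ids[s]
    ligs <- st$ligands
    if (length(ligs) == 0L) next
    keep_idx <- which(vapply(ligs, function(l) {
      l$heavy_atom_count >= config$min_heavy
    }, logical(1L)))
    for (l in setdiff(seq_along(ligs), keep_idx)) {
      drop_log <- note_drop(sid, ligs[[l]]$het_code, "small")
    }
    big <- ligs[keep_idx]
    if (length(big) == 0L) next
    groups <- group_ligands(big, config$group_cutoff)
    surf <- NULL
    for (g in groups) {
      merged <- .merge_ligand_group(big[g])
      verdict <- filter_contacts(merged, st, config$covalent_cutoff,
                                 config$contact_cutoff)
      if (!verdict$keep) {
        drop_log <- note_drop(sid, merged$het_code, verdict$reason)
        next
      }
      if (is.null(surf)) {
        surf <- compute_surface(st, config$probe_radius, config$spacing)
      }
      pk <- build_pocket(st, merged, config,
                         source_id = sprintf("%s:%s", sid, merged$het_code),
                         surface = surf)
      entries[[length(entries) + 1L]] <- pk
    }
    if (is.null(surf)) {
      message(sprintf("structure %s: no surviving ligands", sid))
    }
  }
  db <- structure(list(
    entries = entries,
    index = .build_index(entries),
    metadata = list(order = config$order, grid_dim = config$grid_dim,
                    ball_fill = config$ball_fill,
                    probe_radius = config$probe_radius,
                    spacing = config$spacing,
                    pocket_cutoff = config$pocket_cutoff,
                    min_heavy = config$min_heavy,
                    group_cutoff = config$group_cutoff,
                    covalent_cutoff = config$covalent_cutoff,
                    contact_cutoff = config$contact_cutoff,
                    threshold = config$threshold,
                    n_rays = config$n_rays, ray_offset = config$ray_offset),
    drop_log = drop_log
  ), class = "pocket_database")
  assign_patch_weights(db)
}

.build_index <- function(entries) {
  codes <- vapply(entries, `[[`, "", "ligand_code")
  split(seq_along(entries), codes)
}

#' Fill in dispersion-based patch weights across a database
#'
#' Groups patches by (ligand code, anchor atom name) across entries and
#' applies [compute_weights()] to every group with at least two members;
#' singleton groups keep uniform weights (0.25 each).
#'
#' @param db A `pocket_database`.
#' @return The database with per-patch weights replaced.
#' @export
assign_patch_weights <- function(db) {
  keys <- list()
  for (e in seq_along(db$entries)) {
    pk <- db$entries[[e]]
    for (p in seq_along(pk$patches)) {
      key <- paste(pk$ligand_code, pk$patches[[p]]$anchor_name, sep = "|")
      keys[[key]] <- rbind(keys[[key]], c(e, p))
    }
  }
  for (key in names(keys)) {
    loc <- keys[[key]]
    if (nrow(loc) < 2L) next
    grp <- lapply(seq_len(nrow(loc)), function(i) {
      db$entries[[loc[i, 1L]]]$patches[[loc[i, 2L]]]
    })
    w <- compute_weights(grp)
    for (i in seq_len(nrow(loc))) {
      db$entries[[loc[i, 1L]]]$patches[[loc[i, 2L]]]$weights <- w
    }
  }
  db
}

#' @export
print.pocket_database <- function(x, ...) {
  cat(sprintf("<pocket_database: %d entries, %d ligand type(s), order %d>\n",
              length(x$entries), length(x$index), x$metadata$order))
  invisible(x)
}

#' Save a pocket database to a directory
#'
#' Plain-text layout: `metadata.json`, a tab-separated `index.tsv`
#' (entry id, ligand code, patch count, file name), `drop_log.tsv`, and one
#' descriptor file per entry holding each patch's four channels and
#' weights at 17 significant digits.  Save/load/save round-trips are
#' bit-identical.
#'
#' @param db A `pocket_database`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_database <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(db$metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  idx <- data.frame(
    entry_id = vapply(db$entries, `[[`, "", "source_id"),
    ligand_code = vapply(db$entries, `[[`, "", "ligand_code"),
    patch_count = vapply(db$entries, function(e) length(e$patches), 1L),
    file = sprintf("entry_%04d.tsv", seq_along(db$entries)),
    stringsAsFactors = FALSE
  )
  utils::write.table(idx, file.path(dir, "index.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(db$drop_log, file.path(dir, "drop_log.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (e in seq_along(db$entries)) {
    pk <- db$entries[[e]]
    con <- file(file.path(dir, idx$file[e]), "w")
    for (p in pk$patches) {
      for (ch in .channel_names) {
        writeLines(paste(c(p$anchor_name, ch,
                           sprintf("%.17g", p$descriptors[[ch]])),
                         collapse = "\t"), con)
      }
      writeLines(paste(c(p$anchor_name, "weights",
                         sprintf("%.17g", p$weights)), collapse = "\t"), con)
    }
    close(con)
  }
  invisible(dir)
}

#' Load a pocket database saved by [save_database()]
#'
#' @param dir Database directory.
#' @return A `pocket_database`.  Patches carry descriptors and weights
#'   (point clouds are not persisted; they are not needed for search).
#' @export
load_database <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  idx <- utils::read.table(file.path(dir, "index.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "integer", "character"))
  drop_log <- utils::read.table(file.path(dir, "drop_log.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  entries <- lapply(seq_len(nrow(idx)), function(e) {
    lines <- readLines(file.path(dir, idx$file[e]))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    anchors <- vapply(parts, `[[`, "", 1L)
    kinds <- vapply(parts, `[[`, "", 2L)
    patch_anchors <- unique(anchors)
    patches <- lapply(seq_along(patch_anchors), function(pi) {
      an <- patch_anchors[pi]
      rows <- which(anchors == an)
      desc <- list()
      w <- NULL
      for (r in rows) {
        vals <- as.numeric(parts[[r]][-(1:2)])
        if (kinds[r] == "weights") {
          w <- stats::setNames(vals, .channel_names)
        } else {
          desc[[kinds[r]]] <- vals
        }
      }
      structure(list(anchor_atom = pi, anchor_name = an, point_idx = NULL,
                     points = NULL, property_values = NULL,
                     descriptors = desc[.channel_names], weights = w),
                class = "surface_patch")
    })
    structure(list(source_id = idx$entry_id[e],
                   ligand_code = idx$ligand_code[e],
                   patches = patches, order = meta$order),
              class = "pocket")
  })
  structure(list(entries = entries, index = .build_index(entries),
                 metadata = as.list(meta), drop_log = drop_log),
            class = "pocket_database")
}
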