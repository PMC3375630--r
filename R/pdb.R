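# PDB v3.3 fixed-width parsing and writing, plus the bundled van der Waals
# radius table.  Only ATOM/HETATM/MODEL/ENDMDL records are interpreted;
# insertion codes are kept, models after the first are ignored.

.water_codes <- c("HOH", "WAT", "DOD", "H2O")

# van der Waals radii in Angstrom (Bondi-style values, fixed so that
# surfaces are reproducible across installations)
.vdw_table <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
  FE = 1.40, MG = 1.73, ZN = 1.39, MN = 1.40, CU = 1.40, NI = 1.40,
  CA = 1.90, "NA" = 2.27, K = 2.75, CO = 1.40, MO = 1.45
)

#' van der Waals radius of an element
#'
#' Looks up the bundled fixed radius table.  Unknown elements fall back to
#' the carbon radius with a warning, so surfaces stay computable for exotic
#' hetero atoms.
#'
#' @param element Character vector of element symbols.
#' @return Numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  el <- toupper(trimws(element))
  r <- .vdw_table[el]
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(el[is.na(r)]), collapse = ", "),
            "; using carbon radius")
    r[is.na(r)] <- .vdw_table[["C"]]
  }
  unname(r)
}

.guess_element <- function(name) {
  # PDB atom names right-justify the element in columns 13-14; strip digits
  el <- gsub("[0-9' ]", "", substr(sprintf("%-4s", name), 1L, 2L))
  el <- toupper(el)
  # two-letter symbols only when they are real elements in our table
  ifelse(el %in% names(.vdw_table), el, substr(el, 1L, 1L))
}

.parse_atom_line <- function(line, lineno) {
  x <- suppressWarnings(as.numeric(substr(line, 31L, 38L)))
  y <- suppressWarnings(as.numeric(substr(line, 39L, 46L)))
  z <- suppressWarnings(as.numeric(substr(line, 47L, 54L)))
  if (anyNA(c(x, y, z))) {
    stop(sprintf("malformed coordinates at line %d", lineno))
  }
  occ <- suppressWarnings(as.numeric(substr(line, 55L, 60L)))
  if (is.na(occ)) occ <- 1
  el <- trimws(substr(line, 77L, 78L))
  name <- trimws(substr(line, 13L, 16L))
  if (el == "") el <- .guess_element(name)
  list(
    record = trimws(substr(line, 1L, 6L)),
    name = name,
    altloc = substr(line, 17L, 17L),
    resname = trimws(substr(line, 18L, 20L)),
    chain = substr(line, 22L, 22L),
    resseq = suppressWarnings(as.integer(substr(line, 23L, 26L))),
    icode = substr(line, 27L, 27L),
    x = x, y = y, z = z, occ = occ, element = toupper(el)
  )
}

#' Parse a protein-ligand complex from PDB-format text
#'
#' ATOM records become protein atoms; HETATM records, grouped by (het code,
#' chain, residue number, insertion code), become ligand records.  Waters
#' are discarded.  Alternate locations are resolved by keeping the highest
#' occupancy copy of each atom (ties to the first encountered).  Models
#' after the first are ignored.
#'
#' @param pdb_text Character scalar or vector of PDB lines, or a file path
#'   ending in `.pdb`/`.ent`.
#' @return A `complex_structure`: list with `protein` (data frame of atoms)
#'   and `ligands` (list of `ligand_record`).
#' @export
parse_structure <- function(pdb_text) {
  if (length(pdb_text) == 1L && grepl("\\.(pdb|ent)$", pdb_text) &&
      file.exists(pdb_text)) {
    pdb_text <- readLines(pdb_text)
  }
  lines <- unlist(strsplit(pdb_text, "\n", fixed = TRUE))
  in_model <- 0L
  rows <- list()
  for (i in seq_along(lines)) {
    rec <- substr(lines[i], 1L, 6L)
    if (startsWith(rec, "MODEL")) { in_model <- in_model + 1L; next }
    if (startsWith(rec, "ENDMDL")) next
    if (in_model > 1L) next
    if (rec == "ATOM  " || rec == "HETATM") {
      rows[[length(rows) + 1L]] <- .parse_atom_line(lines[i], i)
    }
  }
  if (length(rows) == 0L || !any(vapply(rows, function(r) r$record == "ATOM",
                                        logical(1L)))) {
    stop("no ATOM records found: not a protein structure")
  }
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(record = r$record, name = r$name, altloc = r$altloc,
               resname = r$resname, chain = r$chain, resseq = r$resseq,
               icode = r$icode, x = r$x, y = r$y, z = r$z, occ = r$occ,
               element = r$element, stringsAsFactors = FALSE)
  }))
  # altLoc resolution: one copy per atom site, highest occupancy wins
  key <- paste(df$record, df$chain, df$resseq, df$icode, df$resname, df$name)
  keep <- unlist(lapply(split(seq_len(nrow(df)), key), function(ix) {
    ix[which.max(df$occ[ix])]
  }), use.names = FALSE)
  df <- df[sort(keep), , drop = FALSE]

  prot <- df[df$record == "ATOM", , drop = FALSE]
  het <- df[df$record == "HETATM" & !(df$resname %in% .water_codes), ,
            drop = FALSE]
  lig_key <- paste(het$resname, het$chain, het$resseq, het$icode, sep = ":")
  ligands <- lapply(split(seq_len(nrow(het)), factor(lig_key,
                                                    levels = unique(lig_key))),
                    function(ix) {
    sub <- het[ix, , drop = FALSE]
    ligand_record(
      het_code = sub$resname[1L], chain = sub$chain[1L],
      resseq = sub$resseq[1L],
      atoms = data.frame(name = sub$name, element = sub$element,
                         x = sub$x, y = sub$y, z = sub$z,
                         stringsAsFactors = FALSE)
    )
  })
  names(ligands) <- NULL
  structure(list(
    protein = prot[, c("name", "element", "resname", "resseq", "icode",
                       "chain", "x", "y", "z")],
    ligands = ligands
  ), class = "complex_structure")
}

#' Construct a ligand record
#'
#' @param het_code Three-letter chemical component identifier.
#' @param chain Chain identifier.
#' @param resseq Residue sequence number.
#' @param atoms Data frame with columns name, element, x, y, z.
#' @return A `ligand_record` with the heavy (non-hydrogen) atom count filled
#'   in.
#' @export
ligand_record <- function(het_code, chain = "A", resseq = 1L, atoms) {
  stopifnot(all(c("name", "element", "x", "y", "z") %in% names(atoms)))
  heavy <- !(toupper(atoms$element) %in% c("H", "D"))
  structure(list(het_code = het_code, chain = chain, resseq = resseq,
                 atoms = atoms, heavy_atom_count = sum(heavy)),
            class = "ligand_record")
}

# coordinates of a ligand's heavy atoms as a matrix
.ligand_heavy_xyz <- function(lig) {
  heavy <- !(toupper(lig$atoms$element) %in% c("H", "D"))
  as.matrix(lig$atoms[heavy, c("x", "y", "z"), drop = FALSE])
}

.protein_xyz <- function(structure) {
  as.matrix(structure$protein[, c("x", "y", "z"), drop = FALSE])
}

#' @export
print.complex_structure <- function(x, ...) {
  cat(sprintf("<complex_structure: %d protein atoms, %d ligand(s)%s>\n",
              nrow(x$protein), length(x$ligands),
              if (length(x$ligands)) paste0(" [",
                paste(vapply(x$ligands, `[[`, "", "het_code"),
                      collapse = ", "), "]") else ""))
  invisible(x)
}

#' @export
print.ligand_record <- function(x, ...) {
  cat(sprintf("<ligand %s chain %s res %d: %d atoms (%d heavy)>\n",
              x$het_code, x$chain, x$resseq, nrow(x$atoms),
              x$heavy_atom_count))
  invisible(x)
}

#' Write a complex structure as fixed-width PDB text
#'
#' Coordinates are written with three decimals, the PDB precision; a
#' structure round-trips through [parse_structure()] at that precision.
#'
#' @param structure A `complex_structure`.
#' @param path Optional output file; when `NULL` the lines are returned.
#' @return Character vector of PDB lines (invisibly when `path` is given).
#' @export
write_pdb <- function(structure, path = NULL) {
  fmt <- function(record, serial, name, resname, chain, resseq, x, y, z,
                  element) {
    sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            record, serial, substr(name, 1L, 4L), resname, chain, resseq,
            x, y, z, 1, 0, element)
  }
  lines <- character(0)
  serial <- 0L
  p <- structure$protein
  for (i in seq_len(nrow(p))) {
    serial <- serial + 1L
    lines <- c(lines, fmt("ATOM", serial, p$name[i], p$resname[i],
                          p$chain[i], p$resseq[i], p$x[i], p$y[i], p$z[i],
                          p$element[i]))
  }
  for (lig in structure$ligands) {
    a <- lig$atoms
    for (i in seq_len(nrow(a))) {
      serial <- serial + 1L
      lines <- c(lines, fmt("HETATM", serial, a$name[i], lig$het_code,
                            lig$chain, lig$resseq, a$x[i], a$y[i], a$z[i],
                            a$element[i]))
    }
  }
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
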