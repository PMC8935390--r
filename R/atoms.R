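# Atomic coordinate input: PDB fixed-column files via bio3d, plus a minimal
# mmCIF atom_site reader. Only the fields the density model needs are kept:
# position, occupancy, isotropic B value and element.

#' Read atomic records from a PDB or mmCIF file
#'
#' Returns one record per ATOM/HETATM. Alternate locations are reduced to
#' the highest-occupancy conformer per atom; hydrogens are kept when
#' present. Waters are kept (they carry density like any other atom);
#' callers may filter on \code{resname}.
#'
#' @param path a PDB (.pdb/.ent) or mmCIF (.cif/.mmcif) file.
#' @return data.frame with columns \code{x,y,z} (Angstrom), \code{occ} in
#'   [0,1], \code{b} (Angstrom^2, >= 0), \code{element}, \code{resname},
#'   \code{resno}, \code{chain}, \code{name}.
#' @export
read_atoms <- function(path) {
  if (!file.exists(path)) stop("read_atoms: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (length(readLines(path, warn = FALSE)) == 0) return(empty_atoms())
  atoms <- if (ext %in% c("cif", "mmcif")) {
    read_atoms_cif(path)
  } else {
    read_atoms_pdb(path)
  }
  if (nrow(atoms) == 0) return(empty_atoms())
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("read_atoms: non-numeric coordinates in ", path)
  }
  atoms$occ[!is.finite(atoms$occ)] <- 1
  atoms$occ <- pmin(pmax(atoms$occ, 0), 1)
  atoms$b[!is.finite(atoms$b) | atoms$b < 0] <- 0
  atoms
}

empty_atoms <- function() {
  data.frame(
    x = numeric(0), y = numeric(0), z = numeric(0),
    occ = numeric(0), b = numeric(0), element = character(0),
    resname = character(0), resno = integer(0), chain = character(0),
    name = character(0), stringsAsFactors = FALSE
  )
}

read_atoms_pdb <- function(path) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE, multi = FALSE),
    error = function(e) stop("read_atoms: cannot parse PDB file ", path, ": ",
      conditionMessage(e)))
  at <- pdb$atom
  df <- data.frame(
    x = at$x, y = at$y, z = at$z,
    occ = at$o, b = at$b,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
      toupper(substr(trimws(at$elety), 1, 1)), trimws(at$elesy)),
    resname = at$resid, resno = at$resno, chain = at$chain,
    name = trimws(at$elety),
    alt = at$alt,
    stringsAsFactors = FALSE
  )
  collapse_altlocs(df)
}

# Loop-based atom_site parser for the supported mmCIF subset (position,
# occupancy, B, element plus identifiers).
read_atoms_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loop_start <- grep("^\\s*loop_\\s*$", lines)
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (length(hdr_idx) == 0) stop("read_atoms: no _atom_site loop in ", path)
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  body_start <- max(hdr_idx) + 1
  rows <- list()
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
      startsWith(ln, "loop_") || startsWith(ln, "data_")) break
    tok <- strsplit(ln, "\\s+")[[1]]
    if (length(tok) != length(fields)) {
      stop("read_atoms: unparseable atom_site row at line ", i, " of ", path)
    }
    rows[[length(rows) + 1]] <- tok
  }
  if (length(rows) == 0) return(empty_atoms())
  m <- do.call(rbind, rows)
  colnames(m) <- fields
  get <- function(nm, default = NA) {
    if (nm %in% fields) m[, nm] else rep(default, nrow(m))
  }
  df <- data.frame(
    x = as.numeric(get("Cartn_x")), y = as.numeric(get("Cartn_y")),
    z = as.numeric(get("Cartn_z")),
    occ = suppressWarnings(as.numeric(get("occupancy", "1"))),
    b = suppressWarnings(as.numeric(get("B_iso_or_equiv", "0"))),
    element = as.character(get("type_symbol", "C")),
    resname = as.character(get("label_comp_id", "")),
    resno = suppressWarnings(as.integer(get("label_seq_id", "0"))),
    chain = as.character(get("label_asym_id", "")),
    name = as.character(get("label_atom_id", "")),
    alt = as.character(get("label_alt_id", "")),
    stringsAsFactors = FALSE
  )
  collapse_altlocs(df)
}

# keep the highest-occupancy conformer of each altloc group
collapse_altlocs <- function(df) {
  df$alt[is.na(df$alt) | df$alt %in% c(".", "?")] <- ""
  key <- paste(df$chain, df$resno, df$resname, df$name, sep = "|")
  keep <- rep(TRUE, nrow(df))
  dup_keys <- unique(key[duplicated(key)])
  for (k in dup_keys) {
    idx <- which(key == k)
    if (length(unique(df$alt[idx])) > 1) {
      best <- idx[which.max(df$occ[idx])]
      keep[idx] <- FALSE
      keep[best] <- TRUE
    }
  }
  df <- df[keep, , drop = FALSE]
  df$alt <- NULL
  rownames(df) <- NULL
  df
}

#' Write atoms as a minimal PDB file
#'
#' Intended for carrying per-atom correlation values in the B-factor column
#' for visualisation, and for round-tripping transformed coordinates.
#'
#' @param atoms data.frame as returned by [read_atoms()].
#' @param path output path.
#' @param b optional numeric vector replacing the B column (e.g. per-atom
#'   correlation values); NA entries are written as 0.00.
#' @return invisibly, \code{path}.
#' @export
write_atoms <- function(atoms, path, b = NULL) {
  if (!is.null(b)) {
    stopifnot(length(b) == nrow(atoms))
    atoms$b <- ifelse(is.finite(b), b, 0)
  }
  nm <- atoms$name; nm[is.na(nm) | nm == ""] <- "X"
  rn <- atoms$resname; rn[is.na(rn) | rn == ""] <- "UNK"
  ch <- atoms$chain; ch[is.na(ch) | ch == ""] <- "A"
  no <- atoms$resno; no[is.na(no)] <- seq_len(nrow(atoms))[is.na(no)]
  el <- atoms$element; el[is.na(el)] <- "C"
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i %% 100000, substr(nm[i], 1, 4), substr(rn[i], 1, 3),
      substr(ch[i], 1, 1), no[i] %% 10000,
      atoms$x[i], atoms$y[i], atoms$z[i], atoms$occ[i], atoms$b[i], el[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
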