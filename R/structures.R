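# Reading protein-ligand complexes from PDB files.
#
# A `pharm_complex` holds the protein atoms, the atoms of exactly one bound
# ligand residue (waters excluded), any CONECT bonds among ligand atoms, and
# (after assign_pharm_roles) the ligand-atom pharmacophore roles.

WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O", "TIP", "SOL")

#' Read a protein-ligand complex from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), keeps altLoc `'A'` or blank, drops
#' waters, and selects exactly one HETATM residue group as the ligand.
#' CONECT records, when present, are kept as explicit ligand bonds.
#'
#' @param pdb Path to a PDB file, or a character string of PDB-format text
#'   (anything containing a newline is treated as text).
#' @param ligand Ligand selector: a residue name (e.g. `"LIG"`), or
#'   `"resname:chain:resno"` to disambiguate.
#' @param complex_id Identifier for the complex; defaults to the file name.
#' @return A `pharm_complex` object: list with `complex_id`,
#'   `protein_atoms`, `ligand_atoms` (tibbles), `bonds`, `ligand_roles`.
#' @export
read_complex <- function(pdb, ligand, complex_id = NULL) {
  if (length(pdb) != 1L || !is.character(pdb)) {
    stopf("`pdb` must be a single path or PDB text string")
  }
  is_text <- grepl("\n", pdb, fixed = TRUE)
  path <- pdb
  if (is_text) {
    path <- tempfile(fileext = ".pdb")
    writeLines(strsplit(pdb, "\n", fixed = TRUE)[[1L]], path)
    on.exit(unlink(path))
  } else if (!file.exists(path)) {
    stopf("PDB file not found: %s", path, class = "pharmboost_input_error")
  }
  if (is.null(complex_id)) {
    complex_id <- if (is_text) "complex" else sub("\\.pdb$", "", basename(path))
  }

  parsed <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stopf("failed to parse PDB input: %s", conditionMessage(e),
                              class = "pharmboost_input_error")
  )
  at <- as_tibble(parsed$atom)
  if (!nrow(at)) stopf("no ATOM/HETATM records found", class = "pharmboost_input_error")
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]

  atoms <- tibble(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    element = pdb_element(at),
    residue_name = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "", at$chain),
    residue_seq = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    formal_charge = pdb_formal_charge(at),
    record = at$type
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stopf("non-finite coordinates in PDB input", class = "pharmboost_input_error")
  }

  het <- atoms[atoms$record == "HETATM" &
                 !(atoms$residue_name %in% WATER_RESIDUES), , drop = FALSE]
  groups <- dplyr::distinct(het, .data$residue_name, .data$chain,
                            .data$residue_seq, .data$insert)
  sel <- parse_ligand_selector(ligand)
  hit <- groups[groups$residue_name == sel$resname, , drop = FALSE]
  if (!is.na(sel$chain)) hit <- hit[hit$chain == sel$chain, , drop = FALSE]
  if (!is.na(sel$resno)) hit <- hit[hit$residue_seq == sel$resno, , drop = FALSE]
  if (nrow(hit) == 0L) {
    stopf("ligand selector '%s' matched no HETATM residue group", ligand,
          class = "pharmboost_selector_error")
  }
  if (nrow(hit) > 1L) {
    cands <- sprintf("%s:%s:%d", hit$residue_name, hit$chain, hit$residue_seq)
    stopf("ligand selector '%s' is ambiguous; candidates: %s", ligand,
          paste(cands, collapse = ", "), class = "pharmboost_ambiguity_error")
  }

  is_lig <- atoms$record == "HETATM" &
    atoms$residue_name == hit$residue_name &
    atoms$chain == hit$chain &
    atoms$residue_seq == hit$residue_seq &
    atoms$insert == hit$insert
  ligand_atoms <- atoms[is_lig, , drop = FALSE]
  protein_atoms <- atoms[atoms$record == "ATOM", , drop = FALSE]
  if (!nrow(protein_atoms)) {
    stopf("no protein (ATOM) records in input", class = "pharmboost_malformed_error")
  }

  bonds <- if (is_text || file.exists(path)) parse_conect(path, ligand_atoms$serial)
           else NULL

  structure(
    list(complex_id = complex_id,
         protein_atoms = protein_atoms[setdiff(names(protein_atoms), "record")],
         ligand_atoms = ligand_atoms[setdiff(names(ligand_atoms), "record")],
         bonds = bonds,
         ligand_roles = NULL),
    class = "pharm_complex"
  )
}

parse_ligand_selector <- function(ligand) {
  if (length(ligand) != 1L || !is.character(ligand) || !nzchar(ligand)) {
    stopf("`ligand` must be a non-empty selector string",
          class = "pharmboost_selector_error")
  }
  parts <- strsplit(ligand, ":", fixed = TRUE)[[1L]]
  list(resname = parts[1L],
       chain = if (length(parts) >= 2L && nzchar(parts[2L])) parts[2L] else NA_character_,
       resno = if (length(parts) >= 3L) as.integer(parts[3L]) else NA_integer_)
}

# Element symbol: PDB column 77-78 when present, else from the atom name.
pdb_element <- function(at) {
  el <- trimws(at$elesy)
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    nm <- gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", trimws(at$elety[miss])))
    two <- toupper(substr(nm, 1, 2)) %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE")
    el[miss] <- ifelse(two, substr(nm, 1, 2), substr(nm, 1, 1))
  }
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 10)))
}

# PDB charge column is "1+", "2-", ...; empty means 0.
pdb_formal_charge <- function(at) {
  ch <- trimws(as.character(at$charge %||% ""))
  out <- integer(nrow(at))
  has <- !is.na(ch) & ch != "" & ch != "0"
  if (any(has)) {
    v <- ch[has]
    sign <- ifelse(grepl("-", v, fixed = TRUE), -1L, 1L)
    num <- suppressWarnings(as.integer(gsub("[^0-9]", "", v)))
    num[is.na(num)] <- 1L
    out[has] <- sign * num
  }
  out
}

# CONECT records restricted to bonds among ligand atoms.
parse_conect <- function(path, ligand_serials) {
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) character())
  lines <- lines[startsWith(lines, "CONECT")]
  if (!length(lines)) return(NULL)
  rows <- list()
  for (ln in lines) {
    flds <- suppressWarnings(as.integer(
      substring(ln, seq(7, 27, by = 5), seq(11, 31, by = 5))))
    flds <- flds[!is.na(flds)]
    if (length(flds) >= 2L) {
      from <- flds[1L]
      for (to in flds[-1L]) {
        if (from %in% ligand_serials && to %in% ligand_serials) {
          rows[[length(rows) + 1L]] <- c(min(from, to), max(from, to))
        }
      }
    }
  }
  if (!length(rows)) return(NULL)
  m <- unique(do.call(rbind, rows))
  tibble(serial_a = as.integer(m[, 1L]), serial_b = as.integer(m[, 2L]))
}

#' @export
print.pharm_complex <- function(x, ...) {
  nr <- if (is.null(x$ligand_roles)) "unassigned" else
    sprintf("%d role records", nrow(x$ligand_roles))
  cat(sprintf("<pharm_complex> '%s': %d protein atoms, %d ligand atoms (%s), roles: %s\n",
              x$complex_id, nrow(x$protein_atoms), nrow(x$ligand_atoms),
              paste(unique(x$ligand_atoms$residue_name), collapse = ","), nr))
  invisible(x)
}

#' Render a complex back to PDB-format text
#'
#' Writes ATOM records for the protein, HETATM records for the ligand, and
#' CONECT records for any explicit ligand bonds. Used mainly by the synthetic
#' generator to exercise the full file-based pipeline.
#'
#' @param complex A `pharm_complex`.
#' @return A single PDB-format string.
#' @export
as_pdb_text <- function(complex) {
  fmt <- function(a, rec) {
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s%2s",
            rec, a$serial,
            ifelse(nchar(a$name) >= 4, a$name, paste0(" ", a$name)),
            " ", a$residue_name, ifelse(a$chain == "", " ", a$chain),
            a$residue_seq, ifelse(a$insert == "", " ", a$insert),
            a$x, a$y, a$z, 1, 0, toupper(a$element),
            ifelse(a$formal_charge == 0, "  ",
                   paste0(abs(a$formal_charge),
                          ifelse(a$formal_charge > 0, "+", "-"))))
  }
  lines <- c(fmt(complex$protein_atoms, "ATOM"),
             fmt(complex$ligand_atoms, "HETATM"))
  if (!is.null(complex$bonds) && nrow(complex$bonds)) {
    lines <- c(lines, sprintf("CONECT%5d%5d",
                              complex$bonds$serial_a, complex$bonds$serial_b))
  }
  paste(c(lines, "END", ""), collapse = "\n")
}
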