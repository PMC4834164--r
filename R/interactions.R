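# Detection of the six protein-ligand interaction types:
# hydrogen bond with ligand acceptor / ligand donor / undetermined roles,
# ionic with ligand cation / ligand anion, and hydrophobic contact.
#
# The geometric cutoffs are conventional medicinal-chemistry defaults (the
# fingerprint definition itself is cutoff-agnostic); all are configurable.

#' Geometric parameters for interaction detection
#'
#' @param hbond_max_dist Donor-heavy-atom to acceptor-heavy-atom cutoff for
#'   hydrogen bonds, in Angstroms (default 3.5).
#' @param hbond_min_angle Minimum D-H...A angle in degrees (default 120);
#'   only enforced when explicit hydrogens are present on the donor.
#' @param ionic_max_dist Cutoff for opposite-formal-charge contacts (default 4.0 A).
#' @param hydrophobic_max_dist Cutoff for apolar carbon-carbon contacts
#'   (default 4.5 A).
#' @return A list of class `interaction_params`.
#' @export
interaction_params <- function(hbond_max_dist = 3.5, hbond_min_angle = 120,
                               ionic_max_dist = 4.0, hydrophobic_max_dist = 4.5) {
  assert_number(hbond_max_dist, "hbond_max_dist", lower = 1e-9)
  assert_number(ionic_max_dist, "ionic_max_dist", lower = 1e-9)
  assert_number(hydrophobic_max_dist, "hydrophobic_max_dist", lower = 1e-9)
  assert_number(hbond_min_angle, "hbond_min_angle", lower = 1e-9, upper = 180)
  structure(list(hbond_max_dist = hbond_max_dist,
                 hbond_min_angle = hbond_min_angle,
                 ionic_max_dist = ionic_max_dist,
                 hydrophobic_max_dist = hydrophobic_max_dist),
            class = "interaction_params")
}

# Role table for standard protein residues, keyed by residue/atom name.
# Backbone N donates, backbone O accepts; side chains per convention;
# apolar side-chain carbons are the hydrophobic partners.
protein_atom_roles <- function(atoms) {
  res <- atoms$residue_name
  nm <- atoms$name
  el <- atoms$element
  role_of <- function(i) {
    r <- res[i]; n <- nm[i]
    if (n == "N" && r != "PRO") return("DONOR")
    if (n %in% c("O", "OXT")) return("ACCEPTOR")
    key <- paste(r, n)
    side <- c(
      "SER OG" = "DONOR|ACCEPTOR", "THR OG1" = "DONOR|ACCEPTOR",
      "TYR OH" = "DONOR|ACCEPTOR",
      "ASN OD1" = "ACCEPTOR", "ASN ND2" = "DONOR",
      "GLN OE1" = "ACCEPTOR", "GLN NE2" = "DONOR",
      "ASP OD1" = "ACCEPTOR|ANION", "ASP OD2" = "ACCEPTOR|ANION",
      "GLU OE1" = "ACCEPTOR|ANION", "GLU OE2" = "ACCEPTOR|ANION",
      "LYS NZ" = "DONOR|CATION",
      "ARG NE" = "DONOR|CATION", "ARG NH1" = "DONOR|CATION",
      "ARG NH2" = "DONOR|CATION",
      "HIS ND1" = "DONOR_OR_ACCEPTOR", "HIS NE2" = "DONOR_OR_ACCEPTOR",
      "TRP NE1" = "DONOR", "CYS SG" = "DONOR", "MET SD" = "ACCEPTOR"
    )
    if (!is.na(side[key])) return(side[[key]])
    apolar <- c(
      ALA = "CB", VAL = "CB CG1 CG2", LEU = "CB CG CD1 CD2",
      ILE = "CB CG1 CG2 CD1", PHE = "CB CG CD1 CD2 CE1 CE2 CZ",
      TRP = "CB CG CD2 CE3 CZ2 CZ3 CH2", MET = "CB CG CE",
      PRO = "CB CG CD", LYS = "CB CG CD", ARG = "CB CG",
      GLU = "CB CG", GLN = "CB CG", ASP = "CB", ASN = "CB",
      HIS = "CB", THR = "CG2", TYR = "CB CG CD1 CD2 CE1 CE2"
    )
    if (el[i] == "C" && !is.na(apolar[r]) &&
        n %in% strsplit(apolar[[r]], " ")[[1L]]) {
      return("HYDROPHOBE")
    }
    NA_character_
  }
  roles <- vapply(seq_len(nrow(atoms)), role_of, character(1))
  tibble(serial = atoms$serial, roles = roles)
}

hb_capability <- function(roles) {
  don <- any(roles %in% c("DONOR", "DONOR_OR_ACCEPTOR"))
  acc <- any(roles %in% c("ACCEPTOR", "DONOR_OR_ACCEPTOR"))
  c(don = don, acc = acc)
}

#' Detect protein-ligand interactions
#'
#' Scans ligand-protein atom pairs against the geometric criteria and the
#' pharmacophore roles of both sides. Hydrogen-bond direction is taken from
#' the ligand atom's roles: a pure acceptor gives `HB_LIG_ACCEPTOR`, a pure
#' donor `HB_LIG_DONOR`; when the ligand atom could be either (e.g. a
#' hydroxyl with no explicit hydrogen) the bond is recorded as
#' `HB_UNDETERMINED`. An ionic contact suppresses a hydrogen bond on the
#' same atom pair. The result is sorted by (ligand serial, protein serial,
#' type) and is invariant under rigid motions of the complex.
#'
#' @param complex A `pharm_complex` with `ligand_roles` assigned.
#' @param params An [interaction_params()] object.
#' @return A tibble with columns `complex_id`, `itype`, `ligand_serial`,
#'   `protein_serial`, `ligand_name`, `protein_name`, `residue`, `distance`,
#'   and the ligand atom coordinates `lig_x`, `lig_y`, `lig_z`.
#' @export
detect_interactions <- function(complex, params = interaction_params()) {
  stopifnot(inherits(complex, "pharm_complex"))
  if (is.null(complex$ligand_roles)) {
    stopf("ligand roles not assigned; run assign_pharm_roles() first")
  }
  empty <- tibble(complex_id = character(), itype = character(),
                  ligand_serial = integer(), protein_serial = integer(),
                  ligand_name = character(), protein_name = character(),
                  residue = character(), distance = double(),
                  lig_x = double(), lig_y = double(), lig_z = double())
  la <- complex$ligand_atoms
  pa <- complex$protein_atoms
  if (!nrow(la) || !nrow(complex$ligand_roles)) return(empty)

  prot_roles <- protein_atom_roles(pa)
  lig_role_list <- split(complex$ligand_roles$role, complex$ligand_roles$serial)

  lxyz <- as.matrix(la[, c("x", "y", "z")])
  pxyz <- as.matrix(pa[, c("x", "y", "z")])
  maxcut <- max(params$hbond_max_dist, params$ionic_max_dist,
                params$hydrophobic_max_dist)
  d2 <- outer(rowSums(lxyz^2), rowSums(pxyz^2), "+") - 2 * tcrossprod(lxyz, pxyz)
  d2[d2 < 0] <- 0
  dmat <- sqrt(d2)
  cand <- which(dmat <= maxcut, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)

  # explicit hydrogens bonded to each ligand atom (for the angle criterion)
  lig_h <- la[la$element == "H", , drop = FALSE]

  rows <- list()
  for (r in seq_len(nrow(cand))) {
    il <- cand[r, 1L]; ip <- cand[r, 2L]
    dist <- dmat[il, ip]
    lser <- la$serial[il]
    lroles <- lig_role_list[[as.character(lser)]]
    if (is.null(lroles)) next
    proles <- strsplit(prot_roles$roles[ip] %||% NA_character_, "|", fixed = TRUE)[[1L]]
    if (length(proles) == 1L && is.na(proles)) proles <- character()

    types <- character()
    # ionic first; it suppresses a hydrogen bond on the same pair
    ionic <- FALSE
    if (dist <= params$ionic_max_dist) {
      if ("CATION" %in% lroles && "ANION" %in% proles) {
        types <- c(types, "IONIC_LIG_CATION"); ionic <- TRUE
      } else if ("ANION" %in% lroles && "CATION" %in% proles) {
        types <- c(types, "IONIC_LIG_ANION"); ionic <- TRUE
      }
    }
    if (!ionic && dist <= params$hbond_max_dist && length(proles)) {
      lc <- hb_capability(lroles); pc <- hb_capability(proles)
      ht <- NA_character_
      if (lc["don"] && lc["acc"]) {
        # ambiguous ligand atom: try to resolve with an explicit hydrogen
        resolved <- FALSE
        if (nrow(lig_h)) {
          hd <- sqrt((lig_h$x - la$x[il])^2 + (lig_h$y - la$y[il])^2 +
                       (lig_h$z - la$z[il])^2)
          hs <- which(hd < 1.3)
          if (length(hs)) {
            ang <- dha_angle(la[il, ], lig_h[hs, , drop = FALSE], pa[ip, ])
            if (pc["acc"] && max(ang) >= params$hbond_min_angle) {
              ht <- "HB_LIG_DONOR"; resolved <- TRUE
            }
          }
        }
        if (!resolved && (pc["don"] || pc["acc"])) ht <- "HB_UNDETERMINED"
      } else if (lc["acc"] && pc["don"]) {
        ht <- "HB_LIG_ACCEPTOR"
      } else if (lc["don"] && pc["acc"]) {
        ht <- "HB_LIG_DONOR"
        if (nrow(lig_h)) {
          hd <- sqrt((lig_h$x - la$x[il])^2 + (lig_h$y - la$y[il])^2 +
                       (lig_h$z - la$z[il])^2)
          hs <- which(hd < 1.3)
          if (length(hs)) {
            ang <- dha_angle(la[il, ], lig_h[hs, , drop = FALSE], pa[ip, ])
            if (max(ang) < params$hbond_min_angle) ht <- NA_character_
          }
        }
      }
      if (!is.na(ht)) types <- c(types, ht)
    }
    if (dist <= params$hydrophobic_max_dist &&
        "HYDROPHOBE" %in% lroles && "HYDROPHOBE" %in% proles) {
      types <- c(types, "HYDROPHOBIC")
    }
    for (tp in types) {
      rows[[length(rows) + 1L]] <- tibble(
        complex_id = complex$complex_id, itype = tp,
        ligand_serial = lser, protein_serial = pa$serial[ip],
        ligand_name = la$name[il], protein_name = pa$name[ip],
        residue = paste0(pa$residue_name[ip], pa$residue_seq[ip]),
        distance = dist,
        lig_x = la$x[il], lig_y = la$y[il], lig_z = la$z[il])
    }
  }
  if (!length(rows)) return(empty)
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$ligand_serial, .data$protein_serial, .data$itype)
}

# D-H...A angle in degrees for each hydrogen row.
dha_angle <- function(donor, hydrogens, acceptor) {
  vapply(seq_len(nrow(hydrogens)), function(i) {
    h <- c(hydrogens$x[i], hydrogens$y[i], hydrogens$z[i])
    dvec <- c(donor$x, donor$y, donor$z) - h
    avec <- c(acceptor$x, acceptor$y, acceptor$z) - h
    cosv <- sum(dvec * avec) / (sqrt(sum(dvec^2)) * sqrt(sum(avec^2)))
    acos(pmin(1, pmax(-1, cosv))) * 180 / pi
  }, double(1))
}

#' Export an interaction list as TSV
#'
#' Columns: `complex_id`, `itype`, `ligand_serial`, `protein_serial`,
#' `distance`.
#'
#' @param interactions Tibble from [detect_interactions()] (rows from several
#'   complexes may be bound together).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(interactions, path) {
  readr::write_tsv(interactions[, c("complex_id", "itype", "ligand_serial",
                                    "protein_serial", "distance")], path)
  invisible(path)
}
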