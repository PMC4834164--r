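# Ligand pharmacophore role assignment.
#
# Roles mirror the ligand-side feature of the six interaction types: DONOR,
# ACCEPTOR, DONOR_OR_ACCEPTOR, CATION, ANION, HYDROPHOBE. Assignment is
# table-driven: an ordered list of (pattern, roles) rules, where each pattern
# is a named structural predicate on the atom's element, formal charge and
# bonded neighborhood. First matching rule wins.

PHARM_ROLES <- c("DONOR", "ACCEPTOR", "DONOR_OR_ACCEPTOR",
                 "CATION", "ANION", "HYDROPHOBE")

# Covalent radii (A) for distance-based bond perception.
COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                    P = 1.07, F = 0.57, Cl = 1.02, Br = 1.20, I = 1.39,
                    B = 0.84, Se = 1.20)

#' Default ligand role rules
#'
#' Reads the role-rule table shipped with the package
#' (`extdata/pharm_role_rules.tsv`): ordered rows of `pattern` (a named
#' structural predicate) and `roles` (comma-separated). Editing a copy of
#' this file lets you swap chemistry conventions without code changes.
#'
#' @return A tibble with columns `pattern` and `roles`.
#' @export
default_role_rules <- function() {
  path <- system.file("extdata", "pharm_role_rules.tsv", package = "pharmboost")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  comment = "#")
}

#' Perceive bonds among ligand atoms
#'
#' Uses explicit CONECT bonds when the complex has them; otherwise two atoms
#' are bonded when their distance is below the sum of covalent radii plus
#' 0.4 A slack.
#'
#' @param complex A `pharm_complex`.
#' @return A tibble with columns `serial_a`, `serial_b`, `dist`.
#' @export
ligand_bonds <- function(complex) {
  la <- complex$ligand_atoms
  if (nrow(la) < 2L) {
    return(tibble(serial_a = integer(), serial_b = integer(), dist = double()))
  }
  xyz <- as.matrix(la[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  if (!is.null(complex$bonds) && nrow(complex$bonds)) {
    b <- complex$bonds
    ia <- match(b$serial_a, la$serial)
    ib <- match(b$serial_b, la$serial)
    return(tibble(serial_a = b$serial_a, serial_b = b$serial_b,
                  dist = d[cbind(ia, ib)]))
  }
  rad <- COVALENT_RADII[la$element]
  rad[is.na(rad)] <- 0.77
  cut <- outer(rad, rad, "+") + 0.4
  idx <- which(upper.tri(d) & d < cut & d > 0.1, arr.ind = TRUE)
  tibble(serial_a = la$serial[idx[, 1L]], serial_b = la$serial[idx[, 2L]],
         dist = d[idx])
}

# Per-atom structural descriptors used by the pattern predicates.
ligand_atom_env <- function(complex) {
  la <- complex$ligand_atoms
  bonds <- ligand_bonds(complex)
  el <- stats::setNames(la$element, la$serial)
  chg <- stats::setNames(la$formal_charge, la$serial)
  nbrs <- function(s) {
    c(bonds$serial_b[bonds$serial_a == s], bonds$serial_a[bonds$serial_b == s])
  }
  bond_len <- function(s, t) {
    hit <- (bonds$serial_a == s & bonds$serial_b == t) |
           (bonds$serial_a == t & bonds$serial_b == s)
    if (any(hit)) bonds$dist[hit][1L] else NA_real_
  }
  lapply(stats::setNames(la$serial, la$serial), function(s) {
    nb <- nbrs(s)
    heavy <- nb[el[as.character(nb)] != "H"]
    list(serial = s, element = el[[as.character(s)]],
         charge = chg[[as.character(s)]],
         heavy_neighbors = heavy,
         heavy_elements = unname(el[as.character(heavy)]),
         n_heavy = length(heavy),
         nbrs = nbrs, bond_len = bond_len, elements = el, charges = chg)
  })
}

# Named structural predicates, evaluated against one atom's environment.
role_patterns <- function() {
  carboxylate_like <- function(env) {
    # terminal O on a C that carries >=2 terminal oxygens
    if (env$n_heavy != 1L || env$heavy_elements[1L] != "C") return(FALSE)
    cc <- env$heavy_neighbors[1L]
    onb <- env$nbrs(cc)
    os <- onb[env$elements[as.character(onb)] == "O"]
    term <- vapply(os, function(o) {
      hv <- env$nbrs(o)
      sum(env$elements[as.character(hv)] != "H") == 1L
    }, logical(1))
    sum(term) >= 2L
  }
  group_charge <- function(env) {
    if (env$n_heavy != 1L) return(env$charge)
    cc <- env$heavy_neighbors[1L]
    members <- unique(c(env$serial, cc, env$nbrs(cc)))
    sum(env$charges[as.character(members)], na.rm = TRUE)
  }
  list(
    o_anion = function(env) {
      env$element == "O" &&
        (env$charge < 0 || (carboxylate_like(env) && group_charge(env) < 0))
    },
    o_carbonyl = function(env) {
      env$element == "O" && env$n_heavy == 1L && {
        bl <- env$bond_len(env$serial, env$heavy_neighbors[1L])
        !is.na(bl) && bl < 1.28
      }
    },
    o_hydroxyl = function(env) env$element == "O" && env$n_heavy <= 1L,
    o_ether = function(env) env$element == "O",
    n_cation = function(env) env$element == "N" && env$charge > 0,
    n_primary = function(env) env$element == "N" && env$n_heavy <= 1L,
    n_secondary = function(env) env$element == "N" && env$n_heavy == 2L,
    n_tertiary = function(env) env$element == "N",
    s_thiol = function(env) env$element == "S" && env$n_heavy <= 1L,
    s_thioether = function(env) env$element == "S",
    c_apolar = function(env) {
      env$element == "C" && env$charge == 0 &&
        !any(env$heavy_elements %in% c("N", "O", "S", "P"))
    }
  )
}

#' Assign pharmacophore roles to the ligand atoms of a complex
#'
#' Deterministic, table-driven assignment: bonds are perceived (CONECT or
#' covalent-radius distance), each atom's structural environment is matched
#' against the ordered rule table, and the first matching rule's roles are
#' recorded. Atoms of unknown elements get an empty role set with a warning.
#'
#' @param complex A `pharm_complex`.
#' @param rules Rule table as returned by [default_role_rules()].
#' @return The complex with `ligand_roles` filled: a tibble of
#'   (`serial`, `role`) records (an atom may carry several roles).
#' @export
assign_pharm_roles <- function(complex, rules = default_role_rules()) {
  stopifnot(inherits(complex, "pharm_complex"))
  pats <- role_patterns()
  unknown_pat <- setdiff(rules$pattern, names(pats))
  if (length(unknown_pat)) {
    stopf("unknown role pattern(s) in rule table: %s",
          paste(unknown_pat, collapse = ", "))
  }
  envs <- ligand_atom_env(complex)
  known <- c(names(COVALENT_RADII))
  rows <- list()
  for (env in envs) {
    if (!(env$element %in% known)) {
      warn(sprintf("unknown element '%s' (ligand atom %d): no roles assigned",
                   env$element, env$serial))
      next
    }
    for (r in seq_len(nrow(rules))) {
      if (isTRUE(pats[[rules$pattern[r]]](env))) {
        roles <- trimws(strsplit(rules$roles[r], ",", fixed = TRUE)[[1L]])
        bad <- setdiff(roles, PHARM_ROLES)
        if (length(bad)) stopf("invalid role(s) in rule table: %s",
                               paste(bad, collapse = ", "))
        rows[[length(rows) + 1L]] <- tibble(serial = env$serial, role = roles)
        break
      }
    }
  }
  complex$ligand_roles <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(serial = integer(), role = character())
  complex
}

#' Set ligand roles explicitly
#'
#' Bypasses structural perception; used by the synthetic generator where the
#' planted roles are the ground truth.
#'
#' @param complex A `pharm_complex`.
#' @param roles A tibble with columns `serial` and `role`.
#' @return The complex with `ligand_roles` set.
#' @export
set_pharm_roles <- function(complex, roles) {
  stopifnot(all(c("serial", "role") %in% names(roles)))
  bad <- setdiff(roles$role, PHARM_ROLES)
  if (length(bad)) stopf("invalid role(s): %s", paste(bad, collapse = ", "))
  if (!all(roles$serial %in% complex$ligand_atoms$serial)) {
    stopf("role serials must be ligand atom serials")
  }
  complex$ligand_roles <- as_tibble(roles[, c("serial", "role")])
  complex
}
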