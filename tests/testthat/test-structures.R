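test_that("read_complex parses a minimal complex and honors the ligand selector", {
  txt <- paste(c(pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
                 pdb_line("HETATM", 2, "C1", "LIG", "L", 1, 3, 0, 0, "C"),
                 "END", ""), collapse = "\n")
  cx <- read_complex(txt, "LIG")
  expect_equal(nrow(cx$protein_atoms), 1L)
  expect_equal(nrow(cx$ligand_atoms), 1L)
  expect_equal(cx$ligand_atoms$x, 3, tolerance = 1e-9)

  expect_error(read_complex(txt, "XYZ"), class = "pharmboost_selector_error")

  # two copies of the ligand residue -> ambiguity listing candidates
  txt2 <- paste(c(pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
                  pdb_line("HETATM", 2, "C1", "LIG", "L", 1, 3, 0, 0, "C"),
                  pdb_line("HETATM", 3, "C1", "LIG", "L", 2, 6, 0, 0, "C"),
                  "END", ""), collapse = "\n")
  expect_error(read_complex(txt2, "LIG"), class = "pharmboost_ambiguity_error")
  cx2 <- read_complex(txt2, "LIG:L:2")
  expect_equal(cx2$ligand_atoms$serial, 3L)

  # no protein records at all
  txt3 <- paste(c(pdb_line("HETATM", 2, "C1", "LIG", "L", 1, 3, 0, 0, "C"),
                  "END", ""), collapse = "\n")
  expect_error(read_complex(txt3, "LIG"), class = "pharmboost_malformed_error")
})

test_that("waters are dropped and fixture atom counts are preserved", {
  prot <- lapply(1:10, function(i) {
    pdb_line("ATOM", i, "CA", "GLY", "A", i, i * 4, 0, 0, "C")
  })
  lig <- lapply(1:5, function(i) {
    pdb_line("HETATM", 100 + i, paste0("C", i), "LIG", "L", 1, i * 1.5, 10, 0, "C")
  })
  wat <- lapply(1:3, function(i) {
    pdb_line("HETATM", 200 + i, "O", "HOH", "W", i, 50 + i, 50, 50, "O")
  })
  txt <- paste(c(unlist(prot), unlist(lig), unlist(wat), "END", ""),
               collapse = "\n")
  cx <- read_complex(txt, "LIG")
  expect_equal(nrow(cx$protein_atoms), 10L)
  expect_equal(nrow(cx$ligand_atoms), 5L)
  expect_false(any(cx$ligand_atoms$residue_name == "HOH"))
})

test_that("pharmacophore roles follow the rule table", {
  # charged carboxylate: C bonded to two terminal O, one carrying -1
  lig <- c(pdb_line("HETATM", 10, "C1", "LIG", "L", 1, 10, 10, 10, "C"),
           pdb_line("HETATM", 11, "O1", "LIG", "L", 1, 11.25, 10, 10, "O", "1-"),
           pdb_line("HETATM", 12, "O2", "LIG", "L", 1, 9.4, 10.95, 10, "O"),
           pdb_line("HETATM", 13, "C2", "LIG", "L", 1, 10, 8.5, 10, "C"),
           pdb_line("HETATM", 14, "C3", "LIG", "L", 1, 10, 7.0, 10, "C"))
  cx <- assign_pharm_roles(read_complex(make_pocket_pdb(lig), "LIG"))
  roles_of <- function(s) sort(cx$ligand_roles$role[cx$ligand_roles$serial == s])
  expect_equal(roles_of(11L), c("ACCEPTOR", "ANION"))
  expect_equal(roles_of(12L), c("ACCEPTOR", "ANION"))
  # terminal aliphatic carbon: only C neighbors -> hydrophobe
  expect_equal(roles_of(14L), "HYDROPHOBE")
  # the carboxylate carbon has O neighbors -> not hydrophobic
  expect_length(roles_of(10L), 0L)

  # hydrocarbon ligand: no donors/acceptors anywhere
  hc <- c(pdb_line("HETATM", 20, "C1", "ETH", "L", 1, 10, 10, 10, "C"),
          pdb_line("HETATM", 21, "C2", "ETH", "L", 1, 11.5, 10, 10, "C"))
  cx2 <- assign_pharm_roles(read_complex(make_pocket_pdb(hc), "ETH"))
  expect_false(any(cx2$ligand_roles$role %in% c("DONOR", "ACCEPTOR",
                                                "DONOR_OR_ACCEPTOR")))
})

test_that("interaction typing follows roles, cutoffs and precedence", {
  # carboxylate O(-1) 3.0 A from LYS NZ -> single ionic (not an H-bond too)
  prot <- c(pdb_line("ATOM", 1, "CA", "LYS", "A", 1, 0, 0, 0, "C"),
            pdb_line("ATOM", 2, "NZ", "LYS", "A", 1, 10, 10, 13, "N"))
  lig <- c(pdb_line("HETATM", 10, "C1", "LIG", "L", 1, 10, 10, 8.75, "C"),
           pdb_line("HETATM", 11, "O1", "LIG", "L", 1, 10, 10, 10, "O", "1-"),
           pdb_line("HETATM", 12, "O2", "LIG", "L", 1, 10, 11.2, 8.2, "O"))
  cx <- assign_pharm_roles(read_complex(make_pocket_pdb(lig, prot), "LIG"))
  det <- detect_interactions(cx)
  ionic <- det[det$ligand_serial == 11L, ]
  expect_equal(nrow(ionic), 1L)
  expect_equal(ionic$itype, "IONIC_LIG_ANION")
  expect_equal(ionic$distance, 3.0, tolerance = 1e-9)

  # everything farther than 6 A -> no interactions
  lig_far <- c(pdb_line("HETATM", 10, "C1", "LIG", "L", 1, 50, 50, 50, "C"),
               pdb_line("HETATM", 11, "O1", "LIG", "L", 1, 51.4, 50, 50, "O"))
  cx_far <- assign_pharm_roles(read_complex(make_pocket_pdb(lig_far, prot), "LIG"))
  expect_equal(nrow(detect_interactions(cx_far)), 0L)

  # ligand hydroxyl O at 2.9 A from a backbone carbonyl O, no hydrogens:
  # ambiguous ligand donor/acceptor -> HB_UNDETERMINED
  prot2 <- c(pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
             pdb_line("ATOM", 2, "C", "GLY", "A", 1, 1.5, 0, 0, "C"),
             pdb_line("ATOM", 3, "O", "GLY", "A", 1, 10, 10, 12.9, "O"))
  lig2 <- c(pdb_line("HETATM", 10, "C1", "LIG", "L", 1, 10, 10, 8.57, "C"),
            pdb_line("HETATM", 11, "O1", "LIG", "L", 1, 10, 10, 10, "O"))
  cx2 <- assign_pharm_roles(read_complex(make_pocket_pdb(lig2, prot2), "LIG"))
  det2 <- detect_interactions(cx2)
  hb <- det2[det2$ligand_serial == 11L & det2$protein_serial == 3L, ]
  expect_equal(hb$itype, "HB_UNDETERMINED")
})

test_that("detection is rigid-motion invariant and deterministic", {
  cx <- gen_pocket_complex(c("HB_LIG_DONOR", "IONIC_LIG_ANION", "HYDROPHOBIC"),
                           c(4.3, 6.1, 5.0), seed = 3)
  det1 <- detect_interactions(cx)
  det2 <- detect_interactions(cx)
  expect_identical(det1, det2)

  # a different seed applies a different rigid motion to the same geometry
  cx2 <- gen_pocket_complex(c("HB_LIG_DONOR", "IONIC_LIG_ANION", "HYDROPHOBIC"),
                            c(4.3, 6.1, 5.0), seed = 99)
  det3 <- detect_interactions(cx2)
  expect_equal(det1$itype, det3$itype)
  expect_equal(det1$ligand_serial, det3$ligand_serial)
  expect_equal(det1$distance, det3$distance, tolerance = 1e-9)
})

test_that("enlarging cutoffs never removes interactions", {
  cx <- gen_pocket_complex(c("HB_LIG_ACCEPTOR", "HYDROPHOBIC", "IONIC_LIG_CATION"),
                           c(3.5, 7.2, 5.5), seed = 11)
  base <- detect_interactions(cx, interaction_params())
  wide <- detect_interactions(cx, interaction_params(hbond_max_dist = 4.5,
                                                     ionic_max_dist = 5.5,
                                                     hydrophobic_max_dist = 6.0))
  key <- function(d) paste(d$itype, d$ligand_serial, d$protein_serial)
  expect_true(all(key(base) %in% key(wide)))
})

test_that("interaction lists export to TSV with the documented columns", {
  cx <- gen_pocket_complex(c("HB_LIG_DONOR", "HB_LIG_ACCEPTOR"), 4.3, seed = 1)
  det <- detect_interactions(cx)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_interactions(det, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_named(back, c("complex_id", "itype", "ligand_serial",
                       "protein_serial", "distance"))
  expect_equal(nrow(back), nrow(det))
})
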