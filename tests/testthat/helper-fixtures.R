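# Fixtures built in code: minimal PDB text and small synthetic configs.

pdb_line <- function(record, serial, name, resname, chain, resno, x, y, z,
                     element, charge = "") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s%2s",
          record, serial, ifelse(nchar(name) >= 4, name, paste0(" ", name)),
          " ", resname, chain, resno, " ", x, y, z, 1, 0, element, charge)
}

# a lysine side-chain tip (NZ), a backbone carbonyl (C=O), and a glycine CA
# pocket fragment at configurable positions
make_pocket_pdb <- function(ligand_lines, protein_lines = NULL) {
  if (is.null(protein_lines)) {
    protein_lines <- c(
      pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
      pdb_line("ATOM", 2, "C", "GLY", "A", 1, 1.5, 0, 0, "C"),
      pdb_line("ATOM", 3, "O", "GLY", "A", 1, 2.1, 1.0, 0, "O"),
      pdb_line("ATOM", 4, "NZ", "LYS", "A", 2, 8, 8, 8, "N")
    )
  }
  paste(c(protein_lines, ligand_lines, "END", ""), collapse = "\n")
}

# small-but-structured synthetic config for fast model tests
small_synth <- function(seed = 1L, ...) {
  synth_config(n_active_train = 30L, n_decoy_train = 300L,
               n_active_test_compounds = 20L, n_decoy_test = 100L,
               poses_per_compound = 3L, seed = seed, ...)
}

# pairwise Mann-Whitney AUC oracle (independent of the ROC path)
mw_auc <- function(score, label) {
  a <- score[label == 1L]; d <- score[label == -1L]
  cmp <- outer(a, d, "-")
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(a) * length(d))
}

# brute-force Pharm-IF oracle: double loop over interaction pairs and bins
brute_force_encode <- function(interactions, k_max) {
  tp <- type_pairs()$pair
  H <- matrix(0, nrow = length(tp), ncol = k_max, dimnames = list(tp, NULL))
  n <- nrow(interactions)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (interactions$ligand_serial[i] == interactions$ligand_serial[j]) next
      d <- sqrt((interactions$lig_x[i] - interactions$lig_x[j])^2 +
                  (interactions$lig_y[i] - interactions$lig_y[j])^2 +
                  (interactions$lig_z[i] - interactions$lig_z[j])^2)
      lab <- canonical_type_pair(interactions$itype[i], interactions$itype[j])
      for (k in seq_len(k_max)) {
        w <- max(0, 1 - abs(k - d))
        H[lab, k] <- H[lab, k] + w
      }
    }
  }
  H
}

fp_to_dense <- function(fp) {
  k_max <- attr(fp, "k_max")
  tp <- type_pairs()$pair
  H <- matrix(0, nrow = length(tp), ncol = k_max, dimnames = list(tp, NULL))
  if (nrow(fp)) H[cbind(match(fp$pair, tp), fp$bin)] <- fp$value
  H
}

# deterministic separable 2-D toy set
toy_separable <- function(n = 20L, gap = 4) {
  x <- rbind(cbind(seq_len(n) / n, gap + seq_len(n) %% 3),
             cbind(seq_len(n) / n, -gap - seq_len(n) %% 3))
  list(x = x, y = rep(c(1L, -1L), each = n))
}
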