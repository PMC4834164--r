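# Synthetic benchmark generation.
#
# Two generators: (1) pocket-scale complexes with planted interaction
# geometry, exercising the structures -> fingerprint chain end to end; and
# (2) class-conditional fingerprint samples with the reference experiment's
# composition (100 active vs 2000 decoy training samples, test set of 5
# poses per compound) and a wrong-docking-pose noise process that replaces a
# fraction of positive training samples with decoy-distributed features.

#' Synthetic benchmark configuration
#'
#' Defaults reproduce the reference composition: 2100 training rows (100
#' positive / 2000 negative, 20:1 imbalance) and 10500 test rows (100 active
#' compounds and 2000 decoy compounds, 5 docking poses each).
#'
#' Free parameters model what docking-derived Pharm-IF data looks like:
#' a conserved pocket "scaffold" profile shared by every pose (the binding
#' -site contacts any docked molecule makes), a small set of signal channels
#' carried by true binders, decoy chemotype clusters with their own channel
#' profiles, sparse pose-specific noise, and within-compound pose
#' correlation.
#'
#' @param n_active_train,n_decoy_train Training composition (100 / 2000).
#' @param n_active_test_compounds,n_decoy_test Test compounds per class
#'   (100 / 2000), each expanded to `poses_per_compound` rows.
#' @param poses_per_compound Docking poses generated per compound (5).
#' @param pose_noise_rate Fraction of positive training samples replaced by
#'   decoy-distributed features, keeping label +1 (default 0.15).
#' @param train_active_compounds Number of distinct active compounds behind
#'   the training positives (default `n_active_train / poses_per_compound`).
#' @param signal_channels Integer indices of the active-class signal
#'   channels; `NULL` picks `n_signal_channels` at random from the seed.
#' @param n_signal_channels,signal_strength Count (6) and mean magnitude
#'   (1.8) of the active-specific fingerprint signal. Binding strength is
#'   bimodal across active compounds: most are potent binders with a tight
#'   strength distribution around `signal_strength`, the rest marginal
#'   binders in the decoy-mimic range.
#' @param signal_expr_prob Probability that a marginal binder or mimic
#'   expresses each signal channel (partial pharmacophore match, 0.9);
#'   potent binders express the full pharmacophore.
#' @param k_max Fingerprint bins; feature dimension is `21 * k_max`.
#' @param n_scaffold_channels,scaffold_scale,scaffold_jitter Shared pocket
#'   profile: channel count (100), exponential mean (2.5), log-normal
#'   jitter sd (0.02).
#' @param n_noise_channels,noise_scale Sparse pose-specific noise: channels
#'   per pose (2) and exponential mean (0.2).
#' @param n_decoy_clusters,cluster_channels,cluster_scale Compound chemotype
#'   clusters (30, shared by actives and decoys) with `cluster_channels`
#'   (3) profile channels of mean `cluster_scale` (0.5).
#' @param decoy_signal_prob,decoy_signal_frac Chance (0.25) and relative
#'   magnitude (0.5) of a decoy compound being a docking false positive
#'   that expresses the signal channels (tail-capped strength).
#' @param corruption_modes Number of recurring wrong-binding-mode chemotypes
#'   the corrupted poses are drawn from (default 2; 0 = spread over all
#'   decoy chemotypes). Incorrect docking poses are not arbitrary: similar
#'   active compounds mis-dock into a small set of alternative binding
#'   modes, so their decoy-like fingerprints concentrate.
#' @param pose_cor Within-compound correlation of pose jitter (0.7).
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_active_train = 100L, n_decoy_train = 2000L,
                         n_active_test_compounds = 100L,
                         poses_per_compound = 5L, n_decoy_test = 2000L,
                         pose_noise_rate = 0.15,
                         train_active_compounds = NULL,
                         signal_channels = NULL, n_signal_channels = 6L,
                         signal_strength = 1.8, signal_expr_prob = 0.9,
                         k_max = 20L,
                         n_scaffold_channels = 100L, scaffold_scale = 2.5,
                         scaffold_jitter = 0.02,
                         n_noise_channels = 2L, noise_scale = 0.2,
                         n_decoy_clusters = 30L, cluster_channels = 3L,
                         cluster_scale = 0.5,
                         decoy_signal_prob = 0.25, decoy_signal_frac = 0.5,
                         corruption_modes = 2L,
                         pose_cor = 0.7, seed = 1L) {
  assert_number(pose_noise_rate, "pose_noise_rate", lower = 0, upper = 1 - 1e-12)
  assert_number(pose_cor, "pose_cor", lower = 0, upper = 1)
  if (is.null(train_active_compounds)) {
    train_active_compounds <- max(1L, ceiling(n_active_train / poses_per_compound))
  }
  cfg <- list(n_active_train = as.integer(n_active_train),
              n_decoy_train = as.integer(n_decoy_train),
              n_active_test_compounds = as.integer(n_active_test_compounds),
              poses_per_compound = as.integer(poses_per_compound),
              n_decoy_test = as.integer(n_decoy_test),
              pose_noise_rate = pose_noise_rate,
              train_active_compounds = as.integer(train_active_compounds),
              signal_channels = signal_channels,
              n_signal_channels = as.integer(n_signal_channels),
              signal_strength = signal_strength,
              signal_expr_prob = signal_expr_prob,
              k_max = as.integer(k_max),
              n_scaffold_channels = as.integer(n_scaffold_channels),
              scaffold_scale = scaffold_scale,
              scaffold_jitter = scaffold_jitter,
              n_noise_channels = as.integer(n_noise_channels),
              noise_scale = noise_scale,
              n_decoy_clusters = as.integer(n_decoy_clusters),
              cluster_channels = as.integer(cluster_channels),
              cluster_scale = cluster_scale,
              decoy_signal_prob = decoy_signal_prob,
              decoy_signal_frac = decoy_signal_frac,
              corruption_modes = as.integer(corruption_modes),
              pose_cor = pose_cor, seed = as.integer(seed))
  structure(cfg, class = "synth_config")
}

# Fixed per-dataset channel layout and profiles, drawn once from the seed.
synth_generator_state <- function(cfg) {
  d <- 21L * cfg$k_max
  need <- cfg$n_scaffold_channels + cfg$n_signal_channels +
    cfg$n_decoy_clusters * cfg$cluster_channels
  if (need > d) stopf("channel layout needs %d channels but only %d exist", need, d)
  perm <- sample.int(d)
  scaffold_idx <- perm[seq_len(cfg$n_scaffold_channels)]
  off <- cfg$n_scaffold_channels
  signal_idx <- cfg$signal_channels %||%
    perm[off + seq_len(cfg$n_signal_channels)]
  off <- off + cfg$n_signal_channels
  cluster_idx <- matrix(perm[off + seq_len(cfg$n_decoy_clusters * cfg$cluster_channels)],
                        nrow = cfg$n_decoy_clusters, byrow = TRUE)
  list(d = d,
       scaffold_idx = scaffold_idx,
       scaffold_mu = stats::rexp(cfg$n_scaffold_channels, rate = 1 / cfg$scaffold_scale),
       signal_idx = as.integer(signal_idx),
       cluster_idx = cluster_idx,
       cluster_mu = matrix(stats::rexp(length(cluster_idx), rate = 1 / cfg$cluster_scale),
                           nrow = nrow(cluster_idx)))
}

# Rows for one compound (active or decoy) with correlated pose jitter.
# Every compound carries the shared pocket scaffold and a chemotype-cluster
# profile (actives and decoys draw from the same chemotype pool); only the
# signal channels are class-informative.
synth_compound_rows <- function(kind, n_poses, gen, cfg, cluster = NULL) {
  rho <- cfg$pose_cor
  mat <- matrix(0, nrow = n_poses, ncol = gen$d)
  # shared pocket scaffold with compound + pose log-normal jitter
  e_comp <- stats::rnorm(length(gen$scaffold_idx), sd = cfg$scaffold_jitter)
  for (p in seq_len(n_poses)) {
    e_pose <- stats::rnorm(length(gen$scaffold_idx), sd = cfg$scaffold_jitter)
    jit <- sqrt(rho) * e_comp + sqrt(1 - rho) * e_pose
    mat[p, gen$scaffold_idx] <- gen$scaffold_mu * exp(jit)
  }
  # chemotype-cluster profile
  g <- cluster %||% sample.int(nrow(gen$cluster_idx), 1L)
  prof_comp <- gen$cluster_mu[g, ] *
    exp(stats::rnorm(ncol(gen$cluster_idx), sd = 0.2))
  for (p in seq_len(n_poses)) {
    jit <- exp(sqrt(1 - rho) * stats::rnorm(ncol(gen$cluster_idx), sd = 0.2))
    mat[p, gen$cluster_idx[g, ]] <- mat[p, gen$cluster_idx[g, ]] + prof_comp * jit
  }
  # class signal: actives always express it (scaled by per-compound binding
  # strength); a fraction of decoys are docking false positives that make
  # the same pharmacophore contacts at reduced strength
  express_signal <- kind == "active" ||
    stats::runif(1L) < cfg$decoy_signal_prob
  if (express_signal) {
    # bimodal binding strength: most actives are potent binders that make
    # the full pharmacophore with a tight strength distribution (a dense
    # mode in fingerprint space); the rest are marginal binders whose
    # partial signal sits in the same range as the decoy mimics
    strong <- kind == "active" && stats::runif(1L) < 0.75
    if (strong) {
      expressed <- rep(TRUE, length(gen$signal_idx))
      val_comp <- cfg$signal_strength *
        stats::rgamma(1L, shape = 100, rate = 100) *
        stats::rgamma(length(gen$signal_idx), shape = 50, rate = 50)
    } else {
      mult <- if (kind == "active") {
        0.2 * stats::rgamma(1L, shape = 1.5, rate = 1.5)
      } else {
        # mimics crowd the mid-range but rarely reach potent-binder strength
        cfg$decoy_signal_frac * stats::rgamma(1L, shape = 8, rate = 8)
      }
      expressed <- stats::runif(length(gen$signal_idx)) < cfg$signal_expr_prob
      val_comp <- cfg$signal_strength * mult *
        stats::rgamma(length(gen$signal_idx), shape = 12, rate = 12)
    }
    for (p in seq_len(n_poses)) {
      jit <- exp(sqrt(1 - rho) * stats::rnorm(length(gen$signal_idx), sd = 0.15))
      mat[p, gen$signal_idx] <- mat[p, gen$signal_idx] +
        expressed * val_comp * jit
    }
  }
  # sparse pose-specific spurious contacts
  for (p in seq_len(n_poses)) {
    ch <- sample.int(gen$d, cfg$n_noise_channels)
    mat[p, ch] <- mat[p, ch] + stats::rexp(cfg$n_noise_channels,
                                           rate = 1 / cfg$noise_scale)
  }
  mat
}

#' Generate a class-conditional fingerprint benchmark
#'
#' Builds training and test fingerprint tables with the configured
#' composition, then applies the wrong-pose noise process: a
#' `pose_noise_rate` fraction of the positive training samples get their
#' features replaced by fresh decoy draws while keeping label +1 (their
#' `is_corrupted` flag records the truth). Fully reproducible from the
#' config seed.
#'
#' @param config A [synth_config()].
#' @return A `synth_screen_data` object: list with `train` and `test`
#'   tibbles (`sample_id`, `compound`, `label`, `is_corrupted`, then the
#'   `21 * k_max` fingerprint columns), the frozen `generator` state, and
#'   the `config` echo.
#' @export
gen_fingerprint_samples <- function(config = synth_config()) {
  cfg <- config
  ds <- with_seed(cfg$seed, {
    gen <- synth_generator_state(cfg)
    build_part <- function(part) {
      if (part == "train") {
        n_comp_a <- cfg$train_active_compounds
        poses_a <- cfg$poses_per_compound
        n_keep_a <- cfg$n_active_train
        n_comp_d <- cfg$n_decoy_train
        poses_d <- 1L
      } else {
        n_comp_a <- cfg$n_active_test_compounds
        poses_a <- cfg$poses_per_compound
        n_keep_a <- n_comp_a * poses_a
        n_comp_d <- cfg$n_decoy_test
        poses_d <- cfg$poses_per_compound
      }
      blocks <- vector("list", n_comp_a + n_comp_d)
      meta <- vector("list", n_comp_a + n_comp_d)
      for (c in seq_len(n_comp_a)) {
        blocks[[c]] <- synth_compound_rows("active", poses_a, gen, cfg)
        meta[[c]] <- tibble(compound = sprintf("%s_act_%03d", part, c),
                            label = 1L, pose = seq_len(poses_a))
      }
      for (c in seq_len(n_comp_d)) {
        blocks[[n_comp_a + c]] <- synth_compound_rows("decoy", poses_d, gen, cfg)
        meta[[n_comp_a + c]] <- tibble(compound = sprintf("%s_dec_%04d", part, c),
                                       label = -1L, pose = seq_len(poses_d))
      }
      mat <- do.call(rbind, blocks)
      info <- dplyr::bind_rows(meta)
      keep <- c(seq_len(n_keep_a),
                (n_comp_a * poses_a) + seq_len(n_comp_d * poses_d))
      mat <- mat[keep, , drop = FALSE]
      info <- info[keep, , drop = FALSE]
      colnames(mat) <- fp_feature_names(cfg$k_max)
      dplyr::bind_cols(
        tibble(sample_id = sprintf("%s_%05d", part, seq_len(nrow(mat))),
               compound = info$compound, label = info$label,
               is_corrupted = FALSE),
        as_tibble(mat))
    }
    list(train = build_part("train"), test = build_part("test"))
  })
  out <- structure(list(train = ds$train, test = ds$test,
                        generator = with_seed(cfg$seed, synth_generator_state(cfg)),
                        config = cfg),
                   class = "synth_screen_data")
  corrupt_labels(out, rate = cfg$pose_noise_rate, seed = cfg$seed + 1L)
}

#' Apply the wrong-docking-pose noise process
#'
#' Replaces the features of exactly `floor(rate * n_positives)` positive
#' training samples with fresh decoy-distributed draws; labels stay +1 and
#' `is_corrupted` records the truth. Deterministic for a fixed seed.
#'
#' @param dataset A `synth_screen_data` object.
#' @param rate Fraction of positive training samples to corrupt, `[0, 1)`.
#' @param seed Integer seed for the choice of samples and the decoy draws.
#' @return The dataset with corrupted training rows.
#' @export
corrupt_labels <- function(dataset, rate, seed = dataset$config$seed + 1L) {
  stopifnot(inherits(dataset, "synth_screen_data"))
  assert_number(rate, "rate", lower = 0, upper = 1 - 1e-12)
  pos <- which(dataset$train$label == 1L)
  n_corrupt <- floor(rate * length(pos))
  if (n_corrupt == 0L) return(dataset)
  cfg <- dataset$config
  gen <- dataset$generator
  feat <- fp_feature_names(cfg$k_max)
  with_seed(seed, {
    victims <- sort(sample(pos, n_corrupt))
    modes <- if (cfg$corruption_modes > 0L) {
      sample.int(nrow(gen$cluster_idx), min(cfg$corruption_modes,
                                            nrow(gen$cluster_idx)))
    } else {
      NULL
    }
    repl <- do.call(rbind, lapply(victims, function(i) {
      g <- if (is.null(modes)) NULL else modes[sample.int(length(modes), 1L)]
      synth_compound_rows("decoy", 1L, gen, cfg, cluster = g)
    }))
    for (k in seq_along(feat)) {
      dataset$train[[feat[k]]][victims] <- repl[, k]
    }
    dataset$train$is_corrupted[victims] <- TRUE
  })
  dataset
}

#' @export
print.synth_screen_data <- function(x, ...) {
  cat(sprintf(paste0("<synth_screen_data> train %d rows (%d pos / %d neg, ",
                     "%d corrupted), test %d rows (%d pos / %d neg), seed %d\n"),
              nrow(x$train), sum(x$train$label == 1), sum(x$train$label == -1),
              sum(x$train$is_corrupted), nrow(x$test),
              sum(x$test$label == 1), sum(x$test$label == -1),
              x$config$seed))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Dense fingerprint CSVs (`train_features.csv`, `test_features.csv`, with
#' `sample_id` plus the `"<pair>/<k>"` feature columns), label TSVs
#' (`sample_id`, `label`, `compound`, `is_corrupted`), and a
#' `generator_log.json` echoing the configuration and seed.
#'
#' @param dataset A `synth_screen_data`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synth_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  feat <- fp_feature_names(dataset$config$k_max)
  for (part in c("train", "test")) {
    df <- dataset[[part]]
    readr::write_csv(
      dplyr::bind_cols(tibble(complex_id = df$sample_id), df[feat]),
      file.path(dir, paste0(part, "_features.csv")))
    readr::write_tsv(df[c("sample_id", "label", "compound", "is_corrupted")],
                     file.path(dir, paste0(part, "_labels.tsv")))
  }
  log <- c(list(package_version = as.character(utils::packageVersion("pharmboost"))),
           unclass(dataset$config))
  log$signal_channels <- dataset$generator$signal_idx
  jsonlite::write_json(log, file.path(dir, "generator_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

# ---- planted pocket complexes ----------------------------------------------

# element / roles / protein partner used for each plantable interaction type
PLANT_SPECS <- list(
  HB_LIG_ACCEPTOR = list(element = "O", charge = 0L, roles = "ACCEPTOR",
                         p_res = "GLY", p_name = "N", p_el = "N", p_dist = 2.9),
  HB_LIG_DONOR = list(element = "N", charge = 0L, roles = "DONOR",
                      p_res = "GLY", p_name = "O", p_el = "O", p_dist = 2.9),
  HB_UNDETERMINED = list(element = "O", charge = 0L,
                         roles = c("DONOR", "ACCEPTOR"),
                         p_res = "SER", p_name = "OG", p_el = "O", p_dist = 2.9),
  IONIC_LIG_CATION = list(element = "N", charge = 1L, roles = "CATION",
                          p_res = "ASP", p_name = "OD1", p_el = "O", p_dist = 3.5),
  IONIC_LIG_ANION = list(element = "O", charge = -1L, roles = "ANION",
                         p_res = "LYS", p_name = "NZ", p_el = "N", p_dist = 3.5),
  HYDROPHOBIC = list(element = "C", charge = 0L, roles = "HYDROPHOBE",
                     p_res = "LEU", p_name = "CD1", p_el = "C", p_dist = 4.0)
)

# Embed a set of pairwise distances in 3-D (classical MDS); errors when the
# distance set violates the triangle/embeddability constraints.
embed_distances <- function(D) {
  m <- nrow(D)
  if (m == 1L) return(matrix(0, 1L, 3L))
  J <- diag(m) - matrix(1 / m, m, m)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- 1e-6 * max(1, abs(e$values[1L]))
  if (any(e$values < -tol) || sum(e$values > tol) > 3L) {
    stopf("planted distances are not embeddable in 3-D (triangle violation)",
          class = "pharmboost_generation_error")
  }
  k <- min(3L, sum(e$values > tol))
  X <- matrix(0, m, 3L)
  if (k > 0) {
    X[, seq_len(k)] <- e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
  }
  X
}

#' Generate a pocket complex with planted interactions
#'
#' Places one ligand atom per requested interaction at the requested mutual
#' distances (embedded in 3-D; infeasible distance sets error), puts a
#' protein partner atom of the right role within each interaction's cutoff,
#' applies a random rigid motion, and verifies that
#' [detect_interactions()] recovers exactly the planted list. The
#' detect -> enumerate -> encode chain then reproduces the planted
#' (type-pair, distance) histogram exactly.
#'
#' @param types Character vector of interaction types (one ligand atom each).
#' @param distances For one atom `NULL`; for two a single distance (A); for
#'   `m` atoms a length-`choose(m, 2)` vector in row-major upper-triangle
#'   order, or a full `m x m` matrix.
#' @param seed Integer seed for the rigid motion.
#' @param complex_id Identifier for the complex.
#' @return A `pharm_complex` with ground-truth roles set.
#' @export
gen_pocket_complex <- function(types, distances = NULL, seed = 1L,
                               complex_id = "synthetic_pocket") {
  m <- length(types)
  bad <- setdiff(types, names(PLANT_SPECS))
  if (length(bad)) stopf("unknown interaction type(s): %s", paste(bad, collapse = ", "))
  D <- matrix(0, m, m)
  if (m > 1L) {
    if (is.matrix(distances)) {
      D <- distances
    } else {
      if (length(distances) != choose(m, 2)) {
        stopf("need %d pairwise distances for %d planted interactions",
              choose(m, 2), m)
      }
      D[upper.tri(D)] <- 0
      k <- 1L
      for (i in seq_len(m - 1L)) for (j in seq((i + 1L), m)) {
        D[i, j] <- D[j, i] <- distances[k]; k <- k + 1L
      }
    }
    if (any(D[upper.tri(D)] <= 0)) stopf("planted distances must be positive")
  }
  X <- if (m > 0L) embed_distances(D) else matrix(0, 0L, 3L)
  centroid <- if (m > 0L) colMeans(X) else c(0, 0, 0)

  empty_atoms <- tibble(serial = integer(), name = character(),
                        element = character(), residue_name = character(),
                        chain = character(), residue_seq = integer(),
                        insert = character(), x = double(), y = double(),
                        z = double(), formal_charge = integer())
  lig <- list(); prot <- list()
  for (i in seq_len(m)) {
    spec <- PLANT_SPECS[[types[i]]]
    dir <- X[i, ] - centroid
    nrm <- sqrt(sum(dir^2))
    dir <- if (nrm < 1e-9) c(1, 0, 0) * (if (i %% 2) 1 else -1) else dir / nrm
    p <- X[i, ] + dir * spec$p_dist
    lig[[i]] <- tibble(serial = i, name = paste0(spec$element, i),
                       element = spec$element, residue_name = "LIG",
                       chain = "L", residue_seq = 1L, insert = "",
                       x = X[i, 1], y = X[i, 2], z = X[i, 3],
                       formal_charge = spec$charge)
    prot[[i]] <- tibble(serial = 1000L + i, name = spec$p_name,
                        element = spec$p_el, residue_name = spec$p_res,
                        chain = "A", residue_seq = 10L + i, insert = "",
                        x = p[1], y = p[2], z = p[3], formal_charge = 0L)
  }
  # distant backbone anchors, outside every interaction cutoff
  for (k in 1:2) {
    far <- centroid + c(30 + 5 * k, 0, 0)
    prot[[m + k]] <- tibble(serial = 2000L + k, name = "CA", element = "C",
                            residue_name = "GLY", chain = "A",
                            residue_seq = 100L + k, insert = "",
                            x = far[1], y = far[2], z = far[3],
                            formal_charge = 0L)
  }
  cplx <- structure(list(complex_id = complex_id,
                         protein_atoms = dplyr::bind_rows(c(list(empty_atoms), prot)),
                         ligand_atoms = dplyr::bind_rows(c(list(empty_atoms), lig)),
                         bonds = NULL, ligand_roles = NULL),
                    class = "pharm_complex")
  roles <- dplyr::bind_rows(c(list(tibble(serial = integer(), role = character())),
                              lapply(seq_len(m), function(i) {
                                tibble(serial = i, role = PLANT_SPECS[[types[i]]]$roles)
                              })))
  cplx <- set_pharm_roles(cplx, roles)
  cplx <- with_seed(seed, rigid_transform(cplx))

  found <- detect_interactions(cplx)
  ok <- nrow(found) == m &&
    all(found$itype[order(found$ligand_serial)] == types) &&
    all(found$ligand_serial %in% seq_len(m))
  if (!ok) {
    stopf("planted geometry produced %d interaction(s) instead of %d; infeasible placement",
          nrow(found), m, class = "pharmboost_generation_error")
  }
  cplx
}

# Random rotation (QR of a Gaussian matrix) + translation of all atoms.
rigid_transform <- function(cplx) {
  qr_ <- qr(matrix(stats::rnorm(9), 3L))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  tr <- stats::runif(3, -20, 20)
  move <- function(at) {
    xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
    at$x <- xyz[, 1L] + tr[1L]; at$y <- xyz[, 2L] + tr[2L]
    at$z <- xyz[, 3L] + tr[3L]
    at
  }
  cplx$protein_atoms <- move(cplx$protein_atoms)
  cplx$ligand_atoms <- move(cplx$ligand_atoms)
  cplx
}
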