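# Pharm-IF encoding: pairs of protein-contacting ligand pharmacophore
# features, soft-binned by the distance between the two ligand atoms.
#
# H[t, k] = sum over interaction pairs i of type-pair t of A_k(i), where
# A_k(i) = max(0, 1 - |k - d_i|) and d_i is the ligand-ligand distance (A).

#' The six protein-ligand interaction types
#'
#' Canonical ordering used throughout the package: hydrogen bond with ligand
#' acceptor, hydrogen bond with ligand donor, hydrogen bond with undetermined
#' roles, ionic with ligand cation, ionic with ligand anion, hydrophobic.
#'
#' @return Character vector of the six interaction type names.
#' @export
interaction_types <- function() {
  c("HB_LIG_ACCEPTOR", "HB_LIG_DONOR", "HB_UNDETERMINED",
    "IONIC_LIG_CATION", "IONIC_LIG_ANION", "HYDROPHOBIC")
}

# Short codes used in feature names and file headers.
type_codes <- function() {
  c(HB_LIG_ACCEPTOR = "HBA", HB_LIG_DONOR = "HBD", HB_UNDETERMINED = "HBX",
    IONIC_LIG_CATION = "CAT", IONIC_LIG_ANION = "ANI", HYDROPHOBIC = "HYD")
}

#' The 21 canonical interaction type-pairs
#'
#' Unordered pairs of the six interaction types (6 same-type + 15 mixed),
#' ordered pair-major by the canonical type order. The `pair` label is the
#' short code of the two types joined by `-`, e.g. `"HBA-HBD"`.
#'
#' @return A tibble with columns `pair`, `type_a`, `type_b`.
#' @export
type_pairs <- function() {
  tt <- interaction_types()
  codes <- type_codes()
  idx <- which(upper.tri(diag(6L), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  tibble(
    pair   = paste(codes[tt[idx[, "row"]]], codes[tt[idx[, "col"]]], sep = "-"),
    type_a = tt[idx[, "row"]],
    type_b = tt[idx[, "col"]]
  )
}

#' Canonical label for a pair of interaction types
#'
#' Vectorised; `(a, b)` and `(b, a)` map to the same label, so the fingerprint
#' has exactly 21 type-pair channels.
#'
#' @param a,b Character vectors of interaction type names.
#' @return Character vector of canonical pair labels.
#' @export
canonical_type_pair <- function(a, b) {
  tt <- interaction_types()
  codes <- type_codes()
  ia <- match(a, tt)
  ib <- match(b, tt)
  if (anyNA(ia) || anyNA(ib)) {
    stopf("unknown interaction type(s): %s",
          paste(setdiff(c(a, b), tt), collapse = ", "))
  }
  lo <- pmin(ia, ib)
  hi <- pmax(ia, ib)
  paste(codes[tt[lo]], codes[tt[hi]], sep = "-")
}

#' Soft-binning weight of a distance in a 1-Angstrom bin
#'
#' A distance `d` contributes `max(0, 1 - |k - d|)` to bin `k`, so a
#' non-integer distance is split linearly across its two flanking bins: a
#' 4.3 A pair puts 0.7 in the 4 A bin and 0.3 in the 5 A bin.
#'
#' @param k Bin index (positive integer, vectorised).
#' @param d Ligand-ligand distance in Angstroms (vectorised).
#' @return Weight(s) in `[0, 1]`.
#' @export
#' @examples
#' bin_weight(4, 4.3)  # 0.7
#' bin_weight(5, 4.3)  # 0.3
bin_weight <- function(k, d) {
  if (!is.numeric(k) || !is.numeric(d) || !all(is.finite(k)) || !all(is.finite(d))) {
    stopf("`k` and `d` must be finite numerics",
          class = "pharmboost_argument_error")
  }
  if (any(k < 1) || any(k != floor(k))) {
    stopf("`k` must be a positive integer bin index",
          class = "pharmboost_argument_error")
  }
  pmax(0, 1 - abs(k - d))
}

#' Enumerate interaction pairs of a complex
#'
#' All unordered pairs of detected interactions whose ligand atoms differ;
#' each pair carries the canonical type-pair label and the Euclidean distance
#' between the two ligand atoms. Pairs on the same ligand atom are excluded
#' (their distance would be zero). Two interactions on the same two ligand
#' atoms but different protein atoms count as distinct pairs.
#'
#' @param interactions A tibble as returned by [detect_interactions()]
#'   (columns `itype`, `ligand_serial`, `lig_x`, `lig_y`, `lig_z`).
#' @return A tibble with one row per pair: `pair` (canonical type-pair label),
#'   `dist` (A), `i`, `j` (row indices into `interactions`).
#' @export
enumerate_pairs <- function(interactions) {
  need <- c("itype", "ligand_serial", "lig_x", "lig_y", "lig_z")
  if (!all(need %in% names(interactions))) {
    stopf("`interactions` must have columns %s", paste(need, collapse = ", "))
  }
  n <- nrow(interactions)
  empty <- tibble(pair = character(), dist = double(),
                  i = integer(), j = integer())
  if (n < 2L) return(empty)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, "row"]; j <- idx[, "col"]
  keep <- interactions$ligand_serial[i] != interactions$ligand_serial[j]
  i <- i[keep]; j <- j[keep]
  if (!length(i)) return(empty)
  dx <- interactions$lig_x[i] - interactions$lig_x[j]
  dy <- interactions$lig_y[i] - interactions$lig_y[j]
  dz <- interactions$lig_z[i] - interactions$lig_z[j]
  tibble(
    pair = canonical_type_pair(interactions$itype[i], interactions$itype[j]),
    dist = sqrt(dx^2 + dy^2 + dz^2),
    i = as.integer(i), j = as.integer(j)
  )
}

#' Encode interaction pairs into a Pharm-IF fingerprint
#'
#' Sums the soft-binning weights of every interaction pair into the
#' (type-pair, distance-bin) histogram `H`. Distances below 1 A put only
#' their bin-1 share into the fingerprint (there is no bin 0), and distances
#' of `k_max + 1` A or more contribute nothing.
#'
#' @param pairs A tibble as returned by [enumerate_pairs()] (columns `pair`,
#'   `dist`).
#' @param k_max Number of distance bins (default 20, i.e. bins 1..20 A).
#' @param complex_id Identifier stored with the fingerprint.
#' @return A `pharm_fp` object: a tibble of nonzero cells (`pair`, `bin`,
#'   `value`) with attributes `k_max` and `complex_id`.
#' @export
pharm_encode <- function(pairs, k_max = 20L, complex_id = NA_character_) {
  assert_number(k_max, "k_max", lower = 1)
  k_max <- as.integer(k_max)
  cells <- tibble(pair = character(), bin = integer(), value = double())
  if (nrow(pairs)) {
    if (any(!is.finite(pairs$dist)) || any(pairs$dist <= 0)) {
      stopf("pair distances must be finite and positive",
            class = "pharmboost_argument_error")
    }
    kf <- floor(pairs$dist)
    cand <- tibble(
      pair = rep(pairs$pair, 2L),
      bin  = as.integer(c(kf, kf + 1)),
      d    = rep(pairs$dist, 2L)
    )
    cand <- cand[cand$bin >= 1L & cand$bin <= k_max, , drop = FALSE]
    cand$value <- pmax(0, 1 - abs(cand$bin - cand$d))
    cells <- cand |>
      dplyr::filter(.data$value > 0) |>
      dplyr::summarise(value = sum(.data$value), .by = c("pair", "bin")) |>
      dplyr::arrange(.data$pair, .data$bin)
  }
  structure(cells, class = c("pharm_fp", class(cells)),
            k_max = k_max, complex_id = complex_id)
}

#' @export
print.pharm_fp <- function(x, ...) {
  cat(sprintf("<pharm_fp> complex '%s', k_max = %d, %d nonzero cells, mass %.3f\n",
              attr(x, "complex_id"), attr(x, "k_max"), nrow(x), sum(x$value)))
  NextMethod()
}

#' Feature names of the dense fingerprint layout
#'
#' Fixed column order: canonical type-pair order (21 channels), distance bin
#' ascending within each channel; names are `"<pair>/<k>"`.
#'
#' @param k_max Number of distance bins.
#' @return Character vector of length `21 * k_max`.
#' @export
fp_feature_names <- function(k_max = 20L) {
  tp <- type_pairs()$pair
  as.vector(t(outer(tp, seq_len(k_max), function(p, k) paste0(p, "/", k))))
}

#' Flatten fingerprints to a samples-by-features tibble
#'
#' @param fps A `pharm_fp` or a list of them (all with the same `k_max`).
#' @return A tibble with a `complex_id` column followed by `21 * k_max`
#'   feature columns in the fixed `"<pair>/<k>"` order.
#' @export
to_feature_matrix <- function(fps) {
  if (inherits(fps, "pharm_fp")) fps <- list(fps)
  kms <- vapply(fps, function(f) attr(f, "k_max"), integer(1))
  if (length(unique(kms)) != 1L) {
    stopf("all fingerprints must share the same k_max (got %s)",
          paste(unique(kms), collapse = ", "), class = "pharmboost_shape_error")
  }
  k_max <- kms[[1L]]
  feats <- fp_feature_names(k_max)
  mat <- matrix(0, nrow = length(fps), ncol = length(feats),
                dimnames = list(NULL, feats))
  ids <- character(length(fps))
  for (r in seq_along(fps)) {
    f <- fps[[r]]
    ids[r] <- attr(f, "complex_id") %||% NA_character_
    if (nrow(f)) mat[r, paste0(f$pair, "/", f$bin)] <- f$value
  }
  dplyr::bind_cols(tibble(complex_id = ids), as_tibble(mat))
}

#' Extract the numeric feature matrix from a fingerprint tibble
#'
#' Drops the metadata columns (`complex_id`, `sample_id`, `label`,
#' `compound`, `is_corrupted`) and returns the remaining feature columns as a
#' numeric matrix.
#'
#' @param df A tibble with fingerprint feature columns.
#' @return Numeric matrix, one row per sample.
#' @export
fp_matrix <- function(df) {
  meta <- c("complex_id", "sample_id", "label", "compound", "is_corrupted")
  keep <- setdiff(names(df), meta)
  m <- as.matrix(df[keep])
  storage.mode(m) <- "double"
  m
}

#' Write / read dense fingerprint matrices as CSV
#'
#' The header row carries the `"<pair>/<k>"` feature names; column order is
#' part of the format contract.
#'
#' @param df Tibble as returned by [to_feature_matrix()].
#' @param path File path.
#' @return `read_fingerprints()` returns the tibble; `write_fingerprints()`
#'   returns `path` invisibly.
#' @export
write_fingerprints <- function(df, path) {
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write / read fingerprints as sparse triplets
#'
#' TSV with columns `complex_id`, `pair`, `bin`, `value`; zero cells omitted.
#'
#' @param fps A `pharm_fp` or list of them.
#' @param path File path.
#' @param k_max Bin count to assume when reading.
#' @return `read_fp_sparse()` returns a list of `pharm_fp`; the writer
#'   returns `path` invisibly.
#' @export
write_fp_sparse <- function(fps, path) {
  if (inherits(fps, "pharm_fp")) fps <- list(fps)
  rows <- purrr::map_dfr(fps, function(f) {
    tibble(complex_id = attr(f, "complex_id") %||% NA_character_,
           pair = f$pair, bin = f$bin, value = f$value)
  })
  readr::write_tsv(rows, path)
  invisible(path)
}

#' @rdname write_fp_sparse
#' @export
read_fp_sparse <- function(path, k_max = 20L) {
  rows <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- unique(rows$complex_id)
  lapply(ids, function(id) {
    sub <- rows[rows$complex_id == id, c("pair", "bin", "value")]
    structure(as_tibble(sub), class = c("pharm_fp", class(as_tibble(sub))),
              k_max = as.integer(k_max), complex_id = id)
  })
}

#' Bar chart of a fingerprint's nonzero channels
#'
#' @param object A `pharm_fp`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pharm_fp <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$bin), y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~pair) +
    ggplot2::labs(x = "distance bin (Å)", y = "Pharm-IF weight",
                  title = attr(object, "complex_id"))
}
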