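test_that("soft binning splits a distance across its flanking bins", {
  expect_equal(bin_weight(4, 4.3), 0.7)
  expect_equal(bin_weight(5, 4.3), 0.3)
  expect_equal(bin_weight(7, 7.0), 1.0)
  expect_equal(bin_weight(2, 5.1), 0.0)
  expect_error(bin_weight(3, NaN), class = "pharmboost_argument_error")
  expect_error(bin_weight(0, 2), class = "pharmboost_argument_error")

  # mass conservation: the two flanking bins always share weight 1
  set.seed(41)
  d <- runif(200, 1, 20)
  mass <- bin_weight(floor(d), d) + bin_weight(floor(d) + 1, d)
  expect_true(all(abs(mass - 1) < 1e-12))
})

test_that("pair enumeration excludes same-atom pairs and measures distances", {
  base <- tibble::tibble(
    itype = c("HB_LIG_DONOR", "HB_LIG_ACCEPTOR", "HYDROPHOBIC"),
    ligand_serial = c(1L, 2L, 3L),
    lig_x = c(0, 3, 0), lig_y = c(0, 0, 4), lig_z = c(0, 0, 0))

  expect_equal(nrow(enumerate_pairs(base[0, ])), 0L)
  expect_equal(nrow(enumerate_pairs(base[1, ])), 0L)

  pairs <- enumerate_pairs(base)
  expect_equal(nrow(pairs), 3L)  # C(3, 2)
  expect_equal(sort(pairs$dist), c(3, 4, 5))

  # two interactions on the same ligand atom produce no pair
  same <- base[c(1, 1), ]
  same$itype <- c("HB_LIG_DONOR", "HYDROPHOBIC")
  expect_equal(nrow(enumerate_pairs(same)), 0L)

  # canonical pair label is orientation-free
  expect_equal(canonical_type_pair("HB_LIG_DONOR", "HB_LIG_ACCEPTOR"),
               canonical_type_pair("HB_LIG_ACCEPTOR", "HB_LIG_DONOR"))
  expect_equal(nrow(type_pairs()), 21L)
})

test_that("encoding sums pair weights into the type-pair histogram", {
  empty <- pharm_encode(tibble::tibble(pair = character(), dist = double()))
  expect_equal(nrow(empty), 0L)

  one <- pharm_encode(tibble::tibble(pair = "HBA-HBD", dist = 4.3))
  expect_equal(one$value[one$bin == 4], 0.7)
  expect_equal(one$value[one$bin == 5], 0.3)
  expect_equal(sum(one$value), 1)

  two <- pharm_encode(tibble::tibble(pair = c("HBA-HBD", "HBA-HBD"),
                                     dist = c(4.3, 4.7)))
  expect_equal(two$value[two$bin == 4], 1.0)
  expect_equal(two$value[two$bin == 5], 1.0)

  # below 1 A only the bin-1 share survives (no bin 0)
  low <- pharm_encode(tibble::tibble(pair = "HYD-HYD", dist = 0.5))
  expect_equal(low$value, 0.5)
  expect_equal(low$bin, 1L)

  # beyond k_max + 1 nothing is recorded
  far <- pharm_encode(tibble::tibble(pair = "HYD-HYD", dist = 25))
  expect_equal(nrow(far), 0L)
})

test_that("encode matches the brute-force double-loop oracle", {
  types <- interaction_types()
  for (case in 1:20) {
    set.seed(1000 + case)
    n <- sample(2:5, 1)
    ints <- tibble::tibble(
      itype = sample(types, n, replace = TRUE),
      ligand_serial = seq_len(n),
      lig_x = runif(n, 0, 15), lig_y = runif(n, 0, 15), lig_z = runif(n, 0, 15))
    fp <- pharm_encode(enumerate_pairs(ints), k_max = 20L)
    expect_equal(fp_to_dense(fp), brute_force_encode(ints, 20L),
                 tolerance = 1e-12)
  }
})

test_that("encoding is invariant to pair order", {
  set.seed(7)
  pairs <- tibble::tibble(
    pair = sample(type_pairs()$pair, 30, replace = TRUE),
    dist = runif(30, 1, 19))
  f1 <- pharm_encode(pairs)
  f2 <- pharm_encode(pairs[sample.int(30), ])
  expect_equal(as.data.frame(f1), as.data.frame(f2))
})

test_that("the feature matrix has the fixed column contract and round-trips", {
  zero <- pharm_encode(tibble::tibble(pair = character(), dist = double()),
                       complex_id = "z")
  tbl <- to_feature_matrix(list(zero))
  expect_equal(dim(tbl), c(1L, 421L))
  expect_equal(names(tbl)[1], "complex_id")
  expect_equal(names(tbl)[-1], fp_feature_names(20L))
  expect_true(all(fp_matrix(tbl) == 0))

  one <- pharm_encode(tibble::tibble(pair = "HBA-HBD", dist = 4.3),
                      complex_id = "w")
  row <- fp_matrix(to_feature_matrix(list(one)))
  nz <- which(row[1, ] != 0)
  expect_equal(length(nz), 2L)
  expect_equal(unname(diff(nz)), 1L)  # adjacent bins of one channel
  expect_equal(unname(row[1, nz]), c(0.7, 0.3))

  # dense CSV and sparse TSV round-trips reproduce values exactly
  set.seed(13)
  fps <- lapply(1:3, function(i) {
    pharm_encode(tibble::tibble(
      pair = sample(type_pairs()$pair, 5, replace = TRUE),
      dist = runif(5, 1, 19)), complex_id = paste0("c", i))
  })
  tbl3 <- to_feature_matrix(fps)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_fingerprints(tbl3, csv)
  expect_equal(as.data.frame(read_fingerprints(csv)), as.data.frame(tbl3),
               tolerance = 1e-12)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_fp_sparse(fps, tsv)
  back <- read_fp_sparse(tsv)
  expect_equal(fp_to_dense(back[[2]]), fp_to_dense(fps[[2]]), tolerance = 1e-12)

  # mixed k_max refuses to build one matrix
  k10 <- pharm_encode(tibble::tibble(pair = "HYD-HYD", dist = 3), k_max = 10L)
  expect_error(to_feature_matrix(list(zero, k10)),
               class = "pharmboost_shape_error")
})

test_that("the structure-to-fingerprint chain is rigid-motion invariant", {
  f <- function(seed) {
    cx <- gen_pocket_complex(c("HB_LIG_DONOR", "HB_LIG_ACCEPTOR", "HYDROPHOBIC"),
                             c(4.3, 6.0, 7.1), seed = seed)
    fp_to_dense(pharm_encode(enumerate_pairs(detect_interactions(cx))))
  }
  expect_equal(f(1), f(2026), tolerance = 1e-9)
})
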