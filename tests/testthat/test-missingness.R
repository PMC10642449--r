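test_that("canonical presence patterns classify as prescribed", {
  des <- design_2x3()
  # fully depleted young, complete old -> MNAR with young depleted
  r1 <- classify_missingness(pattern_tbl(c(0, 0, 0), c(1, 1, 1)), des)
  expect_equal(r1$label, "MNAR")
  expect_equal(r1$depleted_group, "young")
  # complete
  r2 <- classify_missingness(pattern_tbl(c(1, 1, 1), c(1, 1, 1)), des)
  expect_equal(r2$label, "COMPLETE")
  # <2 observed in both groups
  r3 <- classify_missingness(pattern_tbl(c(1, 0, 0), c(1, 0, 0)), des)
  expect_equal(r3$label, "FILTERED")
  # one missing in each group -> MAR
  r4 <- classify_missingness(pattern_tbl(c(1, 1, 0), c(1, 1, 0)), des)
  expect_equal(r4$label, "MAR")
})

test_that("classification matches exhaustive enumeration of all 2^6 patterns", {
  des <- design_2x3()
  grid <- expand.grid(rep(list(0:1), 6))
  for (i in seq_len(nrow(grid))) {
    pat <- as.numeric(grid[i, ])
    got <- classify_missingness(pattern_tbl(pat[1:3], pat[4:6]), des)$label
    expect_equal(got, oracle_classify(sum(pat[1:3]), sum(pat[4:6])),
                 info = paste(pat, collapse = ""))
  }
})

test_that("rule construction rejects inconsistent thresholds", {
  expect_error(missingness_rule(group_size = 3, mnar_min_missing = 4))
  x <- pattern_tbl(c(1, 1, 1), c(1, 1, 1))
  expect_error(classify_missingness(x, design_2x3(),
                                    missingness_rule(group_size = 5)),
               "config error")
})

test_that("MinDet assigns the column minimum of observed values", {
  m <- matrix(c(10, 12.5, NA,
                11, 13.0, 12,
                NA, 14.0, 13), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3")))
  x <- tbl_from_matrix(m)
  out <- as_intensity_matrix(impute_mindet(x))
  expect_equal(out["C", "s1"], 10)   # column minimum of s1
  expect_equal(out["A", "s3"], 12)   # column minimum of s3
  # observed cells untouched
  obs <- !is.na(m)
  expect_equal(out[obs], m[obs])
  # no targets -> identity
  complete <- tbl_from_matrix(matrix(1:4 + 0.5, 2))
  expect_equal(impute_mindet(complete), complete)
  # two cells in one column both get the minimum
  m2 <- matrix(c(NA, 5, NA, 7, 9, 8), ncol = 2,
               dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  out2 <- as_intensity_matrix(impute_mindet(tbl_from_matrix(m2)))
  expect_equal(out2[c("A", "C"), "s1"], c(A = 5, C = 5))
  # a column with no observed values is an error
  m3 <- matrix(c(NA, NA, 1, 2), ncol = 2,
               dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_error(impute_mindet(tbl_from_matrix(m3)), "impossible")
})

test_that("knn imputation averages the nearest rows", {
  # identical neighbour at k = 1 reproduces its value
  m <- matrix(c(1, 2, NA,
                1, 2, 3,
                9, 9, 9), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3")))
  out <- as_intensity_matrix(impute_knn(tbl_from_matrix(m), k = 1))
  expect_equal(out["A", "s3"], 3)

  # five-protein toy case against a brute-force all-pairs oracle at k = 2
  m5 <- matrix(c(1.0, 2.0, NA,
                 1.1, 2.1, 3.0,
                 0.9, 1.9, 2.8,
                 5.0, 6.0, 7.0,
                 1.3, 2.2, 3.4), nrow = 5, byrow = TRUE,
               dimnames = list(LETTERS[1:5], c("s1", "s2", "s3")))
  d_to_A <- apply(m5[-1, 1:2], 1, function(r) sqrt(mean((r - m5[1, 1:2])^2)))
  nb <- names(sort(d_to_A))[1:2]
  expected <- mean(m5[nb, "s3"])
  out5 <- as_intensity_matrix(impute_knn(tbl_from_matrix(m5), k = 2))
  expect_equal(out5["A", "s3"], expected)
  # imputed value lies within the range of neighbour values
  expect_gte(out5["A", "s3"], min(m5[nb, "s3"]))
  expect_lte(out5["A", "s3"], max(m5[nb, "s3"]))
  # observed cells untouched
  obs <- !is.na(m5)
  expect_equal(out5[obs], m5[obs])

  # k larger than the candidate pool shrinks with a warning
  expect_warning(impute_knn(tbl_from_matrix(m), k = 10), "candidate")
})

test_that("apply_imputation drops FILTERED rows, fills the rest, audits all", {
  des <- design_2x3()
  m <- matrix(c(10, 11, 12, 13, 14, 15,      # COMPLETE
                NA, NA, NA, 13, 14, 15,      # MNAR
                10, 11, NA, 13, 14, 15,      # MAR
                10, NA, NA, 13, NA, NA),     # FILTERED
              nrow = 4, byrow = TRUE,
              dimnames = list(c("A", "B", "C", "D"), paste0("s", 1:6)))
  res <- suppressWarnings(apply_imputation(tbl_from_matrix(m), des, k = 2))
  expect_setequal(res$matrix$protein_id, c("A", "B", "C"))
  expect_false(anyNA(as_intensity_matrix(res$matrix)))
  expect_setequal(res$audit$mechanism[res$audit$protein_id == "B"], "MNAR")
  expect_setequal(res$audit$mechanism[res$audit$protein_id == "C"], "MAR")
  expect_equal(res$audit$mechanism[res$audit$protein_id == "D"], "FILTERED")
  # MNAR cells equal their column minima
  out <- as_intensity_matrix(res$matrix)
  expect_equal(out["B", "s1"], 10)
  # observed cells untouched
  obs <- !is.na(m[1:3, ])
  expect_equal(out[obs], m[1:3, ][obs])
  # fully complete input is an identity
  full <- tbl_from_matrix(m[1, , drop = FALSE])
  res2 <- apply_imputation(full, des)
  expect_equal(as_intensity_matrix(res2$matrix), as_intensity_matrix(full))
  expect_equal(nrow(res2$audit), 0)
})

test_that("apply_imputation refuses raw-scale input", {
  x <- tbl_from_matrix(matrix(2^(1:6), 1), scale = "raw")
  expect_error(apply_imputation(x, design_2x3()), "log2")
})

test_that("strongly intensity-dependent dropout is mostly classified MNAR", {
  # generator config with extreme left-censoring: large downregulation pushes
  # the depleted group below a sharp detection threshold (10 seeds)
  des <- design_2x3()
  frac <- sapply(1:10, function(s) {
    cfg <- sim_config(n_proteins = 500, de_fraction = 0.6,
                      de_log2fc = c(mean = -6, sd = 0.5),
                      cv_within_group = 0.1, mnar_midpoint = 15.5,
                      mnar_steepness = 8, mar_rate = 0, seed = s)
    sim <- simulate_lfq_experiment(cfg, des)
    lab <- classify_missingness(log2_transform(sim$matrix), des)
    mean(lab$label[match(sim$dropout$protein_id, lab$protein_id)] == "MNAR")
  })
  expect_true(all(frac >= 0.8))
})

test_that("classification tracks the generating mechanism above chance", {
  # both mechanisms active; per missing cell, compare the classifier's row
  # label to the generator's mechanism; threshold 0.7 documented here
  des <- design_2x3()
  acc <- sapply(1:5, function(s) {
    cfg <- sim_config(n_proteins = 600, de_fraction = 0.5,
                      de_log2fc = c(mean = -5, sd = 1), cv_within_group = 0.1,
                      mnar_midpoint = 15.5, mnar_steepness = 6,
                      mar_rate = 0.03, seed = s)
    sim <- simulate_lfq_experiment(cfg, des)
    lab <- classify_missingness(log2_transform(sim$matrix), des)
    dr <- sim$dropout
    dr$called <- lab$label[match(dr$protein_id, lab$protein_id)]
    dr <- dr[dr$called %in% c("MNAR", "MAR"), ]
    mean((dr$mechanism == "MNAR_TRUE") == (dr$called == "MNAR"))
  })
  expect_true(all(acc > 0.7))
})
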