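test_that("log2 transform is cellwise and preserves missingness", {
  x <- tbl_from_matrix(matrix(c(8, 1, NA, 2), 2,
                              dimnames = list(c("A", "B"), c("s1", "s2"))),
                       scale = "raw")
  out <- as_intensity_matrix(log2_transform(x))
  expect_equal(out["A", "s1"], 3)
  expect_equal(out["B", "s1"], 0)
  expect_true(is.na(out["A", "s2"]))
  bad <- tbl_from_matrix(matrix(c(1, 0), 1), scale = "raw")
  expect_error(log2_transform(bad), "non-positive")
})

test_that("quantile normalization maps columns onto the mean sorted vector", {
  x <- tbl_from_matrix(matrix(c(1, 2, 3, 4, 5, 6), ncol = 2,
                              dimnames = list(c("A", "B", "C"), c("s1", "s2"))))
  out <- as_intensity_matrix(quantile_normalize(x))
  expect_equal(unname(out[, "s1"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, "s2"]), c(2.5, 3.5, 4.5))

  # identical columns are a fixed point
  same <- tbl_from_matrix(matrix(c(5, 1, 3, 5, 1, 3), ncol = 2))
  expect_equal(as_intensity_matrix(quantile_normalize(same)),
               as_intensity_matrix(same))

  # single column unchanged
  one <- tbl_from_matrix(matrix(c(9, 2, 4), ncol = 1))
  expect_equal(as_intensity_matrix(quantile_normalize(one)),
               as_intensity_matrix(one))

  expect_error(quantile_normalize(tbl_from_matrix(matrix(c(1, NA), 1))),
               "sequencing error")
})

test_that("quantile normalization matches limma and its defining invariants", {
  withr::with_seed(10, {
    m <- matrix(rnorm(200 * 5, 20, 2), 200)
    out <- as_intensity_matrix(quantile_normalize(tbl_from_matrix(m)))
    ref <- limma::normalizeQuantiles(m)
    expect_equal(unname(out), unname(ref), tolerance = 1e-12)
    # all columns share one sorted vector; column means equal
    sorted <- apply(out, 2, sort)
    expect_true(all(abs(sorted - sorted[, 1]) < 1e-9))
    expect_true(all(abs(colMeans(out) - mean(out)) < 1e-9))
    # rank order preserved within columns
    expect_equal(unname(apply(out, 2, rank)), apply(m, 2, rank))
  })
})

test_that("trigamma inversion is an inverse", {
  expect_equal(trigamma_inverse(trigamma(3)), 3, tolerance = 1e-8)
  expect_equal(trigamma_inverse(trigamma(c(0.5, 7, 40))), c(0.5, 7, 40),
               tolerance = 1e-7)
})

test_that("moderation prior reports infinite d0 for spreadless variances", {
  p <- fit_moderation_prior(rep(0.25, 500), df_residual = 4)
  expect_true(is.infinite(p$d0))
  expect_gt(p$s0_sq, 0)
  expect_error(fit_moderation_prior(rep(0, 50), 4), "variances")
})

test_that("prior estimation agrees with limma's squeezeVar", {
  withr::with_seed(3, {
    sigma2 <- 4 * 0.05 / rchisq(3000, 4)
    s2 <- sigma2 * rchisq(3000, 4) / 4
    mine <- fit_moderation_prior(s2, 4)
    ref <- limma::squeezeVar(s2, df = 4)
    expect_equal(mine$d0, ref$df.prior, tolerance = 1e-6)
    expect_equal(mine$s0_sq, ref$var.prior, tolerance = 1e-6)
  })
})

test_that("moderated t reduces to the ordinary t and to full shrinkage at the d0 limits", {
  withr::with_seed(21, {
    m <- matrix(rnorm(100 * 6, 15, 1), 100,
                dimnames = list(sprintf("P%03d", 1:100), paste0("s", 1:6)))
    x <- tbl_from_matrix(m, "normalized")
    des <- design_2x3()
    no_shrink <- structure(list(d0 = 0, s0_sq = 1), class = "moderation_prior")
    de0 <- moderated_t_test(x, des, prior = no_shrink)
    expect_equal(de0$t_moderated, de0$t_ordinary, tolerance = 1e-12)

    full <- structure(list(d0 = Inf, s0_sq = 0.8), class = "moderation_prior")
    deI <- moderated_t_test(x, des, prior = full)
    expect_true(all(deI$s_post_sq == 0.8))
  })
})

test_that("posterior variance is a convex combination and t is monotone in the fold change", {
  withr::with_seed(22, {
    m <- matrix(rnorm(200 * 6, 15, 1), 200,
                dimnames = list(sprintf("P%03d", 1:200), paste0("s", 1:6)))
    de <- moderated_t_test(tbl_from_matrix(m, "normalized"), design_2x3())
    pr <- attr(de, "prior")
    lo <- pmin(de$s_sq, pr$s0_sq); hi <- pmax(de$s_sq, pr$s0_sq)
    expect_true(all(de$s_post_sq >= lo - 1e-12 & de$s_post_sq <= hi + 1e-12))
    # same variance, larger |log2fc| -> larger |t|
    ord <- order(abs(de$log2fc / sqrt(de$s_post_sq)))
    expect_true(all(diff(abs(de$t_moderated[ord])) >= -1e-12))
  })
})

test_that("limma's moderated test is reproduced on a shared dataset", {
  withr::with_seed(30, {
    m <- matrix(rnorm(500 * 6, 12, 1), 500,
                dimnames = list(sprintf("P%03d", 1:500), paste0("s", 1:6)))
    m[1:50, 4:6] <- m[1:50, 4:6] + 1.5
    de <- moderated_t_test(tbl_from_matrix(m, "normalized"), design_2x3())
    fit <- limma::eBayes(limma::lmFit(m, cbind(1, rep(c(0, 1), each = 3))))
    expect_equal(de$t_moderated, unname(fit$t[, 2]), tolerance = 1e-10)
    expect_equal(de$p, unname(fit$p.value[, 2]), tolerance = 1e-10)
    expect_equal(de$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  })
})

test_that("paired t-test matches the closed form on prescribed differences", {
  des <- sample_design(c("m1_i", "m2_i", "m3_i", "m1_c", "m2_c", "m3_c"),
                       rep(c("intact", "crush"), each = 3),
                       pair_id = rep(c("m1", "m2", "m3"), 2))
  base <- c(10, 10, 10)
  m <- matrix(c(base, base + c(1, 2, 3)), nrow = 1,
              dimnames = list("A", des$sample))
  de <- paired_t_test(tbl_from_matrix(m), des)
  expect_equal(de$t_statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(de$p, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
  expect_equal(de$p, 0.0742, tolerance = 1e-3)

  # all differences zero -> t = 0, p = 1
  m0 <- matrix(rep(10, 6), nrow = 1, dimnames = list("A", des$sample))
  de0 <- paired_t_test(tbl_from_matrix(m0), des)
  expect_equal(de0$t_statistic, 0)
  expect_equal(de0$p, 1)

  # constant nonzero differences -> degenerate flag
  mc <- matrix(c(base, base + 1), nrow = 1, dimnames = list("A", des$sample))
  dec <- paired_t_test(tbl_from_matrix(mc), des)
  expect_true(dec$degenerate)
  expect_equal(dec$p, 1)
})

test_that("paired design validation catches unpaired samples", {
  des <- sample_design(c("a", "b", "c", "d"), c("intact", "intact", "crush", "crush"),
                       pair_id = c("m1", "m2", "m1", "m1"))
  x <- tbl_from_matrix(matrix(1:4 + 0.5, 1, dimnames = list("A", des$sample)))
  expect_error(paired_t_test(x, des), "design error")
})

test_that("BH and Storey q-values behave as step-up FDR adjustments", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03))$q, rep(0.03, 3))
  expect_equal(adjust_fdr(0.2)$q, 0.2)

  withr::with_seed(5, {
    p <- c(runif(900), runif(100, 0, 1e-4))
    bh <- adjust_fdr(p, "BH")
    st <- adjust_fdr(p, "storey")
    expect_true(all(bh$q >= p))
    expect_true(st$pi0 <= 1 && st$pi0 > 0)
    # Storey q = pi0 * BH q (clipped), hence never larger
    expect_equal(st$q, pmin(1, st$pi0 * bh$q))
    # monotone in p
    ord <- order(p)
    expect_true(all(diff(bh$q[ord]) >= -1e-15))
  })
  expect_error(adjust_fdr(c(0.5, 0)), "input error")
  expect_error(adjust_fdr(c(0.5, 1.2)), "input error")
})

test_that("estimated fold changes are unbiased for proteins without imputation", {
  des <- design_2x3()
  biases <- sapply(1:5, function(s) {
    sim <- simulate_lfq_experiment(
      clean_config(n_proteins = 1000, de_fraction = 0.2,
                   de_log2fc = c(mean = 0, sd = 2), seed = s), des)
    de <- moderated_t_test(quantile_normalize(log2_transform(sim$matrix)), des)
    joined <- dplyr::inner_join(tidy(de), sim$truth, by = "protein_id")
    mean(joined$log2fc - joined$true_log2fc)
  })
  expect_lt(abs(mean(biases)), 0.05)
})
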