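#' Log2-transform a raw intensity table
#'
#' @param x Raw-scale intensity tibble; all observed values must be > 0.
#' @return Log2-scale intensity tibble; missing cells preserved.
#' @export
log2_transform <- function(x) {
  if (intensity_scale(x) != "raw") {
    stop("log2_transform expects a raw-scale table", call. = FALSE)
  }
  m <- as_intensity_matrix(x)
  bad <- which(!is.na(m) & m <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("transform error: non-positive intensity at ",
         rownames(m)[bad[1, 1]], "/", colnames(m)[bad[1, 2]], call. = FALSE)
  }
  matrix_to_tbl(log2(m), "log2")
}

#' Quantile normalization
#'
#' Forces every sample column onto the common distribution given by the
#' across-column mean of sorted values, preserving within-column rank order.
#' Ties map to the average of the reference values at their tied ranks. Run
#' after imputation: missing cells are a sequencing error here.
#'
#' @param x Complete (no missing cells) log2-scale intensity tibble.
#' @return Normalized intensity tibble (`scale = "normalized"`).
#' @export
quantile_normalize <- function(x) {
  m <- as_intensity_matrix(x)
  if (anyNA(m)) {
    stop("sequencing error: quantile_normalize requires a complete matrix (impute first)",
         call. = FALSE)
  }
  if (ncol(m) == 1) return(matrix_to_tbl(m, "normalized"))
  ref <- rowMeans(apply(m, 2, sort))
  n <- nrow(m)
  out <- apply(m, 2, function(col) {
    r <- rank(col, ties.method = "average")
    stats::approx(seq_len(n), ref, xout = r)$y
  })
  dimnames(out) <- dimnames(m)
  matrix_to_tbl(out, "normalized")
}

#' Invert the trigamma function
#'
#' Newton iteration on 1/trigamma (monotone, nearly linear), as used when
#' matching moments of log sample variances.
#'
#' @param y Positive target value(s).
#' @return x with `trigamma(x) = y`.
#' @export
trigamma_inverse <- function(y) {
  vapply(y, function(t) {
    if (!is.finite(t) || t <= 0) return(NA_real_)
    if (t > 1e7) return(1 / sqrt(t))
    if (t < 1e-6) return(1 / t)
    x <- 0.5 + 1 / t
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / t) / psigamma(x, 2)
      x <- x + dif
      if (abs(dif / x) < 1e-10) break
    }
    x
  }, numeric(1))
}

#' Fit the variance-moderation prior
#'
#' Empirical-Bayes prior for variance shrinkage: sample variances are modelled
#' as s0^2 * F(df, d0) draws and (d0, s0^2) are recovered by matching the mean
#' and spread of log s^2 using digamma/trigamma moments. When the observed
#' spread does not exceed what df alone implies, d0 is infinite and s0^2 is
#' the common variance implied by the mean of log s^2.
#'
#' @param s_sq Per-protein sample variances (zeros/NAs dropped).
#' @param df_residual Residual degrees of freedom behind each variance.
#' @return A list of class `moderation_prior` with `d0` and `s0_sq`.
#' @export
fit_moderation_prior <- function(s_sq, df_residual) {
  s_sq <- s_sq[is.finite(s_sq) & s_sq > 0]
  if (length(s_sq) < 10) {
    stop("need >= 10 positive finite variances to fit the prior", call. = FALSE)
  }
  df <- df_residual
  z <- log(s_sq)
  zbar <- mean(z)
  evar <- stats::var(z) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(zbar - digamma(df / 2) + digamma(d0 / 2) +
                   log(df / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(zbar - digamma(df / 2) + log(df / 2))
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "moderation_prior")
}

pooled_group_stats <- function(m, design, grps) {
  m1 <- m[, design$sample[design$group == grps[1]], drop = FALSE]
  m2 <- m[, design$sample[design$group == grps[2]], drop = FALSE]
  n1 <- ncol(m1); n2 <- ncol(m2)
  mean1 <- unname(rowMeans(m1)); mean2 <- unname(rowMeans(m2))
  ss1 <- unname(rowSums((m1 - mean1)^2)); ss2 <- unname(rowSums((m2 - mean2)^2))
  df <- n1 + n2 - 2
  list(mean1 = mean1, mean2 = mean2, s_sq = (ss1 + ss2) / df,
       n1 = n1, n2 = n2, df = df)
}

#' Moderated two-sample t-test
#'
#' Per-protein two-group comparison with empirical-Bayes variance shrinkage:
#' the pooled residual variance s^2 is squeezed toward the prior,
#' s_post^2 = (d0 s0^2 + df s^2) / (d0 + df), and the moderated t statistic
#' log2FC / sqrt(s_post^2 (1/n1 + 1/n2)) is referred to a t distribution with
#' df + d0 degrees of freedom (two-sided). The fold change is group 2 minus
#' group 1 (e.g. old minus young) on the log2 scale. Zero-variance proteins
#' with s_post^2 = 0 are flagged and given p = 1.
#'
#' @param x Complete normalized (or log2) intensity tibble.
#' @param design Two-group design, each group >= 2 samples; the first group in
#'   order of appearance is the reference.
#' @param prior A `moderation_prior`; fitted from this matrix when `NULL`.
#' @param fdr FDR method passed to [adjust_fdr()].
#' @param n_imputed Optional per-protein imputed-cell counts (from an audit
#'   table) carried into the result.
#' @return A `de_result` tibble: `protein_id`, `mean_g1`, `mean_g2`, `log2fc`,
#'   `s_sq`, `s_post_sq`, `t_ordinary`, `t_moderated`, `df_residual`,
#'   `df_total`, `p`, `q`, `n_imputed_cells`, `degenerate`. The prior and
#'   comparison are attached as attributes.
#' @export
moderated_t_test <- function(x, design, prior = NULL, fdr = c("BH", "storey"),
                             n_imputed = NULL) {
  fdr <- match.arg(fdr)
  check_design(x, design)
  grps <- group_levels(design)
  if (length(grps) != 2) stop("moderated_t_test expects two groups", call. = FALSE)
  if (any(table(design$group) < 2)) {
    stop("insufficient replication: each group needs >= 2 samples", call. = FALSE)
  }
  m <- as_intensity_matrix(x)[, design$sample, drop = FALSE]
  if (anyNA(m)) stop("matrix must be complete (impute first)", call. = FALSE)
  st <- pooled_group_stats(m, design, grps)
  if (is.null(prior)) prior <- fit_moderation_prior(st$s_sq, st$df)

  lfc <- st$mean2 - st$mean1
  se_fac <- 1 / st$n1 + 1 / st$n2
  s_post <- if (is.infinite(prior$d0)) {
    rep(prior$s0_sq, length(lfc))
  } else {
    (prior$d0 * prior$s0_sq + st$df * st$s_sq) / (prior$d0 + st$df)
  }
  degenerate <- s_post <= 0
  t_ord <- ifelse(st$s_sq > 0, lfc / sqrt(st$s_sq * se_fac), ifelse(lfc == 0, 0, Inf * sign(lfc)))
  t_mod <- ifelse(degenerate, 0, lfc / sqrt(s_post * se_fac))
  df_total <- st$df + prior$d0
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p[degenerate] <- 1
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  adj <- adjust_fdr(p, method = fdr)

  if (is.null(n_imputed)) n_imputed <- stats::setNames(integer(nrow(m)), rownames(m))
  out <- tibble::tibble(
    protein_id = rownames(m),
    mean_g1 = st$mean1, mean_g2 = st$mean2, log2fc = lfc,
    s_sq = st$s_sq, s_post_sq = s_post,
    t_ordinary = t_ord, t_moderated = t_mod,
    df_residual = st$df, df_total = df_total,
    p = p, q = adj$q,
    n_imputed_cells = as.integer(n_imputed[rownames(m)]),
    degenerate = degenerate
  )
  out$n_imputed_cells[is.na(out$n_imputed_cells)] <- 0L
  new_de_result(out, prior = prior, comparison = paste(grps[2], "vs", grps[1]),
                pi0 = adj$pi0, fdr_method = fdr)
}

#' Paired t-test on within-pair log2 differences
#'
#' For paired designs (e.g. crushed vs intact nerve from the same mouse): per
#' protein, a one-sample t-test on the within-pair differences
#' (condition 2 minus condition 1), df = n_pairs - 1, two-sided p. Zero
#' difference-variance rows are flagged degenerate with p = 1.
#'
#' @param x Complete log2-scale intensity tibble.
#' @param design Design with `pair_id`; every pair must have exactly one
#'   sample in each of the two groups. The first group in order of appearance
#'   is the reference (subtracted).
#' @param fdr FDR method passed to [adjust_fdr()].
#' @return A `de_result` tibble (paired flavour: `mean_diff`, `log2fc`,
#'   `t_statistic`, `df`, `p`, `q`, `degenerate`).
#' @export
paired_t_test <- function(x, design, fdr = c("storey", "BH")) {
  fdr <- match.arg(fdr)
  check_design(x, design)
  if (!"pair_id" %in% names(design)) stop("design error: pair_id required", call. = FALSE)
  grps <- group_levels(design)
  if (length(grps) != 2) stop("paired_t_test expects two groups", call. = FALSE)
  tab <- table(design$pair_id, design$group)
  if (any(tab != 1)) {
    stop("design error: every pair needs exactly one sample per condition",
         call. = FALSE)
  }
  pairs <- rownames(tab)
  if (length(pairs) < 2) stop("need >= 2 pairs", call. = FALSE)
  m <- as_intensity_matrix(x)
  s_of <- function(p, g) design$sample[design$pair_id == p & design$group == g]
  d <- sapply(pairs, function(p) m[, s_of(p, grps[2])] - m[, s_of(p, grps[1])])
  d <- matrix(d, nrow = nrow(m), dimnames = list(rownames(m), pairs))
  if (anyNA(d)) stop("matrix must be complete for the paired test", call. = FALSE)
  n <- length(pairs)
  md <- unname(rowMeans(d))
  sd_d <- unname(sqrt(rowSums((d - md)^2) / (n - 1)))
  degenerate <- sd_d == 0
  t_stat <- ifelse(degenerate, 0, md / (sd_d / sqrt(n)))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  p[degenerate & md == 0] <- 1
  p[degenerate & md != 0] <- 1  # flagged, never called significant silently
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  adj <- adjust_fdr(p, method = fdr)
  out <- tibble::tibble(
    protein_id = rownames(m),
    mean_diff = md, log2fc = md,
    t_statistic = t_stat, df = n - 1,
    p = p, q = adj$q, degenerate = degenerate
  )
  new_de_result(out, prior = NULL, comparison = paste(grps[2], "vs", grps[1]),
                pi0 = adj$pi0, fdr_method = fdr)
}

#' False-discovery-rate adjustment
#'
#' Benjamini–Hochberg step-up q-values, or Storey q-values where the BH
#' multiplier m is replaced by m * pi0 with pi0 estimated from the p-value
#' distribution on a lambda grid (cubic-spline smoother evaluated at the
#' largest lambda, clipped to (0, 1]).
#'
#' @param p P-values in (0, 1].
#' @param method `"BH"` or `"storey"`.
#' @param lambda Grid for the Storey pi0 smoother.
#' @return A list with `q` (same length as `p`) and `pi0` (1 for BH).
#' @export
adjust_fdr <- function(p, method = c("BH", "storey"),
                       lambda = seq(0.05, 0.95, by = 0.05)) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("input error: p-values must lie in (0, 1]", call. = FALSE)
  }
  q_bh <- stats::p.adjust(p, method = "BH")
  if (method == "BH") return(list(q = q_bh, pi0 = 1))
  pi0 <- storey_pi0(p, lambda)
  list(q = pmin(1, pi0 * q_bh), pi0 = pi0)
}

storey_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  lambda <- sort(lambda)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  if (length(p) < 100 || length(unique(pi0_l)) < 4) {
    return(min(1, max(min(pi0_l), 1e-8)))
  }
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(1, max(pi0, 1e-8))
}
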