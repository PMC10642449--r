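check_mask <- function(mask, name) {
  if (!is.logical(mask)) stop(name, " must be a logical matrix", call. = FALSE)
  invisible(mask)
}

#' Mean in-mask fluorescence intensity
#'
#' Raw integrated density (sum of pixel intensities) within the mask,
#' normalized to the mask's pixel count.
#'
#' @param channel Numeric intensity matrix.
#' @param mask Logical matrix of the same dimensions.
#' @return Intensity per positive pixel.
#' @export
intensity_per_area <- function(channel, mask) {
  check_mask(mask, "mask")
  stopifnot(all(dim(channel) == dim(mask)))
  n <- sum(mask)
  if (n == 0) stop("empty mask", call. = FALSE)
  sum(channel[mask]) / n
}

#' Coverage of one mask by another
#'
#' Percentage of the collagen-positive area lying inside the myelin mask
#' (denominator = collagen area by default; set `denominator = "mbp"` for the
#' alternative convention).
#'
#' @param mask_col,mask_mbp Logical matrices of equal dimensions.
#' @param denominator `"col"` (default) or `"mbp"`.
#' @return Coverage percent in \[0, 100\].
#' @export
coverage_within_mask <- function(mask_col, mask_mbp,
                                 denominator = c("col", "mbp")) {
  denominator <- match.arg(denominator)
  check_mask(mask_col, "mask_col"); check_mask(mask_mbp, "mask_mbp")
  stopifnot(all(dim(mask_col) == dim(mask_mbp)))
  den <- if (denominator == "col") sum(mask_col) else sum(mask_mbp)
  if (den == 0) stop("empty mask", call. = FALSE)
  100 * sum(mask_col & mask_mbp) / den
}

#' Overlap fluorescence intensity, doubly normalized
#'
#' Integrated collagen density within the collagen-and-myelin overlap,
#' divided first by the coverage percentage (collagen area inside the myelin
#' mask) and then by the myelin-positive area. Units are arbitrary; only
#' ratios between groups are meaningful.
#'
#' @param channel_col Collagen intensity matrix.
#' @param mask_col,mask_mbp Logical masks of equal dimensions.
#' @return The normalized overlap intensity; `NaN` with a warning when the
#'   overlap is empty.
#' @export
overlap_intensity_normalized <- function(channel_col, mask_col, mask_mbp) {
  check_mask(mask_col, "mask_col"); check_mask(mask_mbp, "mask_mbp")
  stopifnot(all(dim(channel_col) == dim(mask_col)),
            all(dim(mask_col) == dim(mask_mbp)))
  if (sum(mask_col) == 0 || sum(mask_mbp) == 0) stop("empty mask", call. = FALSE)
  overlap <- mask_col & mask_mbp
  if (!any(overlap)) {
    warning("undefined measure: masks do not overlap", call. = FALSE)
    return(NaN)
  }
  density <- sum(channel_col[overlap])
  cov_pct <- coverage_within_mask(mask_col, mask_mbp)
  density / cov_pct / sum(mask_mbp)
}

#' Fixed-threshold mask builder
#'
#' Convenience segmentation: pixels strictly above the threshold are positive.
#'
#' @param channel Intensity matrix.
#' @param threshold Scalar threshold.
#' @return Logical mask.
#' @export
threshold_mask <- function(channel, threshold) channel > threshold

#' All three mask-based measures for one image pair
#'
#' @param channel_col,channel_mbp Intensity matrices.
#' @param mask_col,mask_mbp Logical masks.
#' @return A one-row tibble: `intensity_per_area` (collagen channel over the
#'   collagen mask), `coverage_pct`, `overlap_intensity_norm`.
#' @export
measure_image_pair <- function(channel_col, channel_mbp, mask_col, mask_mbp) {
  tibble::tibble(
    intensity_per_area = intensity_per_area(channel_col, mask_col),
    coverage_pct = coverage_within_mask(mask_col, mask_mbp),
    overlap_intensity_norm = overlap_intensity_normalized(channel_col, mask_col,
                                                          mask_mbp)
  )
}

#' Two-group comparison of image measures
#'
#' Unpaired two-sided pooled-variance t-test plus Cohen's d, the comparison
#' applied to per-nerve image measures between age groups.
#'
#' @param values_g1,values_g2 Numeric vectors (>= 2 per group).
#' @return A one-row tibble: `mean_g1`, `mean_g2`, `t`, `df`, `p`,
#'   `cohens_d`, `degenerate`.
#' @export
compare_groups <- function(values_g1, values_g2) {
  n1 <- length(values_g1); n2 <- length(values_g2)
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 values", call. = FALSE)
  sp2 <- ((n1 - 1) * stats::var(values_g1) + (n2 - 1) * stats::var(values_g2)) /
    (n1 + n2 - 2)
  degenerate <- sp2 == 0
  delta <- mean(values_g1) - mean(values_g2)
  t_stat <- if (degenerate) {
    if (delta == 0) 0 else NaN
  } else {
    delta / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  p <- if (is.nan(t_stat)) NA_real_ else 2 * stats::pt(-abs(t_stat), df = n1 + n2 - 2)
  d <- if (degenerate) NaN else (delta / sqrt(sp2))
  tibble::tibble(mean_g1 = mean(values_g1), mean_g2 = mean(values_g2),
                 t = t_stat, df = n1 + n2 - 2, p = p, cohens_d = d,
                 degenerate = degenerate)
}
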