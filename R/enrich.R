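#' Empirical ground probability of regulation
#'
#' The fraction of the whole tested universe meeting a regulation criterion
#' (fold change in the stated direction and q below alpha). Used as the null
#' success probability when asking whether a protein subset — e.g. the myelin
#' proteome after nerve crush — is regulated more often than the proteome at
#' large.
#'
#' @param de A `de_result` for the full universe.
#' @param direction `"down"` or `"up"`.
#' @param alpha Q-value threshold (default 0.05).
#' @return The ground probability (scalar in \[0, 1\]).
#' @export
ground_probability <- function(de, direction = c("down", "up"), alpha = 0.05) {
  direction <- match.arg(direction)
  if (nrow(de) == 0) stop("empty universe", call. = FALSE)
  sgn <- if (direction == "down") -1 else 1
  mean(sign(de$log2fc) == sgn & de$q < alpha)
}

#' Binomial test of subset regulation against the ground probability
#'
#' One-sided exact binomial tail: the probability of seeing at least the
#' observed number of regulated proteins in the subset if each had the
#' universe-wide ground probability of being regulated. Computed in log space
#' for numerical safety at extreme counts.
#'
#' @param de_subset `de_result` rows restricted to the subset (e.g. myelin
#'   proteins).
#' @param p0 Ground probability from [ground_probability()] (strictly inside
#'   (0, 1)).
#' @param direction `"down"` or `"up"`.
#' @param alpha Q-value threshold defining "regulated" (same as used for p0).
#' @return A list of class `binomial_enrichment`: `n_subset`, `k_regulated`,
#'   `p0`, `direction`, `p_value`.
#' @export
binomial_subset_test <- function(de_subset, p0, direction = c("down", "up"),
                                 alpha = 0.05) {
  direction <- match.arg(direction)
  if (nrow(de_subset) == 0) stop("empty subset", call. = FALSE)
  if (!(p0 > 0 && p0 < 1)) {
    stop("degenerate null: p0 must lie strictly in (0, 1)", call. = FALSE)
  }
  sgn <- if (direction == "down") -1 else 1
  k <- sum(sign(de_subset$log2fc) == sgn & de_subset$q < alpha)
  n <- nrow(de_subset)
  p <- if (k == 0) 1 else exp(stats::pbinom(k - 1, n, p0, lower.tail = FALSE,
                                            log.p = TRUE))
  structure(list(n_subset = n, k_regulated = k, p0 = p0,
                 direction = direction, p_value = min(p, 1)),
            class = "binomial_enrichment")
}

#' @export
print.binomial_enrichment <- function(x, ...) {
  cat(sprintf(
    "Binomial subset enrichment (%s): k = %d of n = %d regulated; p0 = %.4g; p = %.4g\n",
    x$direction, x$k_regulated, x$n_subset, x$p0, x$p_value))
  invisible(x)
}

#' @method tidy binomial_enrichment
#' @export
tidy.binomial_enrichment <- function(x, ...) {
  tibble::tibble(n_subset = x$n_subset, k_regulated = x$k_regulated,
                 p0 = x$p0, direction = x$direction, p_value = x$p_value)
}

#' Fisher-exact over-representation analysis
#'
#' Per gene set, a 2x2 table of study-set membership against set membership
#' over a user-supplied background (the whole proteome quantified in the
#' experiment), with a one-sided (enrichment) Fisher exact p. Gene sets are
#' intersected with the background before tabulation. P-values are reported
#' unadjusted — mirroring the p <= 0.1 call criterion of pathway platforms —
#' with a BH-adjusted column alongside for transparency.
#'
#' @param study_set Character ids (must be a subset of `background`).
#' @param background Character ids of the tested universe.
#' @param gene_sets Data frame with columns `set_id` and `accession`
#'   (optionally `set_name`).
#' @param p_threshold Flagging threshold on the unadjusted p (default 0.1).
#' @return A tibble per set: counts `a_in_study`, `b_study_not_set`,
#'   `c_set_not_study`, `d_neither`, `odds_ratio`, `fisher_p`, `p_bh`,
#'   `enriched`.
#' @export
fisher_ora <- function(study_set, background, gene_sets, p_threshold = 0.1) {
  stopifnot(all(c("set_id", "accession") %in% names(gene_sets)))
  study_set <- unique(study_set); background <- unique(background)
  rogue <- setdiff(study_set, background)
  if (length(rogue)) {
    stop("membership error: study ids outside background: ",
         paste(utils::head(rogue, 10), collapse = ", "), call. = FALSE)
  }
  n_bg <- length(background)
  n_study <- length(study_set)
  res <- gene_sets |>
    dplyr::distinct(.data$set_id, .data$accession) |>
    dplyr::filter(.data$accession %in% background) |>
    dplyr::group_by(.data$set_id) |>
    dplyr::summarise(
      n_set = dplyr::n(),
      a_in_study = sum(.data$accession %in% study_set),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      b_study_not_set = n_study - .data$a_in_study,
      c_set_not_study = .data$n_set - .data$a_in_study,
      d_neither = n_bg - n_study - .data$c_set_not_study
    )
  ft <- purrr::pmap(res[c("a_in_study", "b_study_not_set",
                          "c_set_not_study", "d_neither")],
                    function(a_in_study, b_study_not_set, c_set_not_study, d_neither) {
                      stats::fisher.test(matrix(c(a_in_study, b_study_not_set,
                                                  c_set_not_study, d_neither), 2,
                                                byrow = TRUE),
                                         alternative = "greater")
                    })
  res$odds_ratio <- purrr::map_dbl(ft, ~ unname(.x$estimate))
  res$fisher_p <- purrr::map_dbl(ft, "p.value")
  res$p_bh <- stats::p.adjust(res$fisher_p, method = "BH")
  res$enriched <- res$fisher_p <= p_threshold
  if ("set_name" %in% names(gene_sets)) {
    res <- dplyr::left_join(res,
                            dplyr::distinct(gene_sets, .data$set_id, .data$set_name),
                            by = "set_id")
  }
  dplyr::arrange(res, .data$fisher_p)
}

#' Cohen's d effect size
#'
#' Standardized mean difference with the pooled standard deviation
#' sqrt(((n1-1)s1^2 + (n2-1)s2^2) / (n1+n2-2)).
#'
#' @param group1,group2 Numeric vectors (>= 2 values each).
#' @return d (group1 minus group2, in pooled-sd units); `NaN` with a warning
#'   when the pooled sd is zero.
#' @export
cohens_d <- function(group1, group2) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 values", call. = FALSE)
  sp <- sqrt(((n1 - 1) * stats::var(group1) + (n2 - 1) * stats::var(group2)) /
               (n1 + n2 - 2))
  if (sp == 0) {
    warning("undefined effect size: pooled sd is zero", call. = FALSE)
    return(NaN)
  }
  (mean(group1) - mean(group2)) / sp
}
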