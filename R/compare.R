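#' Normalize protein accessions for cross-dataset joins
#'
#' Uppercases and strips isoform suffixes (`-1`, `-2`, ...); an optional
#' mapping table (columns `from`, `to`) is applied afterwards for ids that
#' differ between datasets.
#'
#' @param ids Character accessions.
#' @param mapping Optional data frame with `from`/`to` columns.
#' @return Normalized character vector.
#' @export
normalize_accession <- function(ids, mapping = NULL) {
  out <- toupper(sub("-\\d+$", "", ids))
  if (!is.null(mapping)) {
    stopifnot(all(c("from", "to") %in% names(mapping)))
    hit <- match(out, toupper(mapping$from))
    out[!is.na(hit)] <- toupper(mapping$to[hit[!is.na(hit)]])
  }
  out
}

#' Overlap between two proteome identifier sets
#'
#' @param ids_a,ids_b Character accession vectors (duplicates are dropped
#'   with a warning).
#' @return A one-row tibble: `n_a`, `n_b`, `n_intersection`, `n_a_only`,
#'   `n_b_only`.
#' @export
proteome_overlap <- function(ids_a, ids_b) {
  dedup <- function(x, nm) {
    if (anyDuplicated(x)) {
      warning("duplicate ids in ", nm, " de-duplicated", call. = FALSE)
      x <- unique(x)
    }
    x
  }
  a <- dedup(ids_a, "ids_a"); b <- dedup(ids_b, "ids_b")
  inter <- length(intersect(a, b))
  tibble::tibble(
    n_a = length(a), n_b = length(b), n_intersection = inter,
    n_a_only = length(a) - inter, n_b_only = length(b) - inter
  )
}

#' Spearman rank correlation
#'
#' Product-moment correlation of mid-ranks (average ranks for ties), with a
#' two-sided p-value from the large-sample t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom. Pairs
#' with a missing member are dropped.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return A one-row tibble: `rho`, `p`, `n_pairs`, `undefined` (TRUE when a
#'   vector is constant and rho does not exist).
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("insufficient data: need >= 3 complete pairs", call. = FALSE)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n_pairs = n,
                          undefined = TRUE))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- .Machine$double.xmin
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  tibble::tibble(rho = rho, p = max(p, .Machine$double.xmin), n_pairs = n,
                 undefined = FALSE)
}

#' Fold change versus baseline abundance
#'
#' Spearman correlation between per-protein log2 fold changes and log2
#' baseline abundance (e.g. mean iBAQ in the reference group). A negative rho
#' means high-abundance proteins tend to be downregulated.
#'
#' @param de A `de_result` (needs `protein_id`, `log2fc`).
#' @param baseline Data frame `protein_id`, `abundance` (raw scale, > 0).
#' @return A one-row tibble as in [spearman_cor()].
#' @export
fc_vs_abundance <- function(de, baseline) {
  stopifnot(all(c("protein_id", "abundance") %in% names(baseline)))
  joined <- dplyr::inner_join(tibble::as_tibble(de)[c("protein_id", "log2fc")],
                              baseline, by = "protein_id")
  if (nrow(joined) < 3) {
    stop("insufficient data: < 3 proteins shared between inputs", call. = FALSE)
  }
  spearman_cor(joined$log2fc, log2(joined$abundance))
}

#' Row-wise z-scoring
#'
#' Centres and scales every protein row to mean 0, sample sd 1 across all
#' samples (the transformation behind expression heatmaps). Constant rows are
#' emitted as all-zero and flagged with a warning.
#'
#' @param x Log2-scale intensity tibble without missing cells.
#' @return A list with `matrix` (z-scored tibble) and `flagged` (protein ids
#'   with zero row sd).
#' @export
row_zscore <- function(x) {
  m <- as_intensity_matrix(x)
  if (ncol(m) < 2) stop("need >= 2 samples to z-score", call. = FALSE)
  mu <- rowMeans(m, na.rm = TRUE)
  sd_r <- apply(m, 1, stats::sd, na.rm = TRUE)
  flagged <- rownames(m)[sd_r == 0]
  if (length(flagged)) {
    warning("zero-sd rows emitted as zeros: ", paste(flagged, collapse = ", "),
            call. = FALSE)
  }
  z <- (m - mu) / ifelse(sd_r == 0, 1, sd_r)
  list(matrix = matrix_to_tbl(z, intensity_scale(x)), flagged = flagged)
}
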