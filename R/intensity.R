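#' Intensity tables
#'
#' The pipeline's central container is an ordinary tibble with a `protein_id`
#' column followed by one numeric column per sample; missing quantifications
#' are `NA`. A `"scale"` attribute records whether values are on the raw
#' intensity scale (`"raw"`), log2 (`"log2"`) or log2 after quantile
#' normalization (`"normalized"`), so stages can refuse inputs on the wrong
#' scale instead of silently double-transforming.
#'
#' @param x A data frame with a `protein_id` column and numeric sample columns.
#' @param scale One of `"raw"`, `"log2"`, `"normalized"`.
#' @return A tibble with the `scale` attribute set.
#' @examples
#' intensity_tbl(tibble::tibble(protein_id = "P1", s1 = 2, s2 = 4), "raw")
#' @export
intensity_tbl <- function(x, scale = c("raw", "log2", "normalized")) {
  scale <- match.arg(scale)
  x <- tibble::as_tibble(x)
  if (!"protein_id" %in% names(x)) {
    stop("intensity table needs a `protein_id` column", call. = FALSE)
  }
  x <- dplyr::relocate(x, "protein_id")
  if (anyDuplicated(x$protein_id)) {
    stop("duplicate protein_id values in intensity table", call. = FALSE)
  }
  not_num <- names(x)[-1][!vapply(x[-1], is.numeric, logical(1))]
  if (length(not_num)) {
    stop("non-numeric sample columns: ", paste(not_num, collapse = ", "),
         call. = FALSE)
  }
  attr(x, "scale") <- scale
  x
}

#' @rdname intensity_tbl
#' @export
intensity_scale <- function(x) {
  sc <- attr(x, "scale", exact = TRUE)
  if (is.null(sc)) "raw" else sc
}

sample_cols <- function(x) setdiff(names(x), "protein_id")

#' @rdname intensity_tbl
#' @export
as_intensity_matrix <- function(x) {
  m <- as.matrix(x[sample_cols(x)])
  storage.mode(m) <- "double"
  rownames(m) <- x$protein_id
  m
}

matrix_to_tbl <- function(m, scale) {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  out <- tibble::add_column(out, protein_id = rownames(m), .before = 1)
  intensity_tbl(out, scale)
}

check_design <- function(x, design) {
  stopifnot(is.data.frame(design), all(c("sample", "group") %in% names(design)))
  missing_samples <- setdiff(design$sample, sample_cols(x))
  if (length(missing_samples)) {
    stop("design samples absent from intensity table: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  invisible(design)
}

#' Build a sample design table
#'
#' @param sample Character vector of sample ids (must match intensity columns).
#' @param group Character/factor group per sample.
#' @param pair_id Optional pairing id (e.g. mouse) for paired designs.
#' @return A tibble with columns `sample`, `group` and optionally `pair_id`.
#' @export
sample_design <- function(sample, group, pair_id = NULL) {
  out <- tibble::tibble(sample = as.character(sample), group = as.character(group))
  if (!is.null(pair_id)) out$pair_id <- as.character(pair_id)
  if (anyDuplicated(out$sample)) stop("duplicate sample ids", call. = FALSE)
  out
}

group_levels <- function(design) unique(design$group)

#' Read / write intensity tables and designs as TSV
#'
#' Matrices are written with proteins as rows and samples as columns; an empty
#' cell encodes a missing quantification.
#'
#' @param path File path.
#' @param scale Scale tag to attach on read (files do not self-describe).
#' @param x Table to write.
#' @return `read_intensity_tsv()` returns an intensity tibble;
#'   `read_design_tsv()` a design tibble; the writers return `x` invisibly.
#' @export
read_intensity_tsv <- function(path, scale = c("raw", "log2", "normalized")) {
  x <- readr::read_tsv(path, show_col_types = FALSE, na = c("", "NA"))
  intensity_tbl(x, match.arg(scale))
}

#' @rdname read_intensity_tsv
#' @export
write_intensity_tsv <- function(x, path) {
  readr::write_tsv(x, path, na = "")
  invisible(x)
}

#' @rdname read_intensity_tsv
#' @export
read_design_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  sample_design(x$sample, x$group, x$pair_id)
}
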