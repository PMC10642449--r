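AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Fully tryptic in-silico digest
#'
#' Cleaves a protein sequence after every lysine (K) or arginine (R) that is
#' not immediately followed by proline (P), with zero missed cleavages — the
#' rule used to define a protein's theoretically observable peptides for iBAQ.
#'
#' @param sequence Uppercase amino-acid string over the 20-letter alphabet.
#' @return A tibble with one row per peptide: `peptide`, `start`, `end`
#'   (0-based half-open coordinates on the protein).
#' @examples
#' tryptic_digest("AAAAAAKSSSSSSRPTTTTTTK")
#' @export
tryptic_digest <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence) ||
      nchar(sequence) == 0) {
    stop("empty input: sequence must be a non-empty string", call. = FALSE)
  }
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad)) {
    stop("alphabet error: illegal residue(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- length(chars)
  # cut after position i if chars[i] is K/R and chars[i+1] is not P
  is_kr <- chars %in% c("K", "R")
  next_is_p <- c(chars[-1] == "P", FALSE)
  cuts <- which(is_kr & !next_is_p & seq_len(n) < n)
  starts <- c(0L, cuts)
  ends <- c(cuts, n)
  tibble::tibble(
    peptide = substring(sequence, starts + 1L, ends),
    start = starts,
    end = as.integer(ends)
  )
}

#' Count observable peptides
#'
#' Number of fully tryptic peptides in a length window; the iBAQ denominator.
#' The 7–30 residue default is the common iBAQ convention.
#'
#' @param digest A [tryptic_digest()] result.
#' @param min_len,max_len Inclusive peptide-length window.
#' @return Integer count.
#' @export
count_observable <- function(digest, min_len = 7L, max_len = 30L) {
  stopifnot(min_len <= max_len)
  len <- nchar(digest$peptide)
  sum(len >= min_len & len <= max_len)
}

#' iBAQ from summed peptide intensity
#'
#' Intensity-based absolute quantification: the sum of a protein's peptide
#' intensities divided by its number of observable peptides.
#'
#' @param peptide_intensity_sum Non-negative summed peptide intensity.
#' @param observable_count Positive count of observable peptides.
#' @return iBAQ value.
#' @export
compute_ibaq <- function(peptide_intensity_sum, observable_count) {
  stopifnot(all(peptide_intensity_sum >= 0))
  if (any(observable_count == 0)) {
    stop("undefined iBAQ: protein has zero observable peptides", call. = FALSE)
  }
  peptide_intensity_sum / observable_count
}

#' Relative abundance shares
#'
#' Each protein's iBAQ as a percentage of the summed iBAQ of all reported
#' proteins (the "share of the proteome" bookkeeping behind pie charts of
#' dominant myelin proteins).
#'
#' @param ibaq A data frame with columns `protein_id` and `ibaq`.
#' @return A tibble with `protein_id`, `ibaq`, `relative_share` (percent,
#'   summing to 100), sorted by descending share.
#' @examples
#' relative_abundance(tibble::tibble(protein_id = c("A", "B"), ibaq = c(3, 1)))
#' @export
relative_abundance <- function(ibaq) {
  stopifnot(is.data.frame(ibaq), all(c("protein_id", "ibaq") %in% names(ibaq)))
  if (any(ibaq$ibaq < 0, na.rm = TRUE)) stop("negative iBAQ", call. = FALSE)
  total <- sum(ibaq$ibaq, na.rm = TRUE)
  if (!isTRUE(total > 0)) {
    stop("degenerate input: all iBAQ values are zero", call. = FALSE)
  }
  ibaq |>
    dplyr::mutate(relative_share = 100 * .data$ibaq / total) |>
    dplyr::arrange(dplyr::desc(.data$relative_share))
}

#' Group-wise mean-iBAQ shares
#'
#' Convenience wrapper: mean raw intensity per protein within each design
#' group, converted to relative shares per group.
#'
#' @param x Raw-scale intensity tibble.
#' @param design Sample design.
#' @return A tibble with `group`, `protein_id`, `ibaq` (group mean, missing
#'   treated as absent), `relative_share`.
#' @export
group_shares <- function(x, design) {
  check_design(x, design)
  if (intensity_scale(x) != "raw") {
    stop("group_shares expects raw-scale intensities", call. = FALSE)
  }
  x |>
    tidyr::pivot_longer(-"protein_id", names_to = "sample", values_to = "intensity") |>
    dplyr::inner_join(design, by = "sample") |>
    dplyr::group_by(.data$group, .data$protein_id) |>
    dplyr::summarise(ibaq = mean(.data$intensity, na.rm = TRUE), .groups = "drop") |>
    dplyr::mutate(ibaq = ifelse(is.nan(.data$ibaq), 0, .data$ibaq)) |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ relative_abundance(.x)) |>
    dplyr::ungroup()
}

#' Detection filter by replicate presence
#'
#' A protein counts as detected in a group when it has at least `min_detected`
#' non-missing values there; it is kept in the analysis universe when detected
#' in at least one group, and labelled by which groups detect it. With the
#' default `min_detected = 2` on triplicate pools this is the "2 of 3 pools"
#' rule applied before all downstream analyses.
#'
#' @param x Intensity tibble (any scale).
#' @param design Two-group sample design.
#' @param min_detected Minimum non-missing values per group to call detection.
#' @return A list with `matrix` (retained rows, original scale) and `labels`
#'   (tibble: `protein_id`, `label` in
#'   `both` / `<groupA>_only` / `<groupB>_only` / `excluded`).
#' @export
detection_filter <- function(x, design, min_detected = 2L) {
  check_design(x, design)
  grps <- group_levels(design)
  if (length(grps) != 2) stop("detection_filter expects two groups", call. = FALSE)
  if (min_detected > min(table(design$group))) {
    stop("min_detected exceeds a group size", call. = FALSE)
  }
  m <- as_intensity_matrix(x)[, design$sample, drop = FALSE]
  det <- sapply(grps, function(g) {
    rowSums(!is.na(m[, design$sample[design$group == g], drop = FALSE])) >= min_detected
  }, simplify = FALSE)
  det <- do.call(cbind, det)
  label <- dplyr::case_when(
    det[, 1] & det[, 2] ~ "both",
    det[, 1] ~ paste0(grps[1], "_only"),
    det[, 2] ~ paste0(grps[2], "_only"),
    .default = "excluded"
  )
  keep <- label != "excluded"
  out <- x[keep, , drop = FALSE]
  attr(out, "scale") <- intensity_scale(x)
  list(
    matrix = out,
    labels = tibble::tibble(protein_id = x$protein_id, label = label)
  )
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file; the first whitespace-delimited token of each header
#'   is taken as the accession.
#' @return A tibble with `accession` and `sequence`.
#' @export
read_protein_fasta <- function(path) {
  lines <- readr::read_lines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA headers found in ", path, call. = FALSE)
  id <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  tibble::tibble(accession = id, sequence = unname(seqs))
}

#' iBAQ table from a peptide-intensity table and sequences
#'
#' Self-computed iBAQ path: per-protein summed peptide intensity per sample,
#' divided by the observable-peptide count from the in-silico digest.
#'
#' @param peptides Data frame `protein_id`, `peptide`, plus per-sample
#'   intensity columns.
#' @param proteins Data frame `accession`, `sequence` (e.g. from
#'   [read_protein_fasta()]).
#' @param min_len,max_len Observable-peptide length window.
#' @return Raw-scale intensity tibble of iBAQ values.
#' @export
ibaq_from_peptides <- function(peptides, proteins, min_len = 7L, max_len = 30L) {
  stopifnot(all(c("protein_id", "peptide") %in% names(peptides)))
  obs <- proteins |>
    dplyr::mutate(observable = purrr::map_int(
      .data$sequence, ~ count_observable(tryptic_digest(.x), min_len, max_len)
    )) |>
    dplyr::select(protein_id = "accession", "observable")
  sums <- peptides |>
    dplyr::select(-"peptide") |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), ~ sum(.x, na.rm = TRUE)),
                     .groups = "drop")
  joined <- dplyr::inner_join(sums, obs, by = "protein_id")
  if (any(joined$observable == 0)) {
    bad <- joined$protein_id[joined$observable == 0]
    stop("undefined iBAQ (zero observable peptides): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- joined |>
    dplyr::mutate(dplyr::across(-c("protein_id", "observable"),
                                ~ .x / .data$observable)) |>
    dplyr::select(-"observable")
  intensity_tbl(out, "raw")
}
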