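#' Missingness classification rule
#'
#' Thresholds, in replicate counts, that sort each protein's presence pattern
#' in a two-group comparison into MNAR (intensity-dependent, one-sided
#' depletion), MAR (scattered random dropout), COMPLETE or FILTERED. The
#' shipped default transcribes the published 5-replicate rule proportionally
#' to triplicate groups: MNAR = missing in at least 2 of 3 in one group while
#' the other group is fully observed; MAR = at most 1 missing per group (and
#' not MNAR); FILTERED = fewer than 2 observed values in both groups, plus any
#' remaining asymmetric pattern too thin to test.
#'
#' @param group_size Replicates per group.
#' @param mnar_min_missing Minimum missing in the depleted group for MNAR.
#' @param mnar_min_present_other Minimum observed in the other group for MNAR.
#' @param mar_max_missing Maximum missing per group for MAR.
#' @return A list of class `missingness_rule`.
#' @export
missingness_rule <- function(group_size = 3L,
                             mnar_min_missing = 2L,
                             mnar_min_present_other = group_size,
                             mar_max_missing = 1L) {
  stopifnot(group_size >= 2, mnar_min_missing <= group_size,
            mnar_min_present_other <= group_size, mar_max_missing < group_size)
  structure(list(group_size = as.integer(group_size),
                 mnar_min_missing = as.integer(mnar_min_missing),
                 mnar_min_present_other = as.integer(mnar_min_present_other),
                 mar_max_missing = as.integer(mar_max_missing)),
            class = "missingness_rule")
}

# Single-pattern classifier on observed-counts; the vectorised path and the
# exhaustive-enumeration test both call this.
classify_counts <- function(obs1, obs2, rule) {
  n <- rule$group_size
  miss1 <- n - obs1; miss2 <- n - obs2
  if (miss1 == 0 && miss2 == 0) return(list(label = "COMPLETE", depleted = NA_integer_))
  if (obs1 < 2 && obs2 < 2) return(list(label = "FILTERED", depleted = NA_integer_))
  if (miss1 >= rule$mnar_min_missing && obs2 >= rule$mnar_min_present_other) {
    return(list(label = "MNAR", depleted = 1L))
  }
  if (miss2 >= rule$mnar_min_missing && obs1 >= rule$mnar_min_present_other) {
    return(list(label = "MNAR", depleted = 2L))
  }
  if (miss1 <= rule$mar_max_missing && miss2 <= rule$mar_max_missing) {
    return(list(label = "MAR", depleted = NA_integer_))
  }
  list(label = "FILTERED", depleted = NA_integer_)
}

#' Classify per-protein missingness for a two-group comparison
#'
#' @param x Intensity tibble.
#' @param design Two-group design with equal group sizes matching the rule.
#' @param rule A [missingness_rule()].
#' @return A tibble with `protein_id`, `label`
#'   (COMPLETE/MNAR/MAR/FILTERED), `depleted_group` (group name, MNAR only),
#'   `n_obs_<group>` counts.
#' @export
classify_missingness <- function(x, design, rule = missingness_rule()) {
  check_design(x, design)
  grps <- group_levels(design)
  if (length(grps) != 2) stop("classification expects two groups", call. = FALSE)
  sizes <- table(design$group)
  if (any(sizes != rule$group_size)) {
    stop("config error: rule group_size (", rule$group_size,
         ") does not match design group sizes", call. = FALSE)
  }
  m <- as_intensity_matrix(x)
  obs1 <- unname(rowSums(!is.na(m[, design$sample[design$group == grps[1]], drop = FALSE])))
  obs2 <- unname(rowSums(!is.na(m[, design$sample[design$group == grps[2]], drop = FALSE])))
  res <- purrr::map2(obs1, obs2, classify_counts, rule = rule)
  out <- tibble::tibble(
    protein_id = x$protein_id,
    label = purrr::map_chr(res, "label"),
    depleted_group = grps[purrr::map_int(res, "depleted")]
  )
  out[[paste0("n_obs_", grps[1])]] <- as.integer(obs1)
  out[[paste0("n_obs_", grps[2])]] <- as.integer(obs2)
  out
}

#' MinDet imputation
#'
#' Deterministic left-censored imputation: each target cell is replaced by the
#' minimum observed value of its own sample column. Intended for MNAR cells on
#' the log2 scale.
#'
#' @param x Intensity tibble (log2 scale expected).
#' @param targets Data frame `protein_id`, `sample` of cells to impute;
#'   defaults to every missing cell.
#' @return The intensity tibble with targets filled in; observed cells are
#'   never altered.
#' @export
impute_mindet <- function(x, targets = NULL) {
  m <- as_intensity_matrix(x)
  tg <- resolve_targets(m, targets)
  if (nrow(tg) == 0) return(x)
  col_min <- apply(m, 2, function(v) if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))
  bad <- unique(tg$sample[is.na(col_min[tg$sample])])
  if (length(bad)) {
    stop("imputation impossible: no observed values in sample(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(tg))) {
    m[tg$protein_id[i], tg$sample[i]] <- col_min[tg$sample[i]]
  }
  matrix_to_tbl(m, intensity_scale(x))
}

resolve_targets <- function(m, targets) {
  if (is.null(targets)) {
    idx <- which(is.na(m), arr.ind = TRUE)
    return(tibble::tibble(protein_id = rownames(m)[idx[, 1]],
                          sample = colnames(m)[idx[, 2]]))
  }
  stopifnot(all(c("protein_id", "sample") %in% names(targets)))
  tibble::tibble(protein_id = targets$protein_id, sample = targets$sample)
}

#' k-nearest-neighbour imputation
#'
#' Each target cell is the mean of the values, in that sample, of the k
#' nearest protein rows. Distance is Euclidean over the columns jointly
#' observed by the two rows (scaled to a common per-column footing);
#' candidate neighbours must be observed in the target's column. Equidistant
#' neighbours are broken by row order (stable, deterministic). If fewer than
#' k candidates exist the available ones are used with a warning.
#'
#' @param x Intensity tibble (log2 scale expected).
#' @param targets Cells to impute (`protein_id`, `sample`); default all
#'   missing cells.
#' @param k Number of neighbours (default 10).
#' @return Imputed intensity tibble; observed cells untouched.
#' @export
impute_knn <- function(x, targets = NULL, k = 10L) {
  stopifnot(k >= 1)
  m <- as_intensity_matrix(x)
  tg <- resolve_targets(m, targets)
  if (nrow(tg) == 0) return(x)
  for (pid in unique(tg$protein_id)) {
    cols <- tg$sample[tg$protein_id == pid]
    row <- m[pid, ]
    d <- knn_row_distances(m, row, pid)
    for (cl in cols) {
      cand <- which(!is.na(d) & !is.na(m[, cl]))
      if (length(cand) == 0) {
        stop("imputation impossible: no neighbour observed in sample ", cl,
             call. = FALSE)
      }
      if (length(cand) < k) {
        warning("impute_knn: only ", length(cand), " candidate neighbours (< k = ",
                k, ") for ", pid, "/", cl, call. = FALSE)
      }
      nb <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
      m[pid, cl] <- mean(m[nb, cl])
    }
  }
  matrix_to_tbl(m, intensity_scale(x))
}

# Mean squared difference over jointly observed columns (NA when no overlap);
# rescaling by overlap keeps rows with different missingness comparable.
knn_row_distances <- function(m, row, self_id) {
  diff2 <- sweep(m, 2, row)^2
  shared <- rowSums(!is.na(diff2))
  d <- sqrt(rowSums(diff2, na.rm = TRUE) / shared)
  d[shared == 0] <- NA_real_
  d[rownames(m) == self_id] <- NA_real_
  d
}

#' Classify, impute and filter in one step
#'
#' The pre-statistics layer: FILTERED proteins are dropped; missing cells of
#' MNAR proteins are MinDet-imputed (left-censored); missing cells of MAR
#' proteins are knn-imputed; an audit table records every imputed cell with
#' its mechanism and value and every dropped protein with its reason.
#'
#' @param x Log2-scale intensity tibble.
#' @param design Two-group design.
#' @param rule A [missingness_rule()].
#' @param k Neighbours for knn imputation.
#' @return A list with `matrix` (complete, imputed), `labels` (from
#'   [classify_missingness()]) and `audit` (tibble: `protein_id`, `sample`,
#'   `mechanism`, `imputed_value`; dropped proteins have `sample = NA` and
#'   `mechanism = "FILTERED"`).
#' @export
apply_imputation <- function(x, design, rule = missingness_rule(), k = 10L) {
  if (intensity_scale(x) == "raw") {
    stop("apply_imputation expects log2-scale intensities; run log2_transform first",
         call. = FALSE)
  }
  labels <- classify_missingness(x, design, rule)
  keep_ids <- labels$protein_id[labels$label != "FILTERED"]
  kept <- x[x$protein_id %in% keep_ids, , drop = FALSE]
  attr(kept, "scale") <- intensity_scale(x)

  m <- as_intensity_matrix(kept)
  all_missing <- resolve_targets(m, NULL)
  all_missing <- dplyr::left_join(all_missing,
                                  labels[c("protein_id", "label")],
                                  by = "protein_id")
  mnar_cells <- all_missing[all_missing$label == "MNAR", c("protein_id", "sample")]
  mar_cells <- all_missing[all_missing$label == "MAR", c("protein_id", "sample")]

  out <- kept
  if (nrow(mnar_cells)) out <- impute_mindet(out, mnar_cells)
  if (nrow(mar_cells)) out <- impute_knn(out, mar_cells, k = k)

  om <- as_intensity_matrix(out)
  cell_value <- function(cells) {
    purrr::map2_dbl(cells$protein_id, cells$sample, function(p, s) om[p, s])
  }
  audit <- dplyr::bind_rows(
    tibble::tibble(protein_id = mnar_cells$protein_id, sample = mnar_cells$sample,
                   mechanism = "MNAR", imputed_value = cell_value(mnar_cells)),
    tibble::tibble(protein_id = mar_cells$protein_id, sample = mar_cells$sample,
                   mechanism = "MAR", imputed_value = cell_value(mar_cells)),
    tibble::tibble(protein_id = labels$protein_id[labels$label == "FILTERED"],
                   sample = NA_character_, mechanism = "FILTERED",
                   imputed_value = NA_real_)
  )
  list(matrix = out, labels = labels, audit = audit)
}
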