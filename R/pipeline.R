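#' Pipeline configuration
#'
#' Bundle of the tunable thresholds shared by the end-to-end analyses; every
#' field is echoed into the run log so reports are self-describing.
#'
#' @param min_detected Detection filter threshold (non-missing per group).
#' @param rule A [missingness_rule()].
#' @param k Neighbours for knn imputation.
#' @param fdr FDR method (`"BH"` or `"storey"`).
#' @param alpha Q-value threshold defining a differentially abundant protein.
#' @param min_len,max_len Observable-peptide window for self-computed iBAQ.
#' @param seed Seed recorded with the run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_detected = 2L, rule = missingness_rule(),
                            k = 10L, fdr = c("BH", "storey"), alpha = 0.05,
                            min_len = 7L, max_len = 30L, seed = 1L) {
  fdr <- match.arg(fdr)
  structure(list(min_detected = as.integer(min_detected), rule = rule,
                 k = as.integer(k), fdr = fdr, alpha = alpha,
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_echo <- function(config) {
  tibble::tibble(
    parameter = c("min_detected", "rule.group_size", "rule.mnar_min_missing",
                  "rule.mnar_min_present_other", "rule.mar_max_missing", "k",
                  "fdr", "alpha", "min_len", "max_len", "seed",
                  "dep_criterion"),
    value = c(config$min_detected, config$rule$group_size,
              config$rule$mnar_min_missing, config$rule$mnar_min_present_other,
              config$rule$mar_max_missing, config$k, config$fdr, config$alpha,
              config$min_len, config$max_len, config$seed,
              paste0("q < ", config$alpha, " (", config$fdr,
                     "; stands in for an empirical-null local FDR)"))
  )
}

log_stage <- function(log, stage, n_in, n_out, note = "") {
  entry <- tibble::tibble(stage = stage, n_in = n_in, n_out = n_out,
                          n_removed = n_in - n_out, note = note)
  stopifnot(entry$n_removed >= 0)
  dplyr::bind_rows(log, entry)
}

#' End-to-end aging-myelin analysis
#'
#' Runs the full unpaired two-group pipeline on a raw intensity table:
#' detection filter, log2 transform, missingness classification + imputation,
#' quantile normalization, moderated t-test with FDR adjustment, group-wise
#' iBAQ shares, and the fold-change-versus-abundance correlation.
#'
#' @param x Raw-scale intensity tibble.
#' @param design Two-group [sample_design()] (reference group first).
#' @param config A [pipeline_config()].
#' @return A list of class `aging_report`: `de` (`de_result`), `shares`,
#'   `fc_abundance_cor`, `filtered_matrix`, `labels` (detection + missingness),
#'   `audit`, `log` (per-stage protein counts), `config` (echoed).
#' @export
run_aging_pipeline <- function(x, design, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  run_log <- tibble::tibble()

  det <- detection_filter(x, design, config$min_detected)
  run_log <- log_stage(run_log, "detection_filter", nrow(x), nrow(det$matrix),
                       paste0(">=", config$min_detected, " per group in >=1 group"))

  lg <- log2_transform(det$matrix)
  imp <- apply_imputation(lg, design, config$rule, config$k)
  run_log <- log_stage(run_log, "impute", nrow(lg), nrow(imp$matrix),
                       "FILTERED patterns dropped; MNAR=MinDet, MAR=knn")

  norm <- quantile_normalize(imp$matrix)
  run_log <- log_stage(run_log, "quantile_normalize", nrow(imp$matrix),
                       nrow(norm))

  n_imp <- table(imp$audit$protein_id[imp$audit$mechanism != "FILTERED"])
  n_imp_vec <- stats::setNames(as.integer(n_imp), names(n_imp))
  de <- moderated_t_test(norm, design, fdr = config$fdr, n_imputed = n_imp_vec)
  run_log <- log_stage(run_log, "moderated_t_test", nrow(norm), nrow(de),
                       paste0("fdr=", config$fdr))

  shares <- group_shares(det$matrix, design)
  ref_group <- group_levels(design)[1]
  baseline <- shares |>
    dplyr::filter(.data$group == ref_group, .data$ibaq > 0) |>
    dplyr::select("protein_id", abundance = "ibaq")
  cor_res <- fc_vs_abundance(de, baseline)

  structure(list(
    de = de, shares = shares, fc_abundance_cor = cor_res,
    filtered_matrix = det$matrix,
    labels = dplyr::left_join(det$labels,
                              imp$labels |>
                                dplyr::select("protein_id",
                                              missingness = "label"),
                              by = "protein_id"),
    audit = imp$audit, log = run_log, config = config_echo(config)
  ), class = "aging_report")
}

#' @export
print.aging_report <- function(x, ...) {
  cat("<aging_report>\n")
  print(glance(x$de))
  cat("stage log:\n"); print(x$log)
  invisible(x)
}

#' End-to-end injury time-course analysis
#'
#' For each timepoint (e.g. 7 and 28 days post crush): paired t-test of crush
#' versus intact, q-values, the universe-wide ground probability of
#' downregulation, and the binomial enrichment of a supplied myelin-protein
#' list against that ground probability. Also tabulates the myelin proteins'
#' log2 fold changes across timepoints.
#'
#' @param experiments Named list (one per timepoint) of lists with elements
#'   `matrix` (raw intensity tibble) and `design` (paired design).
#' @param myelin_ids Character accessions of the myelin proteome.
#' @param config A [pipeline_config()].
#' @return A list of class `injury_report`: `per_timepoint` (each with `de`,
#'   `ground_probability`, `binomial`), `myelin_fc` (myelin log2FC by
#'   timepoint, wide), `log`, `config`.
#' @export
run_injury_pipeline <- function(experiments, myelin_ids,
                                config = pipeline_config(fdr = "storey")) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(myelin_ids) || !length(myelin_ids)) {
    stop("config error: a myelin protein list is required", call. = FALSE)
  }
  if (is.null(names(experiments)) || any(!nzchar(names(experiments)))) {
    stop("experiments must be a named list (one name per timepoint)", call. = FALSE)
  }
  run_log <- tibble::tibble()
  per_tp <- purrr::imap(experiments, function(exp, tp) {
    lg <- log2_transform(exp$matrix)
    m <- as_intensity_matrix(lg)
    complete <- stats::complete.cases(m)
    kept <- lg[complete, , drop = FALSE]
    attr(kept, "scale") <- "log2"
    run_log <<- log_stage(run_log, paste0(tp, ":complete_cases"), nrow(lg),
                          nrow(kept))
    de <- paired_t_test(kept, exp$design, fdr = config$fdr)
    p0 <- ground_probability(de, "down", config$alpha)
    subset_de <- de[de$protein_id %in% myelin_ids, , drop = FALSE]
    binom <- if (p0 > 0 && p0 < 1 && nrow(subset_de) > 0) {
      binomial_subset_test(subset_de, p0, "down", config$alpha)
    } else {
      NULL
    }
    list(de = de, ground_probability = p0, binomial = binom)
  })
  myelin_fc <- purrr::imap(per_tp, function(res, tp) {
    tibble::as_tibble(res$de) |>
      dplyr::filter(.data$protein_id %in% myelin_ids) |>
      dplyr::transmute(.data$protein_id, timepoint = tp, .data$log2fc, .data$q)
  }) |>
    dplyr::bind_rows() |>
    tidyr::pivot_wider(names_from = "timepoint",
                       values_from = c("log2fc", "q"))
  structure(list(per_timepoint = per_tp, myelin_fc = myelin_fc,
                 log = run_log, config = config_echo(config)),
            class = "injury_report")
}

#' @export
print.injury_report <- function(x, ...) {
  cat("<injury_report>\n")
  for (tp in names(x$per_timepoint)) {
    res <- x$per_timepoint[[tp]]
    cat(sprintf("  %s: ground p(down) = %.3f; ", tp, res$ground_probability))
    if (!is.null(res$binomial)) {
      cat(sprintf("myelin subset k/n = %d/%d, binomial p = %.3g\n",
                  res$binomial$k_regulated, res$binomial$n_subset,
                  res$binomial$p_value))
    } else cat("binomial test not applicable\n")
  }
  invisible(x)
}
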