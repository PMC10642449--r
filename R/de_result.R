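new_de_result <- function(x, prior = NULL, comparison = NULL, pi0 = 1,
                          fdr_method = "BH") {
  structure(
    x,
    class = c("de_result", "tbl_df", "tbl", "data.frame"),
    prior = prior, comparison = comparison, pi0 = pi0, fdr_method = fdr_method
  )
}

#' @export
print.de_result <- function(x, ...) {
  cat("<de_result> ", attr(x, "comparison"), "; FDR: ", attr(x, "fdr_method"),
      "\n", sep = "")
  pr <- attr(x, "prior")
  if (!is.null(pr)) {
    cat(sprintf("  moderation prior: d0 = %.3g, s0^2 = %.4g\n", pr$d0, pr$s0_sq))
  }
  NextMethod()
}

#' Tidy a differential-abundance result
#'
#' @param x A `de_result`.
#' @param ... Unused.
#' @return A plain tibble of the per-protein results.
#' @method tidy de_result
#' @export
tidy.de_result <- function(x, ...) {
  out <- x
  attributes(out)[c("prior", "comparison", "pi0", "fdr_method")] <- NULL
  class(out) <- class(tibble::tibble())
  tibble::as_tibble(out)
}

#' One-row summary of a differential-abundance result
#'
#' @param x A `de_result`.
#' @param alpha DEP q-value threshold.
#' @param ... Unused.
#' @return A one-row tibble: protein counts, DEP counts by direction, the
#'   moderation prior (when present) and the Storey pi0 estimate.
#' @method glance de_result
#' @export
glance.de_result <- function(x, alpha = 0.05, ...) {
  pr <- attr(x, "prior")
  tibble::tibble(
    comparison = attr(x, "comparison") %||% NA_character_,
    n_proteins = nrow(x),
    n_dep = sum(x$q < alpha),
    n_dep_down = sum(x$q < alpha & x$log2fc < 0),
    n_dep_up = sum(x$q < alpha & x$log2fc > 0),
    d0 = if (is.null(pr)) NA_real_ else pr$d0,
    s0_sq = if (is.null(pr)) NA_real_ else pr$s0_sq,
    pi0 = attr(x, "pi0") %||% NA_real_,
    fdr_method = attr(x, "fdr_method") %||% NA_character_
  )
}

#' Volcano plot of a differential-abundance result
#'
#' @param object A `de_result`.
#' @param alpha q-value threshold separating differentially abundant proteins.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot de_result
#' @export
autoplot.de_result <- function(object, alpha = 0.05, ...) {
  df <- tidy(object)
  df$status <- dplyr::case_when(
    df$q < alpha & df$log2fc < 0 ~ "down",
    df$q < alpha & df$log2fc > 0 ~ "up",
    .default = "n.s."
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = -log10(.data$p),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(down = "#2166ac", up = "#b2182b",
                                            "n.s." = "grey60")) +
    ggplot2::labs(x = expression(log[2] ~ "fold change"),
                  y = expression(-log[10] ~ italic(p)),
                  colour = NULL,
                  title = attr(object, "comparison")) +
    ggplot2::theme_minimal()
}

#' Bar plot of relative-abundance shares
#'
#' @param shares Output of [relative_abundance()] or [group_shares()].
#' @param top_n Number of leading proteins to show individually; the rest are
#'   pooled into "other".
#' @return A ggplot.
#' @export
plot_abundance_shares <- function(shares, top_n = 10) {
  grouped <- "group" %in% names(shares)
  df <- shares
  if (!grouped) df$group <- "all"
  df <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::arrange(dplyr::desc(.data$relative_share), .by_group = TRUE) |>
    dplyr::mutate(protein = ifelse(dplyr::row_number() <= top_n,
                                   .data$protein_id, "other")) |>
    dplyr::group_by(.data$group, .data$protein) |>
    dplyr::summarise(relative_share = sum(.data$relative_share), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$relative_share,
                                   fill = .data$protein)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "share of total signal (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data %||%
NULL
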