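#' Simulation configuration
#'
#' Parameters of the synthetic LFQ generator. The generator emulates the
#' structure of peripheral-nerve myelin label-free proteomics: a log-normal
#' abundance distribution dominated by a few proteins (MPZ/MBP/PRX-like,
#' default expected shares 40/17/6 percent of total signal), multiplicative
#' within-group noise, a subset of proteins with known log2 fold changes, and
#' two missingness mechanisms — intensity-dependent (MNAR, logistic dropout in
#' log2 intensity) and uniform random (MAR).
#'
#' @param n_proteins Number of proteins.
#' @param n_per_group Samples per group (default 3, matching triplicate pools).
#' @param top_fractions Expected relative shares of the leading proteins; must
#'   sum to < 1.
#' @param de_fraction Fraction of non-top proteins carrying a true effect.
#' @param de_log2fc Mean and sd of the true log2 fold-change distribution.
#' @param cv_within_group Within-group coefficient of variation on the raw
#'   scale (multiplicative log-normal noise).
#' @param base_meanlog,base_sdlog Log-normal parameters of the baseline
#'   abundance of non-top proteins (natural-log scale).
#' @param mnar_midpoint Log2 intensity at which the MNAR dropout probability is
#'   0.5; set to `-Inf` to disable intensity-dependent dropout.
#' @param mnar_steepness Slope of the logistic dropout curve per log2 unit
#'   (must be > 0; larger = sharper censoring).
#' @param mar_rate Per-cell probability of random (MAR) dropout.
#' @param seed Integer seed; all randomness flows from one stream.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 1000,
                       n_per_group = 3,
                       top_fractions = c(0.40, 0.17, 0.06),
                       de_fraction = 0,
                       de_log2fc = c(mean = 0, sd = 1),
                       cv_within_group = 0.25,
                       base_meanlog = log(1e6),
                       base_sdlog = 1.5,
                       mnar_midpoint = 16,
                       mnar_steepness = 1.2,
                       mar_rate = 0.02,
                       seed = 1L) {
  stopifnot(n_proteins >= 1, n_per_group >= 1,
            de_fraction >= 0, de_fraction <= 1,
            mar_rate >= 0, mar_rate <= 1,
            mnar_steepness > 0, cv_within_group > 0)
  if (length(top_fractions) && (any(top_fractions <= 0) || sum(top_fractions) >= 1)) {
    stop("top_fractions must be positive and sum to < 1", call. = FALSE)
  }
  if (n_proteins <= length(top_fractions)) {
    stop("n_proteins must exceed length(top_fractions)", call. = FALSE)
  }
  structure(list(
    n_proteins = as.integer(n_proteins), n_per_group = as.integer(n_per_group),
    top_fractions = top_fractions, de_fraction = de_fraction,
    de_log2fc = de_log2fc, cv_within_group = cv_within_group,
    base_meanlog = base_meanlog, base_sdlog = base_sdlog,
    mnar_midpoint = mnar_midpoint, mnar_steepness = mnar_steepness,
    mar_rate = mar_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

# Baseline abundances: top proteins are fixed so that, in expectation over the
# log-normal remainder, their share of total signal equals top_fractions.
sim_base_abundance <- function(config) {
  n_top <- length(config$top_fractions)
  n_rest <- config$n_proteins - n_top
  rest <- stats::rlnorm(n_rest, config$base_meanlog, config$base_sdlog)
  e_rest_total <- n_rest * exp(config$base_meanlog + config$base_sdlog^2 / 2)
  tops <- config$top_fractions / (1 - sum(config$top_fractions)) * e_rest_total
  c(tops, rest)
}

sim_noise_sdlog <- function(cv) sqrt(log(1 + cv^2))

# Per-cell dropout. Returns a character matrix: NA = observed, otherwise the
# mechanism that removed the cell. MNAR is drawn first (intensity-dependent
# left-censoring), MAR uniformly on the survivors.
sim_dropout <- function(values, config) {
  p_mnar <- stats::plogis(-(log2(values) - config$mnar_midpoint) * config$mnar_steepness)
  mech <- matrix(NA_character_, nrow(values), ncol(values),
                 dimnames = dimnames(values))
  u1 <- matrix(stats::runif(length(values)), nrow(values))
  u2 <- matrix(stats::runif(length(values)), nrow(values))
  mech[u1 < p_mnar] <- "MNAR_TRUE"
  mech[is.na(mech) & u2 < config$mar_rate] <- "MAR_TRUE"
  mech
}

#' Simulate a label-free quantification experiment with known truth
#'
#' Generates a raw-scale proteins-by-samples intensity table for an unpaired
#' multi-group design, together with the generating truth (baseline
#' abundances, true log2 fold changes, and the mechanism behind every missing
#' cell). True effects are applied to all non-reference groups; the leading
#' `top_fractions` proteins never carry an effect, mirroring the stability of
#' the dominant myelin proteins.
#'
#' @param config A [sim_config()].
#' @param design A [sample_design()] with at least two groups of at least two
#'   samples each; the first group (in order of appearance) is the reference.
#' @return A list with `matrix` (raw-scale intensity tibble, `NA` = missing),
#'   `truth` (per-protein tibble: `protein_id`, `true_base_abundance`,
#'   `true_log2fc`, `is_de`) and `dropout` (per missing cell: `protein_id`,
#'   `sample`, `mechanism`).
#' @examples
#' design <- sample_design(paste0("s", 1:6), rep(c("young", "old"), each = 3))
#' sim <- simulate_lfq_experiment(sim_config(n_proteins = 50, seed = 7), design)
#' sim$matrix
#' @export
simulate_lfq_experiment <- function(config, design) {
  stopifnot(inherits(config, "sim_config"))
  grps <- group_levels(design)
  if (length(grps) < 2) stop("design needs >= 2 groups", call. = FALSE)
  if (any(table(design$group) < 2) || config$n_per_group < 2) {
    stop("invalid design: each group needs >= 2 samples", call. = FALSE)
  }
  withr::with_seed(config$seed, {
    n <- config$n_proteins
    n_top <- length(config$top_fractions)
    ids <- sprintf("PROT%04d", seq_len(n))
    base <- sim_base_abundance(config)

    lfc <- numeric(n)
    eligible <- setdiff(seq_len(n), seq_len(n_top))
    n_de <- round(config$de_fraction * length(eligible))
    if (n_de > 0) {
      de_idx <- sample(eligible, n_de)
      lfc[de_idx] <- stats::rnorm(n_de, config$de_log2fc[["mean"]],
                                  config$de_log2fc[["sd"]])
    }

    sdlog <- sim_noise_sdlog(config$cv_within_group)
    is_ref <- design$group == grps[1]
    mu <- outer(base, rep(1, nrow(design))) *
      2^outer(lfc, as.numeric(!is_ref))
    vals <- mu * exp(matrix(stats::rnorm(n * nrow(design), 0, sdlog), n))
    dimnames(vals) <- list(ids, design$sample)

    mech <- sim_dropout(vals, config)
    vals[!is.na(mech)] <- NA_real_

    list(
      matrix = matrix_to_tbl(vals, "raw"),
      truth = tibble::tibble(protein_id = ids, true_base_abundance = base,
                             true_log2fc = lfc, is_de = lfc != 0),
      dropout = dropout_tbl(mech)
    )
  })
}

dropout_tbl <- function(mech) {
  idx <- which(!is.na(mech), arr.ind = TRUE)
  tibble::tibble(
    protein_id = rownames(mech)[idx[, 1]],
    sample = colnames(mech)[idx[, 2]],
    mechanism = mech[idx]
  )
}

#' Simulate a paired nerve-injury experiment
#'
#' One intact and one crushed sample per mouse. A designated leading block of
#' proteins plays the role of the myelin proteome; a `down_fraction` of it is
#' truly downregulated after crush (negative log2 fold change, crush minus
#' intact), while a `down_fraction_other` of the remaining proteins is
#' downregulated as background regulation. A shared per-mouse multiplicative
#' effect makes the design genuinely paired.
#'
#' @param config A [sim_config()]; `de_log2fc` supplies the magnitude
#'   distribution of the (negative) injury effects.
#' @param n_mice Number of mice (>= 2).
#' @param down_fraction Fraction of the myelin block truly downregulated.
#' @param down_fraction_other Fraction of non-myelin proteins downregulated.
#' @param myelin_size Size of the designated myelin block (first proteins).
#' @param mouse_effect_sdlog SD of the per-mouse log-normal random effect.
#' @param seed Seed; defaults to `config$seed`.
#' @return A list with `matrix`, `design` (with `pair_id`), `truth`,
#'   `dropout` and `myelin_ids`.
#' @export
simulate_injury_experiment <- function(config, n_mice, down_fraction,
                                       down_fraction_other = 0,
                                       myelin_size = min(200L, config$n_proteins %/% 2L),
                                       mouse_effect_sdlog = 0.1,
                                       seed = config$seed) {
  stopifnot(inherits(config, "sim_config"),
            down_fraction >= 0, down_fraction <= 1,
            down_fraction_other >= 0, down_fraction_other <= 1,
            myelin_size >= 1, myelin_size < config$n_proteins)
  if (n_mice < 2) stop("invalid design: need >= 2 mice", call. = FALSE)
  withr::with_seed(seed, {
    n <- config$n_proteins
    ids <- sprintf("PROT%04d", seq_len(n))
    base <- sim_base_abundance(config)

    # per-protein Bernoulli, so the regulated count in any subset is itself
    # binomial -- the sampling model the downstream enrichment test assumes
    draw_down <- function(idx, frac) idx[stats::runif(length(idx)) < frac]
    myelin_idx <- seq_len(myelin_size)
    down_idx <- c(draw_down(myelin_idx, down_fraction),
                  draw_down(setdiff(seq_len(n), myelin_idx), down_fraction_other))
    lfc <- numeric(n)
    lfc[down_idx] <- -abs(stats::rnorm(length(down_idx), config$de_log2fc[["mean"]],
                                       config$de_log2fc[["sd"]]))

    mice <- sprintf("mouse%02d", seq_len(n_mice))
    design <- sample_design(
      sample = c(paste0(mice, "_intact"), paste0(mice, "_crush")),
      group = rep(c("intact", "crush"), each = n_mice),
      pair_id = rep(mice, 2)
    )
    mouse_eff <- exp(stats::rnorm(n_mice, 0, mouse_effect_sdlog))
    mouse_mult <- rep(mouse_eff, 2)

    sdlog <- sim_noise_sdlog(config$cv_within_group)
    is_crush <- design$group == "crush"
    mu <- outer(base, mouse_mult) * 2^outer(lfc, as.numeric(is_crush))
    vals <- mu * exp(matrix(stats::rnorm(n * nrow(design), 0, sdlog), n))
    dimnames(vals) <- list(ids, design$sample)

    mech <- sim_dropout(vals, config)
    vals[!is.na(mech)] <- NA_real_

    list(
      matrix = matrix_to_tbl(vals, "raw"),
      design = design,
      truth = tibble::tibble(protein_id = ids, true_base_abundance = base,
                             true_log2fc = lfc, is_de = lfc != 0),
      dropout = dropout_tbl(mech),
      myelin_ids = ids[myelin_idx]
    )
  })
}

#' Generate a two-channel image fixture with exact truth masks
#'
#' Builds a myelin channel (annular "rings", the cross-section appearance of
#' myelin sheaths stained for MBP) and a collagen channel whose signal either
#' lies entirely outside the rings (`"separate"`) or entirely on the ring
#' annuli (`"overlapping"`), so coverage of the collagen mask by the myelin
#' mask is 0 or 100 percent by construction. Intensities are exact constants;
#' truth masks are returned pixel-exact.
#'
#' @param n_rings Number of rings (placed on a jittered grid).
#' @param ring_intensity Intensity of ring pixels in the MBP channel.
#' @param collagen_pattern `"separate"` or `"overlapping"`.
#' @param seed Integer seed for the jitter.
#' @param dim Image dimensions (pixels).
#' @param col_intensity Intensity of collagen-positive pixels.
#' @return A list with numeric matrices `channel_mbp`, `channel_col` and
#'   logical matrices `mask_mbp`, `mask_col`.
#' @export
generate_image_fixture <- function(n_rings, ring_intensity,
                                   collagen_pattern = c("separate", "overlapping"),
                                   seed = 1L, dim = c(96L, 96L),
                                   col_intensity = 100) {
  collagen_pattern <- match.arg(collagen_pattern)
  stopifnot(all(dim > 0), ring_intensity >= 0, col_intensity >= 0, n_rings >= 0)
  if (n_rings == 0 && collagen_pattern == "overlapping") {
    stop("degenerate fixture: overlapping pattern needs at least one ring",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    nr <- dim[1]; nc <- dim[2]
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    mask_mbp <- matrix(FALSE, nr, nc)

    if (n_rings > 0) {
      # ring centres on a grid with jitter; radii fixed relative to spacing
      side <- ceiling(sqrt(n_rings))
      spacing <- floor(min(nr, nc) / (side + 1))
      r_outer <- max(3, floor(spacing / 3))
      r_inner <- max(1, floor(r_outer / 2))
      centers <- expand.grid(i = seq_len(side), j = seq_len(side))[seq_len(n_rings), ]
      for (k in seq_len(n_rings)) {
        ci <- centers$i[k] * spacing + sample(-1:1, 1)
        cj <- centers$j[k] * spacing + sample(-1:1, 1)
        d2 <- (rows - ci)^2 + (cols - cj)^2
        mask_mbp <- mask_mbp | (d2 <= r_outer^2 & d2 >= r_inner^2)
      }
    }

    mask_col <- matrix(FALSE, nr, nc)
    if (collagen_pattern == "overlapping") {
      # collagen occupies roughly half the ring pixels -> strictly inside MBP
      ring_px <- which(mask_mbp)
      mask_col[ring_px[seq_len(max(1L, length(ring_px) %/% 2L))]] <- TRUE
    } else {
      # thin vertical strands, restricted to pixels off the rings
      strand_cols <- unique(pmin(nc, pmax(1, round(seq(2, nc - 1, length.out = 4)))))
      mask_col[, strand_cols] <- TRUE
      mask_col[mask_mbp] <- FALSE
    }

    channel_mbp <- matrix(0, nr, nc); channel_mbp[mask_mbp] <- ring_intensity
    channel_col <- matrix(0, nr, nc); channel_col[mask_col] <- col_intensity
    list(channel_mbp = channel_mbp, channel_col = channel_col,
         mask_mbp = mask_mbp, mask_col = mask_col)
  })
}
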