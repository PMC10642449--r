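# Shared fixtures and independent oracles, built in code at test time.

design_2x3 <- function(groups = c("young", "old")) {
  sample_design(paste0("s", 1:6), rep(groups, each = 3))
}

# generator config with all dropout disabled
clean_config <- function(...) {
  sim_config(mnar_midpoint = -Inf, mar_rate = 0, ...)
}

tbl_from_matrix <- function(m, scale = "log2") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("P%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  x <- tibble::as_tibble(m, .name_repair = "minimal")
  x <- tibble::add_column(x, protein_id = rownames(m), .before = 1)
  intensity_tbl(x, scale)
}

# brute-force digest: scan positions one by one, cutting after K/R not
# followed by P; written independently of the package's vectorised path
oracle_digest <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  peptides <- character()
  current <- ""
  for (i in seq_along(chars)) {
    current <- paste0(current, chars[i])
    cut_here <- chars[i] %in% c("K", "R") &&
      i < length(chars) && chars[i + 1] != "P"
    if (cut_here) {
      peptides <- c(peptides, current)
      current <- ""
    }
  }
  c(peptides, current)
}

# mid-rank Spearman oracle: explicit average-rank assignment then the
# product-moment formula written out longhand
oracle_spearman_rho <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# exact upper binomial tail by direct pmf summation
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), numeric(1)))
}

# one-sided (enrichment) Fisher p by full hypergeometric enumeration
oracle_fisher_greater <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; m1 <- a + c; n <- a + b + c + d
  js <- max(0, m1 - r2):min(r1, m1)
  pmf <- vapply(js, function(j) {
    choose(r1, j) * choose(r2, m1 - j) / choose(n, m1)
  }, numeric(1))
  sum(pmf[js >= a])
}

# literal transcription of the triplicate missingness rule, evaluated on
# observed-counts, independent of the package classifier
oracle_classify <- function(obs1, obs2) {
  if (obs1 == 3 && obs2 == 3) return("COMPLETE")
  if (obs1 < 2 && obs2 < 2) return("FILTERED")
  if ((3 - obs1) >= 2 && obs2 == 3) return("MNAR")
  if ((3 - obs2) >= 2 && obs1 == 3) return("MNAR")
  if ((3 - obs1) <= 1 && (3 - obs2) <= 1) return("MAR")
  "FILTERED"
}

# build an intensity tibble from explicit presence patterns (x = observed)
pattern_tbl <- function(pat1, pat2) {
  v <- c(pat1, pat2)
  vals <- ifelse(v == 1, 10 + seq_along(v), NA_real_)
  tbl_from_matrix(matrix(vals, nrow = 1,
                         dimnames = list("P001", paste0("s", 1:6))))
}

# de_result-shaped tibble with a prescribed number of qualifying rows
fake_de <- function(n, k, direction = "down") {
  sgn <- if (direction == "down") -1 else 1
  tibble::tibble(
    protein_id = sprintf("P%04d", seq_len(n)),
    log2fc = c(rep(sgn, k), rep(-sgn, n - k)),
    q = c(rep(0.01, k), rep(0.9, n - k))
  )
}
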