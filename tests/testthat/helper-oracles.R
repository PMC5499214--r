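# Independent oracles used across the suite. All deliberately naive:
# per-bp boolean masks for interval algebra, an erf-series normal CDF with
# bisection quantiles for the meta-analysis, exhaustive enumeration for the
# permutation test, and a literal two-pass running sum for the GSEA curve.

# ---- per-bp mask oracle for interval algebra --------------------------------

# rasterise a chrom/start/end table onto one logical vector per chromosome
rasterise <- function(df, chrom_len) {
  chroms <- sort(unique(df$chrom))
  masks <- lapply(chroms, function(ch) {
    m <- logical(chrom_len)
    sub <- df[df$chrom == ch, ]
    for (i in seq_len(nrow(sub))) {
      m[(sub$start[i] + 1):sub$end[i]] <- TRUE  # BED bp k covers 1-based k+1
    }
    m
  })
  stats::setNames(masks, chroms)
}

mask_equal <- function(a_df, b_df, chrom_len) {
  chroms <- sort(unique(c(a_df$chrom, b_df$chrom)))
  for (ch in chroms) {
    ma <- if (ch %in% a_df$chrom) rasterise(a_df, chrom_len)[[ch]] else logical(chrom_len)
    mb <- if (ch %in% b_df$chrom) rasterise(b_df, chrom_len)[[ch]] else logical(chrom_len)
    if (!identical(ma, mb)) return(FALSE)
  }
  TRUE
}

mask_to_intervals <- function(mask, chrom) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  tibble::tibble(chrom = chrom, start = starts[keep], end = ends[keep])
}

mask_op <- function(a_df, b_df, chrom_len, op) {
  chroms <- sort(unique(c(a_df$chrom, b_df$chrom)))
  out <- lapply(chroms, function(ch) {
    ma <- if (ch %in% a_df$chrom) rasterise(a_df, chrom_len)[[ch]] else logical(chrom_len)
    mb <- if (ch %in% b_df$chrom) rasterise(b_df, chrom_len)[[ch]] else logical(chrom_len)
    mask_to_intervals(op(ma, mb), ch)
  })
  dplyr::bind_rows(out)
}

# O(n^2) fixpoint clustering, a different algorithm from the package's
# single left-to-right sweep
oracle_cluster <- function(df, max_gap) {
  repeat {
    df <- df[order(df$chrom, df$start), ]
    merged_any <- FALSE
    i <- 1
    while (i < nrow(df)) {
      same <- df$chrom[i] == df$chrom[i + 1]
      if (same && df$start[i + 1] - df$end[i] < max_gap) {
        df$end[i] <- max(df$end[i], df$end[i + 1])
        df <- df[-(i + 1), ]
        merged_any <- TRUE
      } else i <- i + 1
    }
    if (!merged_any) return(df)
  }
}

random_intervals <- function(n, n_chrom = 2, chrom_len = 1e5, max_len = 5000) {
  len <- sample.int(max_len, n, replace = TRUE)
  start <- vapply(len, function(l) sample.int(chrom_len - l, 1) - 1, numeric(1))
  tibble::tibble(chrom = paste0("c", sample.int(n_chrom, n, replace = TRUE)),
                 start = start, end = start + len)
}

# ---- high-precision normal CDF / quantile oracle ----------------------------

# erf by Maclaurin series (|x| <= 6 is ample here: terms shrink fast and
# alternate, so the truncation error is below the last term)
oracle_erf <- function(x) {
  s <- 0
  term <- x
  n <- 0
  repeat {
    s <- s + term / (2 * n + 1)
    n <- n + 1
    term <- -term * x * x / n
    if (abs(term) < 1e-18 * max(1, abs(s))) break
    if (n > 500) break
  }
  2 / sqrt(pi) * s
}

oracle_phi <- function(x) 0.5 * (1 + oracle_erf(x / sqrt(2)))

# standard-normal quantile by bisection on oracle_phi
oracle_qnorm <- function(p, lo = -9, hi = 9, tol = 1e-13) {
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (oracle_phi(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# ---- exhaustive permutation enumeration -------------------------------------

# exact mean and distribution of significant counts over all draws of
# size k from the SNPs outside the set
exhaustive_m_s <- function(sig_outside, k) {
  draws <- utils::combn(length(sig_outside), k)
  apply(draws, 2, function(ix) sum(sig_outside[ix]))
}

# ---- naive two-pass GSEA curve ----------------------------------------------

oracle_es_curve <- function(scores, member) {
  N <- length(scores)
  N_E <- sum(member)
  N_R <- sum(scores[member])
  es <- numeric(N)
  p_hit <- 0
  p_miss <- 0
  for (j in seq_len(N)) {
    if (member[j]) p_hit <- p_hit + scores[j] / N_R
    else p_miss <- p_miss + 1 / (N - N_E)
    es[j] <- p_hit - p_miss
  }
  es
}
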