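#' Permutation test for enrichment of significant SNPs in an annotation set
#'
#' Tests whether an interval set (e.g. a candidate enhancer set) contains
#' more genome-wide-significant SNPs than expected by chance. Each of
#' `n_perm` random draws samples, without replacement, as many SNPs as the
#' set contains (`N_E`) from the SNPs *outside* the set ("the rest of the
#' genome") and counts how many are significant (`m_s`). The observed count
#' inside the set is `n_s`; the fold change is `n_s / mean(m_s)`. The rank P
#' value is `R / (n_perm + 1)` with `R` the number of draws whose `m_s`
#' equals or exceeds `n_s` (ties count against significance); when `n_s`
#' strictly exceeds every draw the P value is below the test's resolution
#' and reported as `< 1 / (n_perm + 1)` (with 10,000 draws, `< 0.0001`).
#'
#' @param snps Data frame with one row per tested SNP, a logical
#'   significance column (`significant`, as produced by [meta_analyze()])
#'   and a logical membership column (see `member_col`); or pass `set` to
#'   compute membership here.
#' @param set Optional [interval_set()]; if supplied, membership is computed
#'   with [snps_in_set()] (requires `chrom` and `pos` columns).
#' @param member_col Name of the logical membership column.
#' @param n_perm Number of random draws (default 10,000).
#' @param seed Integer seed; the same seed gives identical results. The
#'   caller's random state is left untouched.
#' @return An object of class `perm_enrichment` with fields `set_name`,
#'   `N_E`, `n_s`, `m_s` (all per-draw counts), `fold_change`
#'   (`NA` with `fold_defined = FALSE` when `mean(m_s) = 0` and `n_s > 0`;
#'   0 when `n_s = 0`), `rank_R`, `p_value`, `p_below_resolution`, `n_perm`,
#'   `seed`. See [tidy()], [glance()] and [autoplot()] methods.
#' @examples
#' snps <- tibble::tibble(
#'   snp_id = paste0("s", 1:10),
#'   significant = c(TRUE, TRUE, TRUE, rep(FALSE, 7)),
#'   in_set = c(TRUE, TRUE, rep(FALSE, 8))
#' )
#' perm_enrichment(snps, n_perm = 1000, seed = 1)
#' @export
perm_enrichment <- function(snps, set = NULL, member_col = "in_set",
                            n_perm = 10000, seed = NULL) {
  stopifnot(is.data.frame(snps), n_perm >= 1)
  if (!is.null(set)) {
    snps <- snps_in_set(snps, set, col = member_col)
    label <- set_name(set)
  } else {
    label <- member_col
  }
  if (!member_col %in% names(snps)) {
    stop("membership column '", member_col, "' not found; supply `set` or run snps_in_set()")
  }
  if (!"significant" %in% names(snps)) {
    stop("snps must carry a logical 'significant' column (see meta_analyze())")
  }
  member <- as.logical(snps[[member_col]])
  sig <- as.logical(snps$significant)
  N_E <- sum(member)
  if (N_E == 0) stop("the set contains no SNPs (N_E = 0); nothing to test")
  sig_out <- sig[!member]
  if (length(sig_out) < N_E) {
    stop(sprintf("only %d SNPs outside the set but draws of size N_E = %d are required",
                 length(sig_out), N_E))
  }
  n_s <- sum(sig[member])

  m_s <- with_seed_if(seed, {
    vapply(seq_len(n_perm),
           function(k) sum(sig_out[sample.int(length(sig_out), N_E)]),
           integer(1))
  })

  mean_m <- mean(m_s)
  if (n_s == 0) {
    fold <- 0; fold_defined <- TRUE
  } else if (mean_m == 0) {
    fold <- NA_real_; fold_defined <- FALSE
  } else {
    fold <- n_s / mean_m; fold_defined <- TRUE
  }
  rank_R <- sum(m_s >= n_s)
  below <- rank_R == 0
  p_value <- if (below) 1 / (n_perm + 1) else rank_R / (n_perm + 1)

  structure(
    list(set_name = label, N_E = N_E, n_s = n_s, m_s = m_s,
         fold_change = fold, fold_defined = fold_defined,
         rank_R = rank_R, p_value = p_value, p_below_resolution = below,
         n_perm = n_perm, seed = seed, n_snps = length(sig)),
    class = "perm_enrichment"
  )
}

# below-resolution results are conventionally printed against 1/n_perm
# (e.g. "<0.0001" for 10,000 draws); the stored numeric bound is 1/(n_perm+1)
format_perm_p <- function(x) {
  if (x$p_below_resolution) paste0("<", format(1 / x$n_perm)) else format(x$p_value)
}

#' @export
print.perm_enrichment <- function(x, ...) {
  cat(sprintf("# Permutation enrichment test: set '%s'\n", x$set_name))
  cat(sprintf("  N_E = %d of %d SNPs; n_s = %d significant in set\n",
              x$N_E, x$n_snps, x$n_s))
  cat(sprintf("  mean m_s = %.4g over %d draws; fold change = %s\n",
              mean(x$m_s), x$n_perm,
              if (x$fold_defined) format(x$fold_change, digits = 4) else "undefined"))
  cat(sprintf("  P = %s\n", format_perm_p(x)))
  invisible(x)
}

#' Tidy methods for permutation enrichment results
#'
#' `tidy()` returns the per-draw null counts (one row per draw); `glance()`
#' a one-row summary in the shape of a published enrichment table: `N_E`,
#' `n_s`, fold change and rank P.
#'
#' @param x A `perm_enrichment` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.perm_enrichment <- function(x, ...) {
  tibble::tibble(draw = seq_along(x$m_s), m_s = x$m_s)
}

#' @rdname tidy.perm_enrichment
#' @export
glance.perm_enrichment <- function(x, ...) {
  tibble::tibble(
    set = x$set_name, n_snps = x$n_snps, N_E = x$N_E, n_s = x$n_s,
    mean_m_s = mean(x$m_s), fold_change = x$fold_change,
    rank_R = x$rank_R, p_value = x$p_value,
    p_below_resolution = x$p_below_resolution,
    p_label = format_perm_p(x), n_perm = x$n_perm
  )
}

#' @rdname tidy.perm_enrichment
#' @param object A `perm_enrichment` object.
#' @export
autoplot.perm_enrichment <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$m_s)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$n_s, colour = "red", linewidth = 0.8) +
    ggplot2::labs(
      title = sprintf("Permutation null for set '%s'", object$set_name),
      subtitle = sprintf("n_s = %d, fold change = %s, P = %s",
                         object$n_s,
                         if (object$fold_defined) format(object$fold_change, digits = 3) else "undef.",
                         format_perm_p(object)),
      x = "significant SNPs per random draw (m_s)", y = "draws"
    )
}
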