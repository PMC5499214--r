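#' Standard error of a SNP effect recovered from its GWAS P value
#'
#' GWAS summary statistics often report only an effect size and a P value;
#' the standard error is recovered by inverting the normal test statistic.
#' Two inversions are provided. `"two-sided"` (the default) treats `p` as a
#' two-sided P value and returns `|beta| / qnorm(1 - p/2)`, consistent with
#' how the meta-analysis P value is later constructed. `"as-written"` applies
#' the quantile function directly at `p`, returning `|beta / qnorm(p)|`.
#'
#' @param beta Numeric vector of SNP effects.
#' @param p Numeric vector of GWAS P values in (0, 1].
#' @param mode `"two-sided"` or `"as-written"`.
#' @return Numeric vector of standard errors; `NA` marks a *filterable*
#'   record — `beta = 0`, `p = 1`, or a P value at which the chosen inversion
#'   has a zero denominator (`p = 0.5` in `"as-written"` mode). Such variants
#'   carry no usable information and are removed downstream.
#' @examples
#' snp_standard_error(0.4, 0.04550026)            # z = 2, se = 0.2
#' snp_standard_error(1.0, 0.05, mode = "as-written")
#' @export
snp_standard_error <- function(beta, p, mode = c("two-sided", "as-written")) {
  mode <- match.arg(mode)
  if (any(p <= 0 | p > 1, na.rm = TRUE)) {
    stop("P values must lie in (0, 1]")
  }
  z <- switch(mode,
    # qnorm(p/2, lower.tail = FALSE) == qnorm(1 - p/2) without the
    # catastrophic cancellation at very small p
    "two-sided"  = qnorm(p / 2, lower.tail = FALSE),
    "as-written" = qnorm(p)
  )
  se <- abs(beta / z)
  se[beta == 0 | p == 1 | z == 0 | !is.finite(se)] <- NA_real_
  se
}

#' Inverse-variance combination of per-cohort SNP effects
#'
#' Combines one SNP's effects across cohorts with weights
#' `w_j = se_j^-weight_exponent`: the weighted effect is
#' `beta_hat_j = beta_j * w_j`, the combined effect
#' `tilde_beta = sum(beta_hat) / sum(w)` and its dispersion
#' `tilde_v = sqrt(n / sum(w))` with `n` the number of cohorts. The default
#' `weight_exponent = 1` weights each cohort by the reciprocal of its
#' standard error; `weight_exponent = 2` gives the conventional
#' inverse-variance weighting `1/se^2`, under which a single-cohort
#' "meta-analysis" returns `tilde_v = se` and [meta_p_value()] inverts back
#' to the input P value exactly.
#'
#' @param beta Per-cohort effects for one SNP.
#' @param se Per-cohort standard errors (all `> 0`).
#' @param weight_exponent Exponent on `1/se` in the weight (1 or 2).
#' @return A list with elements `w`, `beta_hat`, `tilde_beta`, `tilde_v`,
#'   `n_cohorts`. Invariant to cohort order.
#' @examples
#' combine_cohorts(beta = c(0.4, 0.2), se = c(0.2, 0.2))
#' @export
combine_cohorts <- function(beta, se, weight_exponent = 1) {
  stopifnot(length(beta) == length(se), length(beta) >= 1)
  if (any(!is.finite(se) | se <= 0)) stop("all standard errors must be finite and > 0")
  w <- se^(-weight_exponent)
  beta_hat <- beta * w
  list(
    w = w,
    beta_hat = beta_hat,
    tilde_beta = sum(beta_hat) / sum(w),
    tilde_v = sqrt(length(beta) / sum(w)),
    n_cohorts = length(beta)
  )
}

#' Two-sided meta-analysis P value
#'
#' `tilde_p = 2 * (1 - pnorm(|tilde_beta / tilde_v|))`, the two-sided
#' standard-normal tail probability of the combined test statistic.
#'
#' @param tilde_beta Combined SNP effect(s).
#' @param tilde_v Combined dispersion(s), all `> 0`.
#' @return P values in (0, 1].
#' @examples
#' meta_p_value(0.3, 0.4472136)
#' @export
meta_p_value <- function(tilde_beta, tilde_v) {
  if (any(!is.finite(tilde_v) | tilde_v <= 0)) stop("tilde_v must be > 0")
  # upper-tail form keeps precision for large |z|; floored so the result
  # stays strictly positive
  pmax(2 * pnorm(abs(tilde_beta / tilde_v), lower.tail = FALSE), 1e-320)
}

#' Meta-analyse two-cohort GWAS summary statistics
#'
#' Runs the full per-SNP inverse-variance meta-analysis over a long table of
#' cohort summary statistics: recover standard errors from (beta, P), weight
#' and combine effects across cohorts, compute the combined two-sided P
#' value, remove uninformative variants, and flag genome-wide significance.
#'
#' Variants with no effect (`beta = 0`) or with a P value of 1 in any cohort
#' carry no recoverable standard error and are removed, as are variants whose
#' combined effect is exactly 0 or whose combined P value is 1. Counts at
#' every removal step are recorded in the `filter_log` attribute.
#'
#' @param stats Data frame with columns `snp_id`, `chrom`, `pos`, `cohort`,
#'   `beta`, `p` — one row per SNP per cohort (e.g. bulls and cows).
#' @param se_mode Passed to [snp_standard_error()].
#' @param weight_exponent Passed to [combine_cohorts()].
#' @param threshold Genome-wide significance cutoff on the meta P value
#'   (default `1e-8`); a variant is significant iff `tilde_p <= threshold`.
#' @param single_cohort `"combine"` (default) meta-analyses SNPs observed in
#'   only one cohort with `n = 1`; `"drop"` removes them.
#' @param details If `TRUE`, attach list-columns `cohorts`, `se_by_cohort`,
#'   `w_by_cohort`, `beta_hat_by_cohort` with the per-cohort intermediates.
#' @return A tibble with columns `snp_id`, `chrom`, `pos`, `n_cohorts`,
#'   `tilde_beta`, `tilde_v`, `tilde_p`, `significant`, sorted by
#'   `(chrom, pos)`, with attribute `filter_log` (a tibble of step/count
#'   bookkeeping). Results are invariant to the order of input rows.
#' @examples
#' stats <- tibble::tibble(
#'   snp_id = "rs1", chrom = "1", pos = 100,
#'   cohort = c("bulls", "cows"),
#'   beta = c(0.4, 0.2), p = c(0.04550026, 0.3173105)
#' )
#' meta_analyze(stats)
#' @export
meta_analyze <- function(stats,
                         se_mode = c("two-sided", "as-written"),
                         weight_exponent = 1,
                         threshold = 1e-8,
                         single_cohort = c("combine", "drop"),
                         details = FALSE) {
  se_mode <- match.arg(se_mode)
  single_cohort <- match.arg(single_cohort)
  stopifnot(is.data.frame(stats), threshold > 0, threshold < 1)
  need <- c("snp_id", "chrom", "pos", "cohort", "beta", "p")
  missing_cols <- setdiff(need, names(stats))
  if (length(missing_cols) > 0) {
    stop("cohort statistics lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- tibble::as_tibble(stats)[need]
  if (any(df$p <= 0 | df$p > 1)) stop("P values must lie in (0, 1]")

  pos_check <- df |>
    dplyr::distinct(.data$snp_id, .data$chrom, .data$pos) |>
    dplyr::count(.data$snp_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(pos_check) > 0) {
    stop("snp_id mapped to multiple (chrom, pos): ",
         paste(head(pos_check$snp_id, 3), collapse = ", "))
  }

  df$se <- snp_standard_error(df$beta, df$p, mode = se_mode)
  n_input_snps <- dplyr::n_distinct(df$snp_id)

  # a SNP with any cohort record that cannot yield an se is removed
  bad_ids <- unique(df$snp_id[is.na(df$se)])
  keep <- !(df$snp_id %in% bad_ids)
  log <- tibble::tibble(step = "input SNPs", n = n_input_snps)
  log <- dplyr::add_row(log, step = "removed: no effect or P = 1 in a cohort",
                        n = length(bad_ids))
  df <- df[keep, ]

  grouped <- df |>
    dplyr::group_by(.data$snp_id, .data$chrom, .data$pos) |>
    dplyr::summarise(
      n_cohorts = dplyr::n(),
      sum_w = sum(.data$se^(-weight_exponent)),
      sum_beta_hat = sum(.data$beta * .data$se^(-weight_exponent)),
      .groups = "drop"
    )
  if (single_cohort == "drop") {
    n_single <- sum(grouped$n_cohorts == 1)
    log <- dplyr::add_row(log, step = "removed: present in one cohort only", n = n_single)
    grouped <- grouped[grouped$n_cohorts > 1, ]
  }

  out <- grouped |>
    dplyr::mutate(
      tilde_beta = .data$sum_beta_hat / .data$sum_w,
      tilde_v = sqrt(.data$n_cohorts / .data$sum_w),
      tilde_p = meta_p_value(.data$tilde_beta, .data$tilde_v)
    )
  drop_meta <- out$tilde_beta == 0 | out$tilde_p == 1
  log <- dplyr::add_row(log, step = "removed: combined effect 0 or combined P = 1",
                        n = sum(drop_meta))
  out <- out[!drop_meta, ]
  out <- out |>
    dplyr::mutate(significant = .data$tilde_p <= threshold) |>
    dplyr::select("snp_id", "chrom", "pos", "n_cohorts",
                  "tilde_beta", "tilde_v", "tilde_p", "significant") |>
    dplyr::arrange(.data$chrom, .data$pos, .data$snp_id)
  log <- dplyr::add_row(log, step = "SNPs tested", n = nrow(out))
  log <- dplyr::add_row(log, step = "significant SNPs", n = sum(out$significant))

  if (details) {
    det <- df |>
      dplyr::mutate(w = .data$se^(-weight_exponent),
                    beta_hat = .data$beta * .data$w) |>
      dplyr::group_by(.data$snp_id) |>
      dplyr::summarise(cohorts = list(.data$cohort),
                       se_by_cohort = list(.data$se),
                       w_by_cohort = list(.data$w),
                       beta_hat_by_cohort = list(.data$beta_hat),
                       .groups = "drop")
    out <- dplyr::left_join(out, det, by = "snp_id")
  }
  attr(out, "filter_log") <- log
  attr(out, "threshold") <- threshold
  out
}

#' Filtering bookkeeping of a meta-analysis
#'
#' @param meta Result of [meta_analyze()].
#' @return A tibble with columns `step` and `n`: input variants, variants
#'   removed at each filter, variants tested, significant variants.
#' @export
filter_log <- function(meta) {
  attr(meta, "filter_log") %||%
    stop("no filter_log attribute; was this produced by meta_analyze()?")
}
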