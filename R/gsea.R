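#' Rank SNPs by association strength for the running-sum enrichment test
#'
#' Orders SNPs by descending score `-log10(P)` (most significant first) and
#' attaches set membership. Ties in the score are broken by
#' `(chrom, pos, snp_id)` so the ranking is deterministic.
#'
#' @param snps Data frame with columns `snp_id` and either a `score` column
#'   or a `tilde_p` column from which `score = -log10(tilde_p)` is computed;
#'   `chrom`/`pos` are used for tie-breaking when present.
#' @param set Optional [interval_set()] used to compute membership via
#'   [snps_in_set()].
#' @param member_col Name of the logical membership column.
#' @return A tibble of class `ranked_snps`, sorted by decreasing score, with
#'   columns `snp_id`, `score`, `member` (plus `chrom`/`pos` when supplied)
#'   and attributes `N`, `N_E`, `N_R` (sum of member scores), `set_name`.
#' @export
rank_snps <- function(snps, set = NULL, member_col = "in_set") {
  stopifnot(is.data.frame(snps))
  if (!is.null(set)) {
    snps <- snps_in_set(snps, set, col = member_col)
    label <- set_name(set)
  } else {
    label <- member_col
  }
  if (!member_col %in% names(snps)) {
    stop("membership column '", member_col, "' not found; supply `set` or run snps_in_set()")
  }
  df <- tibble::as_tibble(snps)
  if (!"score" %in% names(df)) {
    if (!"tilde_p" %in% names(df)) stop("need a 'score' or 'tilde_p' column")
    df$score <- -log10(df$tilde_p)
  }
  df$member <- as.logical(df[[member_col]])
  sort_cols <- intersect(c("chrom", "pos", "snp_id"), names(df))
  df <- dplyr::arrange(df, dplyr::desc(.data$score),
                       !!!rlang::syms(sort_cols))
  keep <- intersect(c("snp_id", "chrom", "pos", "score", "member"), names(df))
  df <- df[keep]
  N <- nrow(df); N_E <- sum(df$member)
  if (N_E < 1 || N_E >= N) {
    stop(sprintf("need 1 <= N_E < N; got N_E = %d of N = %d", N_E, N))
  }
  structure(df, class = c("ranked_snps", class(tibble::tibble())),
            N = N, N_E = N_E, N_R = sum(df$score[df$member]),
            set_name = label)
}

#' Running-sum enrichment score curve
#'
#' Walks down a ranked SNP list accumulating a weighted hit term for set
#' members and a uniform miss term for non-members: at position `j`, a
#' member with score `s` adds `s / N_R` (where `N_R` is the total score of
#' all members) and a non-member adds `1 / (N - N_E)`; the enrichment score
#' is the running difference `ES_j = P_hit(j) - P_miss(j)`. Both cumulative
#' terms reach 1 at the end of the list, so the curve always terminates at 0
#' and every value lies in `[-1, 1]`.
#'
#' @param ranked A [rank_snps()] result (requires `N_R > 0`).
#' @return Numeric vector of `ES_j`, one value per ranked position.
#' @examples
#' r <- rank_snps(tibble::tibble(snp_id = paste0("s", 1:4),
#'                               score = c(4, 3, 2, 1),
#'                               in_set = c(FALSE, TRUE, FALSE, TRUE)))
#' es_curve(r)   # -0.5, 0.25, -0.25, 0
#' @export
es_curve <- function(ranked) {
  stopifnot(inherits(ranked, "ranked_snps"))
  N <- attr(ranked, "N"); N_E <- attr(ranked, "N_E"); N_R <- attr(ranked, "N_R")
  if (N_R <= 0) stop("N_R (total member score) must be > 0")
  incr <- ifelse(ranked$member, ranked$score / N_R, -1 / (N - N_E))
  cumsum(incr)
}

max_positive_excursion <- function(es) {
  m <- max(es)
  if (m > 0) list(es_max = m, position = which.max(es), positive = TRUE)
  else list(es_max = 0, position = 0L, positive = FALSE)
}

#' Peak enrichment score and core SNP set
#'
#' `ES_max` is the maximum positive excursion of the running enrichment
#' score; its position defines the strength and location of the enrichment
#' signal, and the member SNPs ranked at or before that position form the
#' candidate core set driving the signal. The maximal absolute deviation is
#' also reported for diagnostics.
#'
#' @param es Curve from [es_curve()].
#' @param ranked The [rank_snps()] result the curve came from.
#' @param include_peak_snp If `TRUE` (default) a member SNP at the peak
#'   position itself belongs to the core set (it is what creates the peak);
#'   if `FALSE` only members strictly before the peak are included.
#' @return A list with `es_max`, `es_max_position` (earliest position
#'   attaining the maximum; 0 with an empty core and
#'   `positive_excursion = FALSE` when the curve never rises above 0),
#'   `core_snp_ids`, `es_max_abs`.
#' @export
es_max_core <- function(es, ranked, include_peak_snp = TRUE) {
  stopifnot(length(es) == nrow(ranked))
  peak <- max_positive_excursion(es)
  upto <- if (include_peak_snp) peak$position else max(peak$position - 1L, 0L)
  core <- ranked$snp_id[seq_len(upto)][ranked$member[seq_len(upto)]]
  list(es_max = peak$es_max, es_max_position = peak$position,
       core_snp_ids = core, es_max_abs = max(abs(es)),
       positive_excursion = peak$positive)
}

# ES_max of one membership assignment given scores fixed at ranks, without
# materialising the full curve: the running sum increases only at member
# positions, so the curve maximum is attained immediately after a hit.
es_max_fast <- function(scores, member_ranks, N, N_E) {
  r <- sort.int(member_ranks)
  sr <- scores[r]
  NR <- sum(sr)
  if (NR <= 0) return(0)
  es_at_hit <- cumsum(sr) / NR - (r - seq_along(r)) / (N - N_E)
  m <- max(es_at_hit)
  if (m > 0) m else 0
}

#' Running-sum (GSEA-style) enrichment test with a rank-shuffle null
#'
#' Computes the observed enrichment score curve, its peak `ES_max` and the
#' core SNP set, then builds a null distribution by repeatedly shuffling
#' which ranks are set members while keeping the score at every rank fixed,
#' recomputing `ES_max` each time. The result is called significant when the
#' observed `ES_max` exceeds every one of the `n_perm` null values; an
#' add-one empirical P value
#' `(1 + #\{ES_NULL >= ES_max\}) / (1 + n_perm)` is reported alongside so
#' the result stays usable at smaller `n_perm`.
#'
#' @inheritParams perm_enrichment
#' @param snps Data frame accepted by [rank_snps()] (needs `score` or
#'   `tilde_p`, plus membership or `set`).
#' @param include_peak_snp See [es_max_core()].
#' @param keep_curve If `TRUE` (default) the full observed ES curve is kept
#'   on the result for plotting.
#' @return An object of class `gsea_enrichment` with fields `set_name`, `N`,
#'   `N_E`, `es_max`, `es_max_position`, `es_max_abs`, `core_snp_ids`,
#'   `null_es_max` (`n_perm` values), `p_value`, `significant`, `seed`, and
#'   (optionally) `es` plus the ranked table. See [tidy()], [glance()],
#'   [autoplot()].
#' @examples
#' snps <- tibble::tibble(snp_id = paste0("s", 1:100),
#'                        score = sort(rexp(100), decreasing = TRUE),
#'                        in_set = c(rep(TRUE, 5), rep(FALSE, 95)))
#' gsea_enrichment(snps, n_perm = 200, seed = 1)
#' @export
gsea_enrichment <- function(snps, set = NULL, member_col = "in_set",
                            n_perm = 10000, seed = NULL,
                            include_peak_snp = TRUE, keep_curve = TRUE) {
  stopifnot(n_perm >= 1)
  ranked <- if (inherits(snps, "ranked_snps")) snps
            else rank_snps(snps, set = set, member_col = member_col)
  es <- es_curve(ranked)
  obs <- es_max_core(es, ranked, include_peak_snp = include_peak_snp)
  N <- attr(ranked, "N"); N_E <- attr(ranked, "N_E")
  scores <- ranked$score

  null_es_max <- with_seed_if(seed, {
    vapply(seq_len(n_perm),
           function(k) es_max_fast(scores, sample.int(N, N_E), N, N_E),
           numeric(1))
  })

  p_value <- (1 + sum(null_es_max >= obs$es_max)) / (1 + n_perm)
  structure(
    list(set_name = attr(ranked, "set_name"), N = N, N_E = N_E,
         es_max = obs$es_max, es_max_position = obs$es_max_position,
         es_max_abs = obs$es_max_abs,
         positive_excursion = obs$positive_excursion,
         core_snp_ids = obs$core_snp_ids,
         null_es_max = null_es_max, p_value = p_value,
         significant = obs$es_max > max(null_es_max),
         n_perm = n_perm, seed = seed,
         es = if (keep_curve) es else NULL,
         ranked = if (keep_curve) ranked else NULL),
    class = "gsea_enrichment"
  )
}

#' @export
print.gsea_enrichment <- function(x, ...) {
  cat(sprintf("# Running-sum enrichment test: set '%s'\n", x$set_name))
  cat(sprintf("  N = %d SNPs, N_E = %d members\n", x$N, x$N_E))
  cat(sprintf("  ES_max = %.4f at rank %d; core set: %d SNPs\n",
              x$es_max, x$es_max_position, length(x$core_snp_ids)))
  cat(sprintf("  significant (ES_max > all %d nulls): %s; empirical P = %.4g\n",
              x$n_perm, x$significant, x$p_value))
  invisible(x)
}

#' Tidy methods for running-sum enrichment results
#'
#' `tidy()` returns the observed enrichment-score curve (one row per ranked
#' SNP, requires `keep_curve = TRUE`); `glance()` a one-row summary.
#'
#' @param x A `gsea_enrichment` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gsea_enrichment <- function(x, ...) {
  if (is.null(x$es)) stop("curve not kept; rerun with keep_curve = TRUE")
  tibble::tibble(position = seq_along(x$es),
                 snp_id = x$ranked$snp_id,
                 score = x$ranked$score,
                 member = x$ranked$member,
                 es = x$es)
}

#' @rdname tidy.gsea_enrichment
#' @export
glance.gsea_enrichment <- function(x, ...) {
  tibble::tibble(
    set = x$set_name, n_snps = x$N, N_E = x$N_E,
    es_max = x$es_max, es_max_position = x$es_max_position,
    es_max_abs = x$es_max_abs,
    n_core = length(x$core_snp_ids),
    p_value = x$p_value, significant = x$significant,
    n_perm = x$n_perm
  )
}

#' @rdname tidy.gsea_enrichment
#' @param object A `gsea_enrichment` object.
#' @export
autoplot.gsea_enrichment <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$es)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(
      data = df[df$position == object$es_max_position, ],
      colour = "red", size = 2
    ) +
    ggplot2::geom_rug(data = df[df$member, ], sides = "b",
                      alpha = 0.3, length = ggplot2::unit(0.02, "npc")) +
    ggplot2::labs(
      title = sprintf("Enrichment score curve: set '%s'", object$set_name),
      subtitle = sprintf("ES_max = %.3f at rank %d; P = %.4g%s",
                         object$es_max, object$es_max_position, object$p_value,
                         if (object$significant) " (exceeds all nulls)" else ""),
      x = "rank (most significant first)", y = "running enrichment score"
    )
}
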