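derive_subsets <- function(sets, pair) {
  stopifnot(length(pair) == 2, all(pair %in% names(sets)))
  a <- sets[[pair[1]]]; b <- sets[[pair[2]]]
  out <- list(
    subtract_sets(a, b, name = paste0(pair[1], "-specific")),
    subtract_sets(b, a, name = paste0(pair[2], "-specific")),
    intersect_sets(a, b, name = paste0("overlap:", pair[1], "&", pair[2]))
  )
  stats::setNames(out, vapply(out, set_name, character(1)))
}

#' Run the full enrichment suite over traits and enhancer sets
#'
#' For every trait, meta-analyses the cohort summary statistics, then runs
#' both enrichment tests (size-matched permutation test and running-sum
#' GSEA) against every enhancer set — optionally including the derived
#' subsets of a nominated pair of sets (each set's specific-only regions
#' and their overlap) — and computes the pairwise overlap-percentage matrix
#' across the base sets. Per-analysis seeds are derived from the master
#' seed and the (trait, set, test) labels with [derive_seed()], so results
#' are reproducible and adding an analysis never changes the others.
#'
#' @param traits Named list; each element is a long cohort-statistics
#'   tibble (columns `snp_id`, `chrom`, `pos`, `cohort`, `beta`, `p`) or a
#'   character vector of per-cohort TSV paths (read with
#'   [read_cohort_stats()], cohort labels from names or file names).
#' @param sets Named list of [interval_set()] objects or BED file paths.
#' @param derive_pair Optional character vector of two set names whose
#'   specific-only and overlap subsets are tested as additional rows.
#' @param threshold Genome-wide significance cutoff (default `1e-8`).
#' @param n_perm Permutations/shuffles per test (default 10,000).
#' @param se_mode,weight_exponent Passed to [meta_analyze()].
#' @param cluster_gap Optional named numeric: sets to expand with
#'   [cluster_merge()] at the given gap before testing (e.g.
#'   `c(dbSUPER = 30000)`).
#' @param seed Master integer seed.
#' @param out_dir Optional directory; when given, TSV/JSON reports, core-SNP
#'   lists (for significant GSEA analyses only) and a run manifest are
#'   written there.
#' @return A list of class `enrichment_suite`: `permutation` and `gsea`
#'   (tibbles, one row per trait x set), `overlap` (an `overlap_matrix`),
#'   `core_snps` (named list, significant GSEA analyses only), `meta`
#'   (named list of meta tibbles), `filter_logs`, `manifest`.
#' @export
run_enrichment_suite <- function(traits, sets, derive_pair = NULL,
                                 threshold = 1e-8, n_perm = 10000,
                                 se_mode = "two-sided", weight_exponent = 1,
                                 cluster_gap = NULL,
                                 seed = 1, out_dir = NULL) {
  stopifnot(is.list(traits), length(traits) >= 1, !is.null(names(traits)),
            is.list(sets), length(sets) >= 1, !is.null(names(sets)),
            n_perm >= 1)

  sets <- lapply(stats::setNames(names(sets), names(sets)), function(nm) {
    s <- sets[[nm]]
    if (is.character(s)) s <- read_bed(s, name = nm)
    if (!inherits(s, "interval_set")) s <- interval_set(s, name = nm)
    s
  })
  for (nm in names(cluster_gap)) {
    if (!nm %in% names(sets)) stop("cluster_gap names unknown set: ", nm)
    sets[[nm]] <- cluster_merge(sets[[nm]], cluster_gap[[nm]])
  }
  ov <- overlap_matrix(sets)

  test_sets <- sets
  if (!is.null(derive_pair)) {
    test_sets <- c(test_sets, derive_subsets(sets, derive_pair))
  }

  perm_rows <- list(); gsea_rows <- list()
  core_snps <- list(); metas <- list(); logs <- list()

  for (trait in names(traits)) {
    tr <- traits[[trait]]
    if (is.character(tr)) {
      labels <- names(tr) %||% sub("\\.(tsv|txt)$", "", basename(tr))
      tr <- dplyr::bind_rows(purrr::map2(tr, labels, read_cohort_stats))
    }
    meta <- meta_analyze(tr, se_mode = se_mode,
                         weight_exponent = weight_exponent,
                         threshold = threshold)
    metas[[trait]] <- meta
    logs[[trait]] <- filter_log(meta)

    for (snm in names(test_sets)) {
      flagged <- snps_in_set(meta, test_sets[[snm]])
      key <- paste(trait, snm, sep = " / ")
      if (sum(flagged$in_set) == 0 ||
          sum(!flagged$in_set) < sum(flagged$in_set)) {
        perm_rows[[key]] <- tibble::tibble(
          trait = trait, set = snm, n_snps = nrow(flagged),
          N_E = sum(flagged$in_set), note = "degenerate: test not run")
        gsea_rows[[key]] <- perm_rows[[key]]
        next
      }
      pr <- perm_enrichment(flagged, n_perm = n_perm,
                            seed = derive_seed(seed, trait, snm, "perm"))
      perm_rows[[key]] <- glance(pr) |>
        dplyr::mutate(set = snm) |>
        dplyr::mutate(trait = trait, .before = 1)
      gr <- gsea_enrichment(flagged, n_perm = n_perm, keep_curve = FALSE,
                            seed = derive_seed(seed, trait, snm, "gsea"))
      gsea_rows[[key]] <- glance(gr) |>
        dplyr::mutate(set = snm) |>
        dplyr::mutate(trait = trait, .before = 1)
      if (gr$significant) core_snps[[key]] <- gr$core_snp_ids
    }
  }

  perm_tbl <- dplyr::bind_rows(perm_rows)
  gsea_tbl <- dplyr::bind_rows(gsea_rows)
  manifest <- list(
    package_version = as.character(utils::packageVersion("varenrich")),
    seed = seed, n_perm = n_perm, threshold = threshold,
    se_mode = se_mode, weight_exponent = weight_exponent,
    traits = names(traits), sets = names(sets),
    derive_pair = derive_pair,
    cluster_gap = as.list(cluster_gap)
  )
  res <- structure(list(permutation = perm_tbl, gsea = gsea_tbl,
                        overlap = ov, core_snps = core_snps,
                        meta = metas, filter_logs = logs,
                        manifest = manifest),
                   class = "enrichment_suite")
  if (!is.null(out_dir)) write_suite(res, out_dir)
  res
}

#' @export
print.enrichment_suite <- function(x, ...) {
  cat(sprintf("# Enrichment suite: %d trait(s) x %d set row(s), n_perm = %d\n",
              length(x$meta), length(unique(x$permutation$set)),
              x$manifest$n_perm))
  cat("\nPermutation tests:\n")
  cols <- intersect(c("trait", "set", "N_E", "n_s", "fold_change", "p_label"),
                    names(x$permutation))
  print(x$permutation[cols], n = Inf)
  cat("\nRunning-sum (GSEA) tests:\n")
  cols <- intersect(c("trait", "set", "es_max", "n_core", "p_value",
                      "significant"), names(x$gsea))
  print(x$gsea[cols], n = Inf)
  invisible(x)
}

write_suite <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(res$permutation, file.path(out_dir, "permutation.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$gsea, file.path(out_dir, "gsea.tsv"), progress = FALSE)
  utils::write.table(round(unclass(res$overlap), 4),
                     file.path(out_dir, "overlap_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  for (key in names(res$core_snps)) {
    fn <- paste0("core_snps_", gsub("[^A-Za-z0-9._-]+", "_", key), ".txt")
    writeLines(res$core_snps[[key]], file.path(out_dir, fn))
  }
  for (trait in names(res$filter_logs)) {
    readr::write_tsv(res$filter_logs[[trait]],
                     file.path(out_dir, paste0("filter_log_", trait, ".tsv")),
                     progress = FALSE)
  }
  jsonlite::write_json(
    list(permutation = res$permutation, gsea = res$gsea,
         manifest = res$manifest),
    file.path(out_dir, "results.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(res)
}

#' Heatmap of an overlap-percentage matrix
#'
#' @param object An `overlap_matrix` from [overlap_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.overlap_matrix <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("row_set", "col_set", "pct")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col_set, y = .data$row_set,
                                   fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$pct)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 100), name = "% of row") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Row-relative overlap percentages")
}
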