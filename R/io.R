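#' Read and write interval sets as BED
#'
#' `read_bed()` parses BED3+ records (chrom, start, end, optional name;
#' 0-based half-open). Lines beginning with `#`, `track` or `browser` are
#' skipped. By default overlapping records are merged so the result
#' satisfies the interval-set invariants; `merge = FALSE` keeps raw records
#' as a plain tibble. `write_bed()` emits sorted, merged BED4 records
#' (the set label in column 4).
#'
#' @param path File path.
#' @param name Set label; defaults to the file name without extension.
#' @param merge Merge overlapping records into an [interval_set()]
#'   (default `TRUE`).
#' @param strip_chr Strip a leading `"chr"` from chromosome labels.
#' @return `read_bed()`: an [interval_set()] (or tibble when
#'   `merge = FALSE`); `write_bed()`: the input, invisibly.
#' @export
read_bed <- function(path, name = NULL, merge = TRUE, strip_chr = FALSE) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  name <- name %||% sub("\\.(bed|txt)$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines)]
  if (length(lines) == 0) {
    df <- tibble::tibble(chrom = character(), start = numeric(), end = numeric())
    return(new_interval_set(df, name))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("malformed BED line %d in %s: fewer than 3 fields",
                 which(nf < 3)[1], path))
  }
  df <- tibble::tibble(
    chrom = vapply(fields, `[[`, character(1), 1),
    start = suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2))),
    end   = suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  )
  if (anyNA(df$start) || anyNA(df$end)) {
    stop("non-numeric coordinates in BED file: ", path)
  }
  if (merge) merge_intervals(df, name = name, strip_chr = strip_chr)
  else {
    if (strip_chr) df$chrom <- sub("^chr", "", df$chrom)
    df
  }
}

#' @rdname read_bed
#' @param set An [interval_set()] (raw tables are merged first).
#' @export
write_bed <- function(set, path) {
  if (!inherits(set, "interval_set")) set <- merge_intervals(set)
  df <- tibble::as_tibble(set)
  lines <- sprintf("%s\t%d\t%d\t%s", df$chrom, as.integer(df$start),
                   as.integer(df$end), set_name(set))
  writeLines(lines, path)
  invisible(set)
}

#' Read and write GWAS cohort summary statistics
#'
#' One tab-separated file per cohort with a header line and columns
#' `snp_id`, `chrom`, `pos` (1-based), `beta`, `p`.
#'
#' @param path File path.
#' @param cohort Cohort label attached to every row (e.g. `"bulls"`);
#'   defaults to the file name without extension.
#' @return A tibble with columns `snp_id`, `chrom`, `pos`, `cohort`,
#'   `beta`, `p`, suitable for [meta_analyze()].
#' @export
read_cohort_stats <- function(path, cohort = NULL) {
  if (!file.exists(path)) stop("cohort statistics file not found: ", path)
  cohort <- cohort %||% sub("\\.(tsv|txt)$", "", basename(path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("snp_id", "chrom", "pos", "beta", "p")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop(path, " lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[need]
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  for (col in c("pos", "beta", "p")) df[[col]] <- as.numeric(df[[col]])
  dplyr::mutate(df, cohort = cohort, .after = "pos")
}

#' @rdname read_cohort_stats
#' @param stats A cohort statistics tibble (long format, `cohort` column).
#' @export
write_cohort_stats <- function(stats, path) {
  readr::write_tsv(stats[c("snp_id", "chrom", "pos", "beta", "p")], path,
                   progress = FALSE)
  invisible(stats)
}

#' @rdname read_cohort_stats
#' @param meta A [meta_analyze()] result.
#' @export
write_meta_stats <- function(meta, path) {
  readr::write_tsv(meta[c("snp_id", "chrom", "pos", "tilde_beta",
                          "tilde_v", "tilde_p", "significant")], path,
                   progress = FALSE)
  invisible(meta)
}

gff3_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
  out <- rep(NA_character_, length(attrs))
  hit <- lengths(regmatches(attrs, gregexpr(paste0("(^|;)", key, "="), attrs))) > 0
  out[hit] <- sub(paste0("^;?", key, "="), "", m)
  out
}

#' Read a minimal GFF3 gene model
#'
#' Parses the subset of GFF3 needed for functional classification of
#' variants: `gene` features (with `ID=` and optional
#' `biotype=protein_coding` attributes) and their `exon`,
#' `five_prime_UTR`, `three_prime_UTR` and `stop_codon` children (linked by
#' `Parent=`). Coordinates are kept 1-based inclusive as in GFF3.
#'
#' @param path GFF3 file path.
#' @return A `gene_model` tibble with columns `gene_id`, `chrom`, `strand`,
#'   `feature`, `start`, `end`, `coding`.
#' @export
read_gene_model <- function(path) {
  if (!file.exists(path)) stop("gene model file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) {
    stop(sprintf("malformed GFF3 line %d in %s: fewer than 9 fields",
                 which(nf < 9)[1], path))
  }
  df <- tibble::tibble(
    chrom = vapply(fields, `[[`, character(1), 1),
    feature = vapply(fields, `[[`, character(1), 3),
    start = as.numeric(vapply(fields, `[[`, character(1), 4)),
    end = as.numeric(vapply(fields, `[[`, character(1), 5)),
    strand = vapply(fields, `[[`, character(1), 7),
    attrs = vapply(fields, `[[`, character(1), 9)
  )
  keep <- c("gene", "exon", "five_prime_UTR", "three_prime_UTR", "stop_codon")
  df <- df[df$feature %in% keep, ]
  genes <- df[df$feature == "gene", ]
  genes$gene_id <- gff3_attr(genes$attrs, "ID")
  bt <- gff3_attr(genes$attrs, "biotype")
  genes$coding <- is.na(bt) | bt == "protein_coding"
  kids <- df[df$feature != "gene", ]
  kids$gene_id <- gff3_attr(kids$attrs, "Parent")
  coding_map <- stats::setNames(genes$coding, genes$gene_id)
  kids$coding <- unname(coding_map[kids$gene_id])
  out <- dplyr::bind_rows(
    genes[c("gene_id", "chrom", "strand", "feature", "start", "end", "coding")],
    kids[c("gene_id", "chrom", "strand", "feature", "start", "end", "coding")]
  )
  gene_model(out)
}

#' Construct a gene model table
#'
#' @param x Data frame with columns `gene_id`, `chrom`, `strand`, `feature`
#'   (`gene`, `exon`, `five_prime_UTR`, `three_prime_UTR`, `stop_codon`),
#'   `start`, `end` (1-based inclusive) and logical `coding`.
#' @return A validated `gene_model` tibble.
#' @export
gene_model <- function(x) {
  need <- c("gene_id", "chrom", "strand", "feature", "start", "end", "coding")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("gene model lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- tibble::as_tibble(x)[need]
  stopifnot(all(df$start <= df$end), all(df$strand %in% c("+", "-", ".")))
  spans <- df[df$feature == "gene", ]
  kids <- df[df$feature != "gene", ]
  if (nrow(kids) > 0) {
    j <- dplyr::left_join(kids, spans[c("gene_id", "start", "end")],
                          by = "gene_id", suffix = c("", ".gene"))
    if (any(is.na(j$start.gene)) ||
        any(j$start < j$start.gene | j$end > j$end.gene)) {
      stop("gene model features must lie within their gene span")
    }
  }
  structure(dplyr::arrange(df, .data$chrom, .data$start),
            class = c("gene_model", class(tibble::tibble())))
}

#' @rdname read_gene_model
#' @param model A `gene_model` tibble.
#' @export
write_gene_model <- function(model, path) {
  stopifnot(inherits(model, "gene_model"))
  attrs <- ifelse(
    model$feature == "gene",
    sprintf("ID=%s;biotype=%s", model$gene_id,
            ifelse(model$coding, "protein_coding", "noncoding")),
    sprintf("Parent=%s", model$gene_id)
  )
  lines <- c("##gff-version 3",
             sprintf("%s\tvarenrich\t%s\t%d\t%d\t.\t%s\t.\t%s",
                     model$chrom, model$feature, as.integer(model$start),
                     as.integer(model$end), model$strand, attrs))
  writeLines(lines, path)
  invisible(model)
}
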