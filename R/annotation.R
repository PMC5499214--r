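FUNCTIONAL_CLASSES <- c("splicing", "stop", "5'-UTR", "3'-UTR", "exonic",
                        "non-coding exonic", "intronic", "upstream",
                        "downstream", "intergenic")

# class of one position relative to one gene's features; NA when the
# position is outside the gene span and outside both flanking windows
classify_against_gene <- function(pos, gene, feats, upstream, downstream,
                                  splice_window) {
  g_start <- gene$start; g_end <- gene$end
  plus <- gene$strand != "-"
  if (pos >= g_start && pos <= g_end) {
    within <- function(type) {
      f <- feats[feats$feature == type, ]
      nrow(f) > 0 && any(pos >= f$start & pos <= f$end)
    }
    exons <- feats[feats$feature == "exon", ]
    in_exon <- nrow(exons) > 0 && any(pos >= exons$start & pos <= exons$end)
    if (!in_exon && nrow(exons) > 1) {
      # intron boundaries are the bases adjacent to exon ends/starts
      ex <- exons[order(exons$start), ]
      ib <- c(ex$end[-nrow(ex)] + 1, ex$start[-1] - 1)
      if (any(abs(pos - ib) < splice_window)) return("splicing")
    }
    if (within("stop_codon")) return("stop")
    if (within("five_prime_UTR")) return("5'-UTR")
    if (within("three_prime_UTR")) return("3'-UTR")
    if (in_exon) return(if (isTRUE(gene$coding[1])) "exonic" else "non-coding exonic")
    return("intronic")
  }
  five_prime_ok <- if (plus) pos < g_start && pos >= g_start - upstream
                   else pos > g_end && pos <= g_end + upstream
  if (five_prime_ok) return("upstream")
  three_prime_ok <- if (plus) pos > g_end && pos <= g_end + downstream
                    else pos < g_start && pos >= g_start - downstream
  if (three_prime_ok) return("downstream")
  NA_character_
}

#' Assign a functional class to each variant from a gene model
#'
#' A simplified positional classifier: each SNP receives exactly one of the
#' classes splicing, stop, 5'-UTR, 3'-UTR, exonic, non-coding exonic,
#' intronic, upstream, downstream or intergenic. When a position satisfies
#' several definitions (e.g. overlapping genes), the most specific
#' annotation wins, in the priority order just listed. Upstream and
#' downstream are strand-aware windows beyond the gene ends; splicing means
#' an intronic base within `splice_window` bp of an intron boundary.
#'
#' @param snps Data frame with columns `chrom` and `pos` (1-based).
#' @param model A [gene_model()] tibble.
#' @param upstream,downstream Window sizes in bp beyond the 5' and 3' gene
#'   ends (defaults 5000).
#' @param splice_window Distance in bp from an intron boundary that counts
#'   as splicing (default 2).
#' @return `snps` as a tibble with a `functional_class` factor column
#'   (levels in priority order). Positions on chromosomes absent from the
#'   model are classed intergenic with a warning.
#' @export
classify_variants <- function(snps, model, upstream = 5000, downstream = 5000,
                              splice_window = 2) {
  stopifnot(is.data.frame(snps), all(c("chrom", "pos") %in% names(snps)),
            inherits(model, "gene_model"))
  if (any(snps$pos < 1)) stop("SNP positions must be >= 1")
  out <- tibble::as_tibble(snps)
  genes <- model[model$feature == "gene", ]
  feats_by_gene <- split(model[model$feature != "gene", ],
                         model$gene_id[model$feature != "gene"])
  cls <- rep("intergenic", nrow(out))
  unknown <- !(out$chrom %in% unique(genes$chrom))
  if (any(unknown)) {
    warning(sum(unknown), " SNP(s) on chromosome(s) absent from the gene model; ",
            "classed intergenic")
  }
  prio <- stats::setNames(seq_along(FUNCTIONAL_CLASSES), FUNCTIONAL_CLASSES)
  win <- max(upstream, downstream)
  for (ch in intersect(unique(out$chrom), unique(genes$chrom))) {
    g <- genes[genes$chrom == ch, ]
    idx <- which(out$chrom == ch)
    pos <- out$pos[idx]
    for (k in seq_len(nrow(g))) {
      gene <- g[k, ]
      near <- which(pos >= gene$start - win & pos <= gene$end + win)
      if (length(near) == 0) next
      feats <- feats_by_gene[[gene$gene_id]] %||%
        model[0, ]
      for (m in near) {
        c_new <- classify_against_gene(pos[m], gene, feats, upstream,
                                       downstream, splice_window)
        if (!is.na(c_new) && prio[c_new] < prio[cls[idx[m]]]) {
          cls[idx[m]] <- c_new
        }
      }
    }
  }
  out$functional_class <- factor(cls, levels = FUNCTIONAL_CLASSES)
  out
}

#' Functional-class composition of a SNP set
#'
#' Proportion of SNPs in each functional class. Counting is integer so the
#' proportions sum to 1 exactly; classes absent from the input are reported
#' as 0.
#'
#' @param classified Output of [classify_variants()] (or any data frame with
#'   a `functional_class` column).
#' @return A tibble with columns `functional_class`, `n`, `proportion`, one
#'   row per class in priority order.
#' @export
class_composition <- function(classified) {
  stopifnot(is.data.frame(classified),
            "functional_class" %in% names(classified))
  if (nrow(classified) == 0) stop("no SNPs to summarise")
  f <- factor(as.character(classified$functional_class),
              levels = FUNCTIONAL_CLASSES)
  if (anyNA(f)) stop("unknown functional class label(s)")
  n <- as.integer(table(f))
  tibble::tibble(functional_class = factor(FUNCTIONAL_CLASSES,
                                           levels = FUNCTIONAL_CLASSES),
                 n = n, proportion = n / sum(n))
}

#' Bar chart of functional-class composition
#'
#' @param composition Output of [class_composition()].
#' @return A ggplot object.
#' @export
plot_class_composition <- function(composition) {
  ggplot2::ggplot(composition,
                  ggplot2::aes(x = .data$functional_class,
                               y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "proportion of SNPs") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
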