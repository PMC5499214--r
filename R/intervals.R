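#' Genomic interval sets
#'
#' An interval set is a tibble with columns `chrom`, `start`, `end` holding
#' non-overlapping intervals in the BED convention (0-based start, exclusive
#' end), sorted by `(chrom, start)`, with the set label stored in the
#' `set_name` attribute. Enhancer sets, promoter sets and any other genomic
#' annotation handled by this package are represented this way. Strand is
#' ignored throughout: enhancer activity is strandless.
#'
#' @param x A data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open). Extra columns are dropped.
#' @param name Set label (e.g. `"H3K27ac"`).
#' @param strip_chr If `TRUE`, a leading `"chr"` prefix is stripped from
#'   chromosome labels so sets from mixed assemblies compare as equal.
#' @return A tibble of class `interval_set`, sorted, with attribute
#'   `set_name`.
#' @details The constructor validates the set invariants (every interval has
#'   `0 <= start < end`; no two intervals on the same chromosome overlap) and
#'   errors otherwise. To build a set from raw, possibly overlapping
#'   intervals use [merge_intervals()].
#' @examples
#' interval_set(data.frame(chrom = "1", start = c(0, 200), end = c(100, 300)),
#'              name = "demo")
#' @export
interval_set <- function(x, name = "set", strip_chr = FALSE) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing_cols) > 0) {
    stop("interval table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- tibble::tibble(
    chrom = as.character(x$chrom),
    start = as.numeric(x$start),
    end   = as.numeric(x$end)
  )
  if (strip_chr) df$chrom <- sub("^chr", "", df$chrom)
  check_intervals(df)
  df <- dplyr::arrange(df, .data$chrom, .data$start, .data$end)
  bad <- df |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(ovl = .data$start < dplyr::lag(cummax(.data$end), default = -Inf)) |>
    dplyr::ungroup()
  if (any(bad$ovl)) {
    i <- which(bad$ovl)[1]
    stop(sprintf("intervals overlap within set '%s' (e.g. %s:%g-%g); use merge_intervals()",
                 name, df$chrom[i], df$start[i], df$end[i]))
  }
  new_interval_set(df, name)
}

new_interval_set <- function(df, name) {
  structure(df,
            class = c("interval_set", class(tibble::tibble())),
            set_name = name)
}

check_intervals <- function(df) {
  bad <- which(!(df$start >= 0 & df$start < df$end) | !is.finite(df$start) | !is.finite(df$end))
  if (length(bad) > 0) {
    i <- bad[1]
    stop(sprintf("malformed interval at row %d: %s:%s-%s (need 0 <= start < end)",
                 i, df$chrom[i], format(df$start[i]), format(df$end[i])))
  }
  invisible(df)
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("# Interval set '%s': %d intervals, %s bp on %d chromosome(s)\n",
              set_name(x), nrow(x), format(total_bp(x), big.mark = ","),
              length(unique(x$chrom))))
  NextMethod()
}

#' Set label and total covered bases of an interval set
#'
#' @param set An `interval_set` (or any chrom/start/end table for
#'   `total_bp()`).
#' @return `set_name()`: the label; `total_bp()`: the summed interval
#'   lengths in bp.
#' @export
set_name <- function(set) attr(set, "set_name") %||% "set"

#' @rdname set_name
#' @export
total_bp <- function(set) if (nrow(set) == 0) 0 else sum(set$end - set$start)

# Shared left-to-right sweep: intervals sorted by (chrom, start) are grouped
# whenever start - max(end of earlier intervals) < gap_threshold, then each
# group is collapsed to its span. gap_threshold = -min_overlap gives plain
# merging (join only on > min_overlap shared bp); gap_threshold = max_gap
# gives gap clustering (join when the gap is strictly below max_gap).
sweep_collapse <- function(df, gap_threshold, name) {
  df <- dplyr::arrange(df, .data$chrom, .data$start, .data$end)
  out <- df |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      gap = .data$start - dplyr::lag(cummax(.data$end)),
      new_grp = is.na(.data$gap) | .data$gap >= gap_threshold,
      grp = cumsum(.data$new_grp)
    ) |>
    dplyr::group_by(.data$chrom, .data$grp) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    dplyr::select("chrom", "start", "end") |>
    dplyr::arrange(.data$chrom, .data$start)
  new_interval_set(out, name)
}

#' Merge overlapping genomic intervals into a non-overlapping set
#'
#' Collapses every chain of pairwise-overlapping intervals into a single
#' longer interval, the operation used to combine intervals from several
#' sources (e.g. the outputs of two aligners) into a library of
#' non-overlapping candidate enhancer regions. Two intervals are joined when
#' they share strictly more than `min_overlap` bp; with the default
#' `min_overlap = 0` this is standard BED merge semantics, in which
#' book-ended intervals (0 shared bp) stay separate.
#'
#' @param x Data frame of raw intervals (`chrom`, `start`, `end`, 0-based
#'   half-open); overlaps and duplicates allowed.
#' @param name Label for the resulting set.
#' @param min_overlap Minimum shared bp (exclusive) required to join two
#'   intervals. `min_overlap = 1` joins only intervals sharing at least 2 bp.
#' @param strip_chr Strip a leading `"chr"` from chromosome labels first.
#' @return An [interval_set()].
#' @examples
#' merge_intervals(data.frame(chrom = "c1", start = c(100, 150), end = c(200, 300)))
#' @seealso [cluster_merge()] for joining across gaps.
#' @export
merge_intervals <- function(x, name = "set", min_overlap = 0, strip_chr = FALSE) {
  stopifnot(is.data.frame(x), min_overlap >= 0)
  df <- tibble::tibble(chrom = as.character(x$chrom),
                       start = as.numeric(x$start),
                       end = as.numeric(x$end))
  if (strip_chr) df$chrom <- sub("^chr", "", df$chrom)
  check_intervals(df)
  sweep_collapse(df, gap_threshold = -min_overlap, name = name)
}

#' Merge intervals separated by less than a maximum gap
#'
#' Joins intervals on the same chromosome whose gap (`next start - previous
#' end`) is strictly less than `max_gap`, transitively left to right. This is
#' the expansion applied to super-enhancer catalogues, where enhancer
#' sequences within less than 30 kb of each other are merged into a single
#' longer enhancer sequence.
#'
#' @param set An [interval_set()].
#' @param max_gap Maximum gap in bp (exclusive); must be `>= 0`. With
#'   `max_gap = 0` this equals [merge_intervals()].
#' @param name Label for the result; defaults to the input label.
#' @return An [interval_set()].
#' @examples
#' s <- interval_set(data.frame(chrom = "c1", start = c(0, 10100),
#'                              end = c(100, 10200)), "dbSUPER")
#' cluster_merge(s, max_gap = 30000)
#' @export
cluster_merge <- function(set, max_gap, name = set_name(set)) {
  if (!is.numeric(max_gap) || length(max_gap) != 1 || max_gap < 0) {
    stop("max_gap must be a single non-negative number")
  }
  check_intervals(set)
  sweep_collapse(tibble::as_tibble(set)[c("chrom", "start", "end")],
                 gap_threshold = max_gap, name = name)
}

# two-pointer intersection of sorted non-overlapping intervals on one chromosome
intersect_chrom <- function(s1, e1, s2, e2) {
  i <- 1L; j <- 1L
  n1 <- length(s1); n2 <- length(s2)
  os <- numeric(0); oe <- numeric(0)
  while (i <= n1 && j <= n2) {
    s <- max(s1[i], s2[j]); e <- min(e1[i], e2[j])
    if (s < e) { os <- c(os, s); oe <- c(oe, e) }
    if (e1[i] < e2[j]) i <- i + 1L else j <- j + 1L
  }
  list(start = os, end = oe)
}

per_chrom_op <- function(a, b, fun, name) {
  chroms <- sort(unique(c(a$chrom, b$chrom)))
  pieces <- lapply(chroms, function(ch) {
    ai <- a[a$chrom == ch, ]; bi <- b[b$chrom == ch, ]
    r <- fun(ai$start, ai$end, bi$start, bi$end)
    if (length(r$start) == 0) return(NULL)
    tibble::tibble(chrom = ch, start = r$start, end = r$end)
  })
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0) out <- tibble::tibble(chrom = character(), start = numeric(), end = numeric())
  new_interval_set(dplyr::arrange(out, .data$chrom, .data$start), name)
}

#' Intersect and subtract interval sets
#'
#' `intersect_sets()` returns the bases covered by both sets;
#' `subtract_sets()` the bases covered by `a` but not `b`. These build the
#' derived annotation subsets compared in enrichment analyses, e.g. the
#' regions marked by both of two histone modifications versus the regions
#' specific to one of them. For any `a` and `b`,
#' `total_bp(intersect_sets(a, b)) + total_bp(subtract_sets(a, b)) ==
#' total_bp(a)` exactly.
#'
#' @param a,b [interval_set()] objects.
#' @param name Label for the result.
#' @return An [interval_set()] (possibly empty).
#' @examples
#' A <- interval_set(data.frame(chrom = "c1", start = 0, end = 100), "A")
#' B <- interval_set(data.frame(chrom = "c1", start = 40, end = 60), "B")
#' intersect_sets(A, B)
#' subtract_sets(A, B)
#' @export
intersect_sets <- function(a, b, name = paste0(set_name(a), "&", set_name(b))) {
  check_intervals(a); check_intervals(b)
  per_chrom_op(a, b, intersect_chrom, name)
}

#' @rdname intersect_sets
#' @export
subtract_sets <- function(a, b, name = paste0(set_name(a), "-", set_name(b))) {
  check_intervals(a); check_intervals(b)
  subtract_chrom <- function(s1, e1, s2, e2) {
    if (length(s1) == 0) return(list(start = numeric(0), end = numeric(0)))
    # complement of b over a window covering a, then intersect with a
    lo <- min(s1); hi <- max(e1)
    bnd <- c(lo, rbind(s2, e2), hi)
    cs <- bnd[seq(1, length(bnd) - 1, by = 2)]
    ce <- bnd[seq(2, length(bnd), by = 2)]
    keep <- cs < ce
    intersect_chrom(s1, e1, cs[keep], ce[keep])
  }
  per_chrom_op(a, b, subtract_chrom, name)
}

#' Pairwise overlap-percentage matrix between interval sets
#'
#' Entry `(r, c)` is the total number of bp shared by sets `r` and `c`,
#' expressed as a percentage of the total bp of the *row* set. The matrix is
#' generally asymmetric: a small set contained in a large one overlaps it
#' 100% while the converse entry is small. Diagonal entries are exactly 100.
#'
#' @param sets A named list of [interval_set()] objects, each with
#'   `total_bp > 0`.
#' @return An object of class `overlap_matrix`: a square numeric matrix of
#'   percentages with set labels as dimnames.
#' @examples
#' A <- interval_set(data.frame(chrom = "c1", start = 0, end = 1000), "A")
#' B <- interval_set(data.frame(chrom = "c1", start = 0, end = 100), "B")
#' overlap_matrix(list(A, B))
#' @export
overlap_matrix <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1)
  labels <- vapply(seq_along(sets), function(i) {
    nm <- names(sets)[i]
    if (!is.null(nm) && nzchar(nm)) nm else set_name(sets[[i]])
  }, character(1))
  tot <- vapply(sets, total_bp, numeric(1))
  if (any(tot == 0)) {
    stop("set(s) with zero covered bp: ", paste(labels[tot == 0], collapse = ", "))
  }
  k <- length(sets)
  m <- matrix(100, k, k, dimnames = list(labels, labels))
  if (k > 1) {
    for (r in seq_len(k - 1)) {
      for (c in seq(r + 1, k)) {
        shared <- total_bp(intersect_sets(sets[[r]], sets[[c]]))
        m[r, c] <- 100 * shared / tot[r]
        m[c, r] <- 100 * shared / tot[c]
      }
    }
  }
  structure(m, class = c("overlap_matrix", "matrix", "array"))
}

#' @export
print.overlap_matrix <- function(x, digits = 1, ...) {
  cat("# Row-relative overlap percentages\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Flag SNPs falling inside an interval set
#'
#' Adds a logical membership column for an interval set to a SNP table.
#' Intervals use the BED convention (0-based half-open) while SNP positions
#' are 1-based (VCF convention), so a SNP at 1-based position `p` lies in an
#' interval iff `start < p <= end`; the conversion between the two
#' conventions is confined to this function.
#'
#' @param snps Data frame with columns `chrom` and `pos` (1-based).
#' @param set An [interval_set()].
#' @param col Name of the logical column to add (default `in_set`).
#' @param strip_chr Strip a leading `"chr"` from SNP chromosome labels before
#'   matching.
#' @return `snps` as a tibble with the membership column added; the member
#'   count is `sum(out[[col]])`.
#' @examples
#' set <- interval_set(data.frame(chrom = "c1", start = 100, end = 200), "E")
#' snps_in_set(data.frame(chrom = "c1", pos = c(100, 101, 150, 200, 201)), set)
#' @export
snps_in_set <- function(snps, set, col = "in_set", strip_chr = FALSE) {
  stopifnot(is.data.frame(snps), all(c("chrom", "pos") %in% names(snps)))
  if (any(snps$pos < 1)) {
    stop("SNP positions must be >= 1 (1-based); offending row ",
         which(snps$pos < 1)[1])
  }
  check_intervals(set)
  out <- tibble::as_tibble(snps)
  ch <- as.character(out$chrom)
  if (strip_chr) ch <- sub("^chr", "", ch)
  member <- logical(nrow(out))
  for (c_i in unique(ch)) {
    iv <- set[set$chrom == c_i, ]
    if (nrow(iv) == 0) next
    idx <- ch == c_i
    p <- out$pos[idx]
    # last interval with start <= p - 1, i.e. start < p; member if p <= its end
    hit <- findInterval(p - 1, iv$start)
    member[idx] <- hit >= 1 & p <= iv$end[pmax(hit, 1)]
  }
  out[[col]] <- member
  out
}
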