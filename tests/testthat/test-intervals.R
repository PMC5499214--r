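iv <- function(chrom, start, end) tibble::tibble(chrom = chrom, start = start, end = end)

test_that("merge_intervals joins overlapping but not book-ended intervals", {
  m <- merge_intervals(iv("c1", c(100, 150), c(200, 300)))
  expect_equal(m$start, 100)
  expect_equal(m$end, 300)

  # same coordinates on different chromosomes never merge
  m2 <- merge_intervals(iv(c("c1", "c2"), c(100, 100), c(200, 200)))
  expect_equal(nrow(m2), 2)

  # book-ended: 0 shared bp, kept separate
  m3 <- merge_intervals(iv("c1", c(100, 200), c(200, 300)))
  expect_equal(nrow(m3), 2)

  # literal >1 bp reading via min_overlap: 1 shared bp no longer joins
  m4 <- merge_intervals(iv("c1", c(100, 199), c(200, 300)), min_overlap = 1)
  expect_equal(nrow(m4), 2)
  m5 <- merge_intervals(iv("c1", c(100, 198), c(200, 300)), min_overlap = 1)
  expect_equal(nrow(m5), 1)
})

test_that("malformed intervals are rejected with the offending record named", {
  expect_error(merge_intervals(iv("c1", 200, 100)), "malformed interval")
  expect_error(merge_intervals(iv("c1", 100, 100)), "c1:100-100")
  expect_error(interval_set(iv("c1", -5, 10)), "malformed")
})

test_that("interval_set rejects overlapping rows and sorts valid ones", {
  expect_error(interval_set(iv("c1", c(0, 50), c(100, 150))), "overlap")
  s <- interval_set(iv("c1", c(200, 0), c(300, 100)))
  expect_equal(s$start, c(0, 200))
  expect_equal(total_bp(s), 200)
})

test_that("cluster_merge closes gaps strictly below max_gap", {
  s <- interval_set(iv("c1", c(0, 10100), c(100, 10200)))
  expect_equal(nrow(cluster_merge(s, 30000)), 1)
  expect_equal(cluster_merge(s, 30000)$end, 10200)

  far <- interval_set(iv("c1", c(0, 35100), c(100, 35200)))
  expect_equal(nrow(cluster_merge(far, 30000)), 2)

  # boundary: gap exactly equal to max_gap stays open
  exact <- interval_set(iv("c1", c(0, 30100), c(100, 30200)))
  expect_equal(nrow(cluster_merge(exact, 30000)), 2)

  # chained 20-kb gaps collapse transitively into one span
  three <- interval_set(iv("c1", c(0, 20100, 40200), c(100, 20200, 40300)))
  cm <- cluster_merge(three, 30000)
  expect_equal(nrow(cm), 1)
  expect_equal(c(cm$start, cm$end), c(0, 40300))

  expect_error(cluster_merge(s, -1), "non-negative")
})

test_that("intersect and subtract cover exactly the right bases", {
  A <- interval_set(iv("c1", 0, 100), "A")
  B <- interval_set(iv("c1", 50, 150), "B")
  expect_equal(as.data.frame(intersect_sets(A, B))$start, 50)
  expect_equal(as.data.frame(intersect_sets(A, B))$end, 100)
  expect_equal(as.data.frame(subtract_sets(A, B))$end, 50)

  # disjoint -> empty; nested -> inner set
  D <- interval_set(iv("c2", 0, 10), "D")
  expect_equal(nrow(intersect_sets(A, D)), 0)
  Inner <- interval_set(iv("c1", 20, 30), "I")
  expect_equal(as.data.frame(intersect_sets(A, Inner)),
               as.data.frame(Inner), ignore_attr = TRUE)

  # subtraction splitting an interval in two
  Mid <- interval_set(iv("c1", 40, 60), "M")
  sp <- subtract_sets(A, Mid)
  expect_equal(sp$start, c(0, 60))
  expect_equal(sp$end, c(40, 100))

  expect_equal(nrow(subtract_sets(A, A)), 0)
})

test_that("overlap matrix is row-relative with a 100 diagonal", {
  A <- interval_set(iv("c1", 0, 1000), "A")
  B <- interval_set(iv("c1", 0, 100), "B")
  m <- overlap_matrix(list(A, B))
  expect_equal(unclass(m), matrix(c(100, 100, 10, 100), 2, 2,
                                  dimnames = list(c("A", "B"), c("A", "B"))))
  # identical sets overlap fully both ways
  m2 <- overlap_matrix(list(X = A, Y = A))
  expect_true(all(m2 == 100))
  empty <- structure(tibble::tibble(chrom = character(), start = numeric(),
                                    end = numeric()),
                     class = class(A), set_name = "Z")
  expect_error(overlap_matrix(list(A, empty)), "zero covered bp")
})

test_that("SNP membership follows BED/VCF coordinate conventions", {
  set <- interval_set(iv("c1", 100, 200), "E")
  res <- snps_in_set(tibble::tibble(chrom = "c1",
                                    pos = c(100, 101, 150, 200, 201)), set)
  expect_equal(res$in_set, c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_error(snps_in_set(tibble::tibble(chrom = "c1", pos = 0), set),
               ">= 1")
  # chr-prefix stripping
  res2 <- snps_in_set(tibble::tibble(chrom = "chrc1", pos = 150), set,
                      strip_chr = TRUE)
  expect_false("chrc1" %in% set$chrom)
  expect_true(res2$in_set)
})

test_that("interval algebra agrees with the per-bp mask oracle", {
  withr::with_seed(421, {
    for (rep in 1:60) {
      raw_a <- random_intervals(sample.int(30, 1))
      raw_b <- random_intervals(sample.int(30, 1))
      a <- merge_intervals(raw_a, "A")
      b <- merge_intervals(raw_b, "B")

      expect_true(mask_equal(a, raw_a, 1e5 + 5000))
      expect_true(mask_equal(intersect_sets(a, b),
                             mask_op(a, b, 1e5 + 5000, `&`), 1e5 + 5000))
      expect_true(mask_equal(subtract_sets(a, b),
                             mask_op(a, b, 1e5 + 5000,
                                     function(x, y) x & !y), 1e5 + 5000))

      gap <- sample.int(20000, 1)
      cm <- cluster_merge(a, gap)
      orc <- oracle_cluster(tibble::as_tibble(a), gap)
      expect_equal(as.data.frame(cm)[c("chrom", "start", "end")],
                   as.data.frame(orc)[c("chrom", "start", "end")],
                   ignore_attr = TRUE)

      # conservation: intersect + subtract partition a exactly
      expect_identical(total_bp(intersect_sets(a, b)) +
                         total_bp(subtract_sets(a, b)), total_bp(a))
    }
  })
})

test_that("merge is idempotent, order-invariant, and equals gap-0 clustering", {
  withr::with_seed(77, {
    for (rep in 1:20) {
      raw <- random_intervals(25)
      m <- merge_intervals(raw, "S")
      expect_equal(as.data.frame(merge_intervals(m)), as.data.frame(m),
                   ignore_attr = TRUE)
      shuf <- raw[sample.int(nrow(raw)), ]
      expect_equal(as.data.frame(merge_intervals(shuf)), as.data.frame(m),
                   ignore_attr = TRUE)
      expect_equal(as.data.frame(cluster_merge(m, 0)), as.data.frame(m),
                   ignore_attr = TRUE)

      # overlap percentages do not depend on interval order within a set
      b <- merge_intervals(random_intervals(25), "B")
      expect_equal(overlap_matrix(list(m, b)),
                   overlap_matrix(list(merge_intervals(shuf, "S"), b)))
    }
  })
})

test_that("interval algebra matches IRanges on random instances", {
  skip_if_not_installed("GenomicRanges")
  to_gr <- function(df) {
    GenomicRanges::GRanges(df$chrom,
                           IRanges::IRanges(start = df$start + 1, end = df$end))
  }
  from_gr <- function(gr) {
    tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr))
  }
  withr::with_seed(99, {
    for (rep in 1:20) {
      a <- merge_intervals(random_intervals(20), "A")
      b <- merge_intervals(random_intervals(20), "B")
      got <- as.data.frame(intersect_sets(a, b))
      ref <- as.data.frame(from_gr(GenomicRanges::intersect(to_gr(a), to_gr(b))))
      got <- got[order(got$chrom, got$start), ]
      ref <- ref[order(ref$chrom, ref$start), ]
      expect_equal(got, ref, ignore_attr = TRUE)
    }
  })
})
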