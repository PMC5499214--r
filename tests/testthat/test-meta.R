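two_cohort_stats <- function(beta, p, ids = "rs1") {
  tibble::tibble(snp_id = ids, chrom = "1", pos = 100,
                 cohort = c("bulls", "cows"), beta = beta, p = p)
}

test_that("standard error inversion matches an independent normal oracle", {
  # two-sided: p = 0.04550026 corresponds to z = 2 => se = |0.4| / 2
  z <- oracle_qnorm(1 - 0.04550026 / 2)
  expect_equal(z, 2, tolerance = 1e-6)
  expect_equal(snp_standard_error(0.4, 0.04550026), 0.2, tolerance = 1e-7)

  # as-written: se = |1 / qnorm(0.05)|
  expect_equal(snp_standard_error(1.0, 0.05, mode = "as-written"),
               abs(1 / oracle_qnorm(0.05)), tolerance = 1e-9)
  expect_equal(snp_standard_error(1.0, 0.05, mode = "as-written"),
               0.6079568, tolerance = 1e-6)

  # filterable records yield NA rather than a number
  expect_true(is.na(snp_standard_error(0.4, 1)))
  expect_true(is.na(snp_standard_error(0, 0.01)))
  expect_true(is.na(snp_standard_error(1, 0.5, mode = "as-written")))
  expect_error(snp_standard_error(1, 0), "\\(0, 1\\]")

  # tiny P values survive without cancellation
  expect_true(is.finite(snp_standard_error(0.4, 1e-300)))
})

test_that("the two-cohort worked example reproduces all intermediates", {
  cc <- combine_cohorts(beta = c(0.4, 0.2), se = c(0.2, 0.2))
  expect_equal(cc$w, c(5, 5))
  expect_equal(cc$beta_hat, c(2, 1))
  expect_equal(cc$tilde_beta, 0.3)
  expect_equal(cc$tilde_v, sqrt(2 / 10))
  p <- meta_p_value(cc$tilde_beta, cc$tilde_v)
  expect_equal(p, 2 * (1 - oracle_phi(0.3 / sqrt(0.2))), tolerance = 1e-10)
  expect_equal(p, 0.5023, tolerance = 1e-4)

  # same example through the tidy front end (cows p gives se = 0.2 exactly)
  p_cows <- 2 * (1 - pnorm(1))
  m <- meta_analyze(two_cohort_stats(c(0.4, 0.2), c(0.04550026, p_cows)))
  expect_equal(m$tilde_beta, 0.3, tolerance = 1e-7)
  expect_equal(m$tilde_v, sqrt(0.2), tolerance = 1e-7)
  expect_equal(m$tilde_p, 0.5023, tolerance = 1e-4)
})

test_that("meta P value matches the oracle and handles edge cases", {
  expect_equal(meta_p_value(0, 1), 1)
  z2 <- meta_p_value(2, 1)
  expect_equal(z2, 0.04550026, tolerance = 1e-7)
  expect_equal(z2, 2 * (1 - oracle_phi(2)), tolerance = 1e-10)
  expect_error(meta_p_value(1, 0), "tilde_v")
  expect_error(meta_p_value(1, -1), "tilde_v")
  # monotone decreasing in |z|
  zs <- seq(0, 8, by = 0.25)
  expect_true(all(diff(meta_p_value(zs, 1)) < 0))
})

test_that("identical cohorts return the shared effect; order never matters", {
  m1 <- meta_analyze(two_cohort_stats(c(0.5, 0.5), c(0.02, 0.02)))
  expect_equal(m1$tilde_beta, 0.5)

  stats <- tibble::tibble(
    snp_id = rep(c("a", "b"), each = 2), chrom = "1", pos = rep(c(10, 20), each = 2),
    cohort = rep(c("bulls", "cows"), 2),
    beta = c(0.4, 0.2, -0.1, 0.3), p = c(0.01, 0.2, 0.5, 0.04)
  )
  m_fwd <- meta_analyze(stats)
  m_rev <- meta_analyze(stats[nrow(stats):1, ])
  expect_equal(m_fwd, m_rev, ignore_attr = TRUE)
})

test_that("rescaling all effects leaves the meta P unchanged", {
  withr::with_seed(5, {
    n <- 200
    stats <- tibble::tibble(
      snp_id = rep(sprintf("s%03d", 1:n), each = 2),
      chrom = "1", pos = rep(1:n, each = 2),
      cohort = rep(c("bulls", "cows"), n),
      beta = rnorm(2 * n), p = runif(2 * n)
    )
    # the combined effect scales with the data under either weighting
    m1 <- meta_analyze(stats)
    m2 <- meta_analyze(dplyr::mutate(stats, beta = beta * 3.7))
    expect_equal(m2$tilde_beta, 3.7 * m1$tilde_beta, tolerance = 1e-12)
    expect_true(all(m1$tilde_p > 0 & m1$tilde_p <= 1))
    # scale-invariance of the meta P holds under 1/se^2 weights, where the
    # test statistic beta/v is dimensionless; under 1/se weights the
    # statistic scales with sqrt(c) by construction
    w1 <- meta_analyze(stats, weight_exponent = 2)
    w2 <- meta_analyze(dplyr::mutate(stats, beta = beta * 3.7),
                       weight_exponent = 2)
    expect_equal(w2$tilde_p, w1$tilde_p, tolerance = 1e-12)
    expect_equal(m2$tilde_beta / m2$tilde_v,
                 sqrt(3.7) * (m1$tilde_beta / m1$tilde_v), tolerance = 1e-12)
  })
})

test_that("single-cohort meta inverts back to the input P with 1/se^2 weights", {
  withr::with_seed(11, {
    n <- 500
    stats <- tibble::tibble(
      snp_id = sprintf("s%04d", 1:n), chrom = "1", pos = 1:n,
      cohort = "bulls",
      beta = rnorm(n, 0, 2), p = runif(n)
    )
    stats <- stats[stats$beta != 0, ]
    m <- meta_analyze(stats, weight_exponent = 2)
    inp <- stats[match(m$snp_id, stats$snp_id), ]
    expect_equal(m$tilde_p, inp$p, tolerance = 1e-10)
    # and tilde_v equals the recovered per-SNP standard error
    expect_equal(m$tilde_v, snp_standard_error(inp$beta, inp$p),
                 tolerance = 1e-12)
  })
})

test_that("filtering removes uninformative variants and logs the counts", {
  stats <- tibble::tibble(
    snp_id = rep(c("ok", "zero", "pone", "opp"), each = 2),
    chrom = "1", pos = rep(1:4, each = 2),
    cohort = rep(c("bulls", "cows"), 4),
    beta = c(0.4, 0.2, 0, 0.1, 0.3, 0.2, 0.4, -0.4),
    p = c(0.001, 0.01, 0.05, 0.05, 0.02, 1, 0.05, 0.05)
  )
  m <- meta_analyze(stats)
  # "zero" has a no-effect cohort, "pone" a P=1 cohort, "opp" cancels to 0
  expect_equal(m$snp_id, "ok")
  log <- filter_log(m)
  expect_equal(log$n[log$step == "input SNPs"], 4)
  expect_equal(log$n[grepl("no effect or P = 1", log$step)], 2)
  expect_equal(log$n[grepl("combined effect 0", log$step)], 1)
  expect_equal(log$n[log$step == "SNPs tested"], 1)
})

test_that("significance is flagged at the genome-wide threshold", {
  # both cohorts z = 3 with se = 4: meta z = z * sqrt(se) = 6, P ~ 2e-9
  p_hi <- rep(2 * pnorm(-3), 2)
  p_lo <- c(0.3, 0.4)
  stats <- tibble::tibble(
    snp_id = rep(c("hit", "null"), each = 2), chrom = "1",
    pos = rep(1:2, each = 2), cohort = rep(c("bulls", "cows"), 2),
    beta = c(12, 12, 0.05, 0.04), p = c(p_hi, p_lo)
  )
  m <- meta_analyze(stats, threshold = 1e-8)
  expect_true(m$significant[m$snp_id == "hit"])
  expect_false(m$significant[m$snp_id == "null"])
})

test_that("SNPs in a single cohort are combined with n = 1 or dropped", {
  stats <- tibble::tibble(snp_id = c("a", "a", "b"), chrom = "1",
                          pos = c(1, 1, 2),
                          cohort = c("bulls", "cows", "bulls"),
                          beta = c(0.4, 0.2, 0.3), p = c(0.01, 0.2, 0.04))
  m <- meta_analyze(stats)
  expect_equal(m$n_cohorts[m$snp_id == "b"], 1)
  m_strict <- meta_analyze(stats, single_cohort = "drop")
  expect_false("b" %in% m_strict$snp_id)

  # one id, two positions: schema error
  bad <- dplyr::mutate(stats, pos = c(1, 5, 2))
  expect_error(meta_analyze(bad), "multiple")
})
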