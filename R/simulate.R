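#' Configuration for the synthetic GWAS generator
#'
#' Describes a synthetic genome, enhancer sets with planted enrichment, and
#' two phenotype cohorts. Defaults emulate the statistical structure of a
#' two-cohort dairy-cattle GWAS at desk scale: a polygenic trait with a
#' small fraction of causal variants, one candidate enhancer set in which
#' causal variants are enriched threefold, a matched unenriched decoy set,
#' and cohorts of unequal measurement precision (progeny-derived bull
#' phenotypes are less noisy than individual cow records).
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @param n_snps Total SNP count (uniform over the genome, no duplicates).
#' @param sets A list of set specifications, each a list with `name`,
#'   `f` (target fraction of the genome covered, in (0, 1)), `n_intervals`
#'   and `lambda` (relative risk of a SNP being causal inside the set).
#' @param pi_causal Overall fraction of SNPs that are causal.
#' @param tau Standard deviation of causal effects on the cohort z-scale.
#' @param cohorts Named numeric vector of per-cohort noise scales; the
#'   simulated standard error of every SNP effect in a cohort equals its
#'   noise scale.
#' @param n_genes_per_chrom Genes simulated per chromosome for the
#'   functional-annotation stand-in.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 5,
                       chrom_length = 2e6,
                       n_snps = 100000,
                       sets = list(
                         list(name = "enhancer_chip", f = 0.05,
                              n_intervals = 1000, lambda = 3),
                         list(name = "enhancer_decoy", f = 0.05,
                              n_intervals = 1000, lambda = 1)
                       ),
                       pi_causal = 0.01,
                       tau = 4.8,
                       cohorts = c(bulls = 1.0, cows = 1.25),
                       n_genes_per_chrom = 40) {
  cfg <- list(n_chrom = n_chrom, chrom_length = chrom_length, n_snps = n_snps,
              sets = sets, pi_causal = pi_causal, tau = tau, cohorts = cohorts,
              n_genes_per_chrom = n_genes_per_chrom)
  stopifnot(n_chrom >= 1, chrom_length >= 1000, n_snps >= 10,
            pi_causal > 0, pi_causal < 1, tau > 0,
            length(cohorts) >= 1, all(cohorts > 0))
  for (s in sets) {
    stopifnot(is.character(s$name), s$f > 0, s$f < 1, s$n_intervals >= 1,
              s$lambda >= 0)
    mean_len <- s$f * n_chrom * chrom_length / s$n_intervals
    if (mean_len < 1 || mean_len > chrom_length / 2) {
      stop(sprintf("infeasible set spec '%s': implied mean interval length %.1f bp",
                   s$name, mean_len))
    }
  }
  structure(cfg, class = "sim_config")
}

simulate_one_set <- function(spec, n_chrom, chrom_length) {
  genome_bp <- n_chrom * chrom_length
  mean_len <- spec$f * genome_bp / spec$n_intervals
  len <- pmax(1, round(runif(spec$n_intervals, 0.5, 1.5) * mean_len))
  chrom <- paste0("chr", sample.int(n_chrom, spec$n_intervals, replace = TRUE))
  start <- floor(runif(spec$n_intervals, 0, chrom_length - len))
  merge_intervals(tibble::tibble(chrom = chrom, start = start,
                                 end = start + len),
                  name = spec$name)
}

simulate_genes <- function(n_chrom, chrom_length, n_per_chrom) {
  rows <- list()
  for (c_i in seq_len(n_chrom)) {
    ch <- paste0("chr", c_i)
    # regular spacing keeps genes non-overlapping without rejection sampling
    slot <- chrom_length / n_per_chrom
    for (g in seq_len(n_per_chrom)) {
      g_len <- round(runif(1, 5000, min(30000, slot * 0.8)))
      g_start <- round((g - 1) * slot + runif(1, 1, slot - g_len))
      g_end <- g_start + g_len - 1
      strand <- sample(c("+", "-"), 1)
      coding <- runif(1) < 0.9
      gene_id <- sprintf("G%s_%03d", c_i, g)
      n_ex <- sample(3:8, 1)
      cuts <- sort(sample.int(g_len - 1, 2 * n_ex - 2))
      ex_start <- g_start + c(0, cuts[seq(2, length(cuts), by = 2)])
      ex_end <- g_start + c(cuts[seq(1, length(cuts), by = 2)] - 1, g_len - 1)
      feats <- tibble::tibble(gene_id = gene_id, chrom = ch, strand = strand,
                              feature = "exon", start = ex_start, end = ex_end,
                              coding = coding)
      gene_row <- tibble::tibble(gene_id = gene_id, chrom = ch, strand = strand,
                                 feature = "gene", start = g_start, end = g_end,
                                 coding = coding)
      extra <- NULL
      if (coding) {
        first <- if (strand == "+") 1 else nrow(feats)
        last <- if (strand == "+") nrow(feats) else 1
        utr5 <- feats[first, ]; utr5$feature <- "five_prime_UTR"
        utr5_len <- min(100, utr5$end - utr5$start)
        if (strand == "+") utr5$end <- utr5$start + utr5_len
        else utr5$start <- utr5$end - utr5_len
        utr3 <- feats[last, ]; utr3$feature <- "three_prime_UTR"
        utr3_len <- min(100, utr3$end - utr3$start)
        if (strand == "+") utr3$start <- utr3$end - utr3_len
        else utr3$end <- utr3$start + utr3_len
        stopc <- feats[last, ]; stopc$feature <- "stop_codon"
        if (strand == "+") {
          stopc$end <- utr3$start - 1; stopc$start <- max(stopc$end - 2, feats$start[last])
        } else {
          stopc$start <- utr3$end + 1; stopc$end <- min(stopc$start + 2, feats$end[last])
        }
        extra <- dplyr::bind_rows(utr5, utr3, stopc)
        extra <- extra[extra$start <= extra$end, ]
      }
      rows[[length(rows) + 1]] <- dplyr::bind_rows(gene_row, feats, extra)
    }
  }
  gene_model(dplyr::bind_rows(rows))
}

#' Simulate a genome, enhancer sets, gene model and causal-variant truth
#'
#' Places SNPs uniformly along each chromosome, builds each configured
#' interval set to cover roughly its target genome fraction, and plants
#' causal variants: a SNP's probability of being causal is proportional to
#' the product of the `lambda` values of the sets containing it, normalised
#' so the overall causal fraction equals `pi_causal`. For a single set
#' covering a fraction `f` of SNPs with enrichment `lambda`, the expected
#' fraction of causal SNPs inside the set is
#' `lambda * f / (lambda * f + (1 - f))`. Causal effects are drawn from
#' `N(0, tau^2)` on the z-scale. Everything is a pure function of
#' `(config, seed)`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list of class `sim_truth` with elements `snps` (tibble:
#'   `snp_id`, `chrom`, `pos`, one logical membership column `in_<set>` per
#'   set, `causal`, `beta_true`), `sets` (named list of [interval_set()]),
#'   `gene_model`, `config`, `seed`, and `expected` (per-set expected causal
#'   fraction inside the set).
#' @export
simulate_truth <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_if(seed, {
    snps <- dplyr::bind_rows(lapply(seq_len(config$n_chrom), function(c_i) {
      n_c <- round(config$n_snps / config$n_chrom)
      if (c_i == config$n_chrom) {
        n_c <- config$n_snps - n_c * (config$n_chrom - 1)
      }
      tibble::tibble(chrom = paste0("chr", c_i),
                     pos = sort(sample.int(config$chrom_length, n_c)))
    }))
    snps <- dplyr::mutate(snps,
                          snp_id = sprintf("snp_%07d", dplyr::row_number()),
                          .before = 1)

    sets <- list()
    for (spec in config$sets) {
      sets[[spec$name]] <- simulate_one_set(spec, config$n_chrom,
                                            config$chrom_length)
      snps <- snps_in_set(snps, sets[[spec$name]],
                          col = paste0("in_", spec$name))
    }

    rel_risk <- rep(1, nrow(snps))
    for (spec in config$sets) {
      member <- snps[[paste0("in_", spec$name)]]
      rel_risk[member] <- rel_risk[member] * spec$lambda
    }
    p_causal <- config$pi_causal * rel_risk / mean(rel_risk)
    if (any(p_causal > 1)) stop("infeasible config: causal probability > 1")
    snps$causal <- runif(nrow(snps)) < p_causal
    snps$beta_true <- ifelse(snps$causal, rnorm(nrow(snps), 0, config$tau), 0)

    gm <- simulate_genes(config$n_chrom, config$chrom_length,
                         config$n_genes_per_chrom)

    expected <- vapply(config$sets, function(spec) {
      m <- mean(snps[[paste0("in_", spec$name)]])
      spec$lambda * m / (spec$lambda * m + (1 - m))
    }, numeric(1))
    names(expected) <- vapply(config$sets, `[[`, character(1), "name")

    structure(list(snps = snps, sets = sets, gene_model = gm,
                   config = config, seed = seed, expected = expected),
              class = "sim_truth")
  })
}

#' Simulate GWAS summary statistics for one cohort
#'
#' Each SNP's observed z-statistic is its true effect on the z-scale plus
#' independent standard-normal noise; the reported effect is
#' `beta = z * noise_scale`, so the implied standard error of every SNP in
#' the cohort equals `noise_scale`, and `p` is the two-sided normal tail
#' probability of `|z|`. Cohorts simulated from the same truth share causal
#' variants but carry independent noise, mirroring two gender cohorts
#' phenotyped with different precision. P values are floored at `1e-320` to
#' stay within (0, 1].
#'
#' @param truth A [simulate_truth()] result.
#' @param cohort Cohort label; must appear in `truth$config$cohorts` unless
#'   `noise_scale` is given.
#' @param noise_scale Positive noise scale; defaults to the configured value
#'   for `cohort`.
#' @param seed Integer seed (independent of the truth seed).
#' @return A cohort statistics tibble (`snp_id`, `chrom`, `pos`, `cohort`,
#'   `beta`, `p`) for [meta_analyze()].
#' @export
simulate_cohort_stats <- function(truth, cohort, noise_scale = NULL,
                                  seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  noise_scale <- noise_scale %||% unname(truth$config$cohorts[cohort])
  if (is.null(noise_scale) || is.na(noise_scale) || noise_scale <= 0) {
    stop("noise_scale must be a positive number (unknown cohort '",
         cohort, "'?)")
  }
  with_seed_if(seed, {
    z <- truth$snps$beta_true / noise_scale + rnorm(nrow(truth$snps))
    tibble::tibble(
      snp_id = truth$snps$snp_id,
      chrom = truth$snps$chrom,
      pos = truth$snps$pos,
      cohort = cohort,
      beta = z * noise_scale,
      p = pmax(2 * pnorm(-abs(z)), 1e-320)
    )
  })
}

#' Simulate all configured cohorts at once
#'
#' @inheritParams simulate_cohort_stats
#' @param seeds Optional named integer seeds per cohort; defaults to seeds
#'   derived from the truth seed and the cohort label via [derive_seed()].
#' @return A long tibble of all cohorts, ready for [meta_analyze()].
#' @export
simulate_all_cohorts <- function(truth, seeds = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  cohorts <- names(truth$config$cohorts)
  dplyr::bind_rows(lapply(cohorts, function(co) {
    s <- if (!is.null(seeds)) seeds[[co]] else derive_seed(truth$seed, "cohort", co)
    simulate_cohort_stats(truth, co, seed = s)
  }))
}
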