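# Synthetic genotype and phenotype generation.

test_that("haplotype frequencies sum to 1 and honour limiting cases", {
  # perfect LD with equal MAFs collapses to a two-haplotype system
  h <- haplotype_freqs(0.15, 0.15, 1)
  expect_equal(unname(h), c(0.15, 0, 0, 0.85))
  # independence gives product frequencies
  h0 <- haplotype_freqs(0.1, 0.3, 0)
  expect_equal(unname(h0), c(0.03, 0.07, 0.27, 0.63))
  expect_equal(sum(haplotype_freqs(0.1, 0.16, 0.51)), 1)
})

test_that("infeasible LD requests error with the Frechet bound", {
  # r2 = 1 is unattainable for unequal MAFs
  expect_error(haplotype_freqs(0.1, 0.4, 1), "Frechet")
  expect_error(haplotype_freqs(0.1, 0.4, 1), "maximum attainable")
  expect_error(haplotype_freqs(0.6, 0.1, 0.5), "MAFs")
})

test_that("sampled haplotypes recover the design r-squared values", {
  n <- 5e5  # one million haplotypes per LD pair
  g <- sample_genotypes(n, seed = 123)
  # r2 = 1 pair: dosages identical in every individual
  expect_identical(g$rs16937976, g$rs13268757)
  # r2 = 0.51 pair: genotype dosage correlation squared estimates the
  # haplotype r2 under Hardy-Weinberg sampling
  r2_hat <- cor(g$rs920829, g$rs959976)^2
  expect_lt(abs(r2_hat - 0.51), 0.01)
})

test_that("empirical MAFs match specification within 3 MC SEs", {
  n <- 5e5
  g <- sample_genotypes(n, seed = 124)
  snps <- trpa1_snps()
  for (i in seq_len(nrow(snps))) {
    maf_hat <- mean(g[[snps$rsid[i]]]) / 2
    se <- sqrt(snps$maf[i] * (1 - snps$maf[i]) / (2 * n))
    expect_lt(abs(maf_hat - snps$maf[i]), 3 * se)
  }
  # Hardy-Weinberg minor-homozygote frequency at the common SNP
  expect_lt(abs(mean(g$rs7819749 == 2) - 0.16), 3 * sqrt(0.16 * 0.84 / n))
})

test_that("genotype sampling is reproducible under a fixed seed", {
  expect_identical(sample_genotypes(500, seed = 9),
                   sample_genotypes(500, seed = 9))
})

test_that("recall honours eligibility and genotype constraints", {
  g <- sample_genotypes(30000, seed = 22)
  coh <- recall_sample(g, c(control = 40, group1 = 25, group2 = 10,
                            group3 = 10), seed = 23)
  snps <- trpa1_snps()
  probs <- as.matrix(coh[paste0("prob_", snps$rsid)])
  expect_true(all(probs > 0.99))
  dos <- as.matrix(coh[snps$rsid])
  expect_true(all(dos[coh$recall_group == "control", ] == 0))
  expect_true(all(dos[coh$recall_group == "group1", "rs7819749"] == 2))
  expect_true(all(dos[coh$recall_group == "group2",
                      c("rs920829", "rs959976")] == 2))
  expect_true(all(dos[coh$recall_group == "group3",
                      c("rs16937976", "rs13268757")] == 2))
})

test_that("control-pool frequency matches the closed form without LD", {
  snps <- trpa1_snps()
  n <- 2e5
  g <- sample_genotypes(n, snps = snps, ld_pairs = NULL, seed = 31,
                        certainty = function(n) rep(1, n))
  p_control <- prod((1 - snps$maf)^2)
  obs <- mean(rowSums(as.matrix(g[snps$rsid])) == 0)
  expect_lt(abs(obs - p_control), 3 * sqrt(p_control * (1 - p_control) / n))
})

test_that("minor-homozygote pools are scarce at low MAF and shortfalls error", {
  g <- sample_genotypes(50000, seed = 32)
  # rs920829 (MAF 0.10): homozygote pool ~ 1% of the genotyped sample
  expect_lt(abs(mean(g$rs920829 == 2) - 0.01),
            3 * sqrt(0.01 * 0.99 / 50000))
  err <- tryCatch(recall_sample(g, c(group2 = 20000)), error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "insufficient pool")
  expect_match(conditionMessage(err), "expectation")
})

test_that("screening exclusions follow their prevalences", {
  rec <- data.frame(participant_id = seq_len(5e4))
  expect_identical(nrow(screen_exclusions(rec, c(a = 0, b = 0))), 5e4L)
  expect_identical(nrow(screen_exclusions(rec, c(a = 1), seed = 1)), 0L)
  p <- 0.05; k <- 4
  kept <- screen_exclusions(rec, setNames(rep(p, k), letters[1:k]), seed = 2)
  expect_lt(abs(nrow(kept) / 5e4 - (1 - p)^k),
            3 * sqrt((1 - p)^k * (1 - (1 - p)^k) / 5e4))
  expect_length(attr(kept, "excluded"), k)
})

test_that("QST phenotypes have the specified marginals and null calibration", {
  g <- sample_genotypes(20000, seed = 41)
  coh <- recall_sample(g, c(control = 400, group1 = 400), seed = 42)
  q <- generate_qst(coh, effect_map = c(group1 = 0), seed = 43)
  expect_equal(mean(q$hpt_baseline), 42, tolerance = 0.01)
  expect_equal(sd(q$hpt_baseline), 2.5, tolerance = 0.05)
  expect_equal(sd(q$hpt_post), 2.5, tolerance = 0.05)
  # between-visit correlation near the configured 0.7
  expect_equal(cor(q$hpt_baseline, q$hpt_post), 0.7, tolerance = 0.05)
  # null group effect: post means indistinguishable
  tt <- t.test(hpt_post ~ recall_group, q, var.equal = TRUE)
  expect_gt(tt$p.value, 0.001)
  expect_true(all(q$cinnamaldehyde_rating %in% 0:10))
})

test_that("an injected group effect is recovered by the mean difference", {
  reps <- 100L
  hits <- 0L
  for (i in seq_len(reps)) {
    coh <- synthesize_cohort(pool_n = 4000,
                             group_sizes = c(control = 30, group1 = 30),
                             effect_map = c(group1 = 4), seed = 500 + i)
    tt <- t.test(coh$hpt_post[coh$recall_group == "group1"],
                 coh$hpt_post[coh$recall_group == "control"])
    if (tt$conf.int[1] <= 4 && 4 <= tt$conf.int[2]) hits <- hits + 1L
  }
  # nominal 95% coverage; bound is 3 binomial SEs below nominal
  expect_gte(hits, ceiling(reps * (0.95 - 3 * sqrt(0.95 * 0.05 / reps))))
})

test_that("cohort CSV and VCF round-trip through standard tooling", {
  skip_if_not_installed("vcfR")
  coh <- synthesize_cohort(pool_n = 3000,
                           group_sizes = c(control = 10, group1 = 10),
                           seed = 61)
  csv <- tempfile(fileext = ".csv"); vcf <- tempfile(fileext = ".vcf")
  write_cohort_csv(coh, csv)
  back <- read.csv(csv)
  expect_identical(nrow(back), 20L)
  expect_true(all(c("participant_id", "recall_group", "hpt_baseline",
                    "hpt_post", "cinnamaldehyde_rating") %in% names(back)))
  write_cohort_vcf(coh, vcf)
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  expect_identical(nrow(v@gt), 5L)               # five SNP records
  expect_identical(ncol(v@gt), 21L)              # FORMAT + 20 samples
  gt <- vcfR::extract.gt(v, element = "GT")
  dos_vcf <- (gt == "0/1") + 2 * (gt == "1/1")
  for (rsid in trpa1_snps()$rsid)
    expect_equal(unname(dos_vcf[rsid, ]), coh[[rsid]])
  unlink(c(csv, vcf))
})
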