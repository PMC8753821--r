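# Synthetic recall-by-genotype cohort generator.
#
# Emulates recruitment from a genotyped birth cohort: Hardy-Weinberg
# genotypes at five biallelic TRPA1 SNPs (two pairs in linkage
# disequilibrium), imputation-certainty eligibility filtering, telephone
# screening exclusions, genotype-driven recall into control and
# minor-allele-homozygote test groups, and quantitative-sensory-testing
# phenotypes with a configurable group effect on the heat pain threshold.
# Everything downstream (interim decisions, simulations) can therefore be
# exercised end to end without access to real cohort data.

#' The five TRPA1 SNPs of the default design
#'
#' Minor allele frequencies as observed in the source cohort. Groups: the
#' group-1 variant stands alone; groups 2 and 3 are each defined by a pair
#' of SNPs in linkage disequilibrium (see [trpa1_ld()]), so a test-group
#' member is homozygous for the minor allele at both SNPs of its pair.
#'
#' @return Data frame with columns `rsid`, `maf`, `group`.
#' @export
trpa1_snps <- function() {
  data.frame(rsid = c("rs7819749", "rs920829", "rs959976",
                      "rs16937976", "rs13268757"),
             maf = c(0.40, 0.10, 0.16, 0.15, 0.15),
             group = c(1L, 2L, 2L, 3L, 3L))
}

#' Linkage-disequilibrium pairs of the default design
#'
#' Pairwise r-squared between the two SNPs defining test group 2 (0.51) and
#' test group 3 (1.0), with minor alleles positively associated.
#'
#' @return Data frame with columns `snp_a`, `snp_b`, `r2`, `sign`.
#' @export
trpa1_ld <- function() {
  data.frame(snp_a = c("rs920829", "rs16937976"),
             snp_b = c("rs959976", "rs13268757"),
             r2 = c(0.51, 1.0), sign = c(1, 1))
}

#' Two-locus haplotype frequencies from MAFs and r-squared
#'
#' Converts a pairwise LD specification into the four haplotype
#' frequencies. With minor-allele frequencies `p_a`, `p_b` the disequilibrium
#' coefficient is `D = sign * sqrt(r2 * p_a(1-p_a) * p_b(1-p_b))` and the
#' minor-minor haplotype has frequency `p_a * p_b + D`. The requested `r2`
#' must be feasible for the MAF pair (Frechet bounds); an infeasible request
#' errors with the maximum attainable r-squared.
#'
#' @param maf_a,maf_b Minor-allele frequencies in (0, 0.5].
#' @param r2 Squared allelic correlation in \[0, 1\].
#' @param sign +1 (default) if the minor alleles are positively associated,
#'   -1 otherwise.
#' @return Named numeric vector of haplotype frequencies
#'   `c(mm, mM, Mm, MM)` (first letter = locus a, lower case = minor);
#'   always sums to 1.
#' @examples
#' haplotype_freqs(0.15, 0.15, 1)          # two-haplotype system
#' haplotype_freqs(0.10, 0.16, 0.51)
#' @export
haplotype_freqs <- function(maf_a, maf_b, r2, sign = 1) {
  for (p in c(maf_a, maf_b))
    if (!is.numeric(p) || p <= 0 || p > 0.5)
      stop("MAFs must lie in (0, 0.5].", call. = FALSE)
  if (!is.numeric(r2) || r2 < 0 || r2 > 1)
    stop("r2 must lie in [0, 1].", call. = FALSE)
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1.", call. = FALSE)
  D <- sign * sqrt(r2 * maf_a * (1 - maf_a) * maf_b * (1 - maf_b))
  h <- c(mm = maf_a * maf_b + D,
         mM = maf_a * (1 - maf_b) - D,
         Mm = (1 - maf_a) * maf_b - D,
         MM = (1 - maf_a) * (1 - maf_b) + D)
  if (any(h < -1e-12) || any(h > 1 + 1e-12)) {
    d_max <- if (sign > 0) min(maf_a * (1 - maf_b), (1 - maf_a) * maf_b)
             else min(maf_a * maf_b, (1 - maf_a) * (1 - maf_b))
    r2_max <- d_max^2 / (maf_a * (1 - maf_a) * maf_b * (1 - maf_b))
    stop("infeasible LD: r2 = ", r2, " violates the Frechet bounds for ",
         "MAFs (", maf_a, ", ", maf_b, "); maximum attainable r2 is ",
         signif(r2_max, 4), ".", call. = FALSE)
  }
  pmin(pmax(h, 0), 1)
}

#' Sample Hardy-Weinberg genotypes at the design SNPs
#'
#' Draws minor-allele dosages (0/1/2) for `n` individuals. SNPs that are
#' members of an LD pair are sampled as two haplotypes per individual from
#' [haplotype_freqs()]; remaining SNPs are independent Binomial(2, maf).
#' A per-SNP imputation certainty is attached, drawn from `certainty`.
#'
#' @param n Number of individuals.
#' @param snps SNP table as from [trpa1_snps()] (columns `rsid`, `maf`).
#' @param ld_pairs LD table as from [trpa1_ld()]; may be empty.
#' @param seed Optional RNG seed.
#' @param certainty Function of `n` returning `n` imputation-certainty
#'   values in (0, 1]. The default emulates a well-imputed cohort: 96% of
#'   calls uniform on (0.99, 1], the rest uniform on (0.90, 0.99].
#' @return Data frame with `participant_id`, one dosage column per rsid,
#'   and one `prob_<rsid>` certainty column per rsid.
#' @export
sample_genotypes <- function(n, snps = trpa1_snps(), ld_pairs = trpa1_ld(),
                             seed = NULL, certainty = default_certainty) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1, all(c("rsid", "maf") %in% names(snps)))
  geno <- matrix(NA_integer_, n, nrow(snps),
                 dimnames = list(NULL, snps$rsid))
  in_pair <- character(0)
  if (!is.null(ld_pairs) && nrow(ld_pairs) > 0) {
    for (i in seq_len(nrow(ld_pairs))) {
      a <- ld_pairs$snp_a[i]; b <- ld_pairs$snp_b[i]
      if (!all(c(a, b) %in% snps$rsid))
        stop("LD pair references unknown SNP(s): ", a, ", ", b, call. = FALSE)
      h <- haplotype_freqs(snps$maf[snps$rsid == a],
                           snps$maf[snps$rsid == b],
                           ld_pairs$r2[i], ld_pairs$sign[i])
      # haplotypes coded by minor-allele count at (a, b)
      hap_a <- c(1L, 1L, 0L, 0L); hap_b <- c(1L, 0L, 1L, 0L)
      draw1 <- sample.int(4L, n, replace = TRUE, prob = h)
      draw2 <- sample.int(4L, n, replace = TRUE, prob = h)
      geno[, a] <- hap_a[draw1] + hap_a[draw2]
      geno[, b] <- hap_b[draw1] + hap_b[draw2]
      in_pair <- c(in_pair, a, b)
    }
  }
  for (s in setdiff(snps$rsid, in_pair))
    geno[, s] <- stats::rbinom(n, 2L, snps$maf[snps$rsid == s])
  probs <- vapply(snps$rsid, function(s) certainty(n), numeric(n))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = n)
  colnames(probs) <- paste0("prob_", snps$rsid)
  cbind(data.frame(participant_id = sprintf("P%06d", seq_len(n))),
        as.data.frame(geno), as.data.frame(probs))
}

default_certainty <- function(n) {
  hi <- stats::runif(n, 0.99, 1)
  lo <- stats::runif(n, 0.90, 0.99)
  ifelse(stats::runif(n) < 0.96, hi, lo)
}

#' Recall participants by genotype
#'
#' Applies the eligibility filter (imputation certainty above the threshold
#' at all SNPs), then samples, without replacement: a control group of
#' individuals homozygous for the major allele at every SNP, and per test
#' group individuals homozygous for the minor allele at all of that group's
#' defining SNP(s). Genotypes at non-defining loci are unconstrained for
#' test groups.
#'
#' @param genotypes Output of [sample_genotypes()].
#' @param group_sizes Named integer vector, e.g.
#'   `c(control = 50, group1 = 15)`; names other than `"control"` must be
#'   `"group<k>"` matching `snps$group`.
#' @param snps SNP table (columns `rsid`, `maf`, `group`).
#' @param seed Optional RNG seed.
#' @param certainty_threshold Minimum per-SNP imputation certainty for
#'   eligibility (default 0.99, exclusive).
#' @return The selected rows of `genotypes` plus columns `eligible` and
#'   `recall_group`. Errors if any pool is too small, reporting the
#'   shortfall and the Hardy-Weinberg expected yield.
#' @export
recall_sample <- function(genotypes, group_sizes, snps = trpa1_snps(),
                          seed = NULL, certainty_threshold = 0.99) {
  if (!is.null(seed)) set.seed(seed)
  rsids <- snps$rsid
  probs <- as.matrix(genotypes[paste0("prob_", rsids)])
  eligible <- rowSums(probs > certainty_threshold) == length(rsids)
  dosage <- as.matrix(genotypes[rsids])
  pools <- list(control = eligible & rowSums(dosage) == 0)
  for (g in sort(unique(snps$group))) {
    gsnps <- rsids[snps$group == g]
    pools[[paste0("group", g)]] <-
      eligible & rowSums(dosage[, gsnps, drop = FALSE] == 2L) == length(gsnps)
  }
  expected_yield <- function(label) {
    n <- nrow(genotypes)
    if (label == "control") return(n * prod((1 - snps$maf)^2))
    gsnps <- which(snps$group == as.integer(sub("group", "", label)))
    # for an LD pair use the stronger single-SNP bound (exact under r2 = 1)
    n * min(snps$maf[gsnps]^2)
  }
  picked <- list()
  for (label in names(group_sizes)) {
    if (!label %in% names(pools))
      stop("unknown recall group \"", label, "\".", call. = FALSE)
    pool <- which(pools[[label]])
    need <- group_sizes[[label]]
    if (length(pool) < need)
      stop("insufficient pool for ", label, ": need ", need, ", have ",
           length(pool), " eligible (Hardy-Weinberg expectation ~",
           round(expected_yield(label), 1), " before certainty filtering).",
           call. = FALSE)
    picked[[label]] <- sample(pool, need)
  }
  idx <- unlist(picked, use.names = FALSE)
  out <- genotypes[idx, , drop = FALSE]
  out$eligible <- TRUE
  out$recall_group <- rep(names(group_sizes),
                          times = vapply(picked, length, integer(1)))
  rownames(out) <- NULL
  out
}

#' Screen a cohort for exclusion criteria
#'
#' Emulates telephone screening: each criterion is an independent Bernoulli
#' flag with a configurable prevalence; flagged records are dropped.
#'
#' @param records Data frame of participants.
#' @param prevalences Named vector of exclusion prevalences in \[0, 1\].
#'   Defaults cover the screening criteria of a healthy-young-adult pain
#'   study (neurological disorder, regular analgesic use, analgesics in the
#'   last 24 h, pregnancy, acute/chronic pain conditions, severe
#'   anxiety/depression, relevant allergies, recreational drug use).
#' @param seed Optional RNG seed.
#' @return The retained rows, with an attribute `"excluded"` giving the
#'   count dropped per criterion (a record counts toward every criterion it
#'   triggers).
#' @export
screen_exclusions <- function(records,
                              prevalences = c(neurological = 0.02,
                                              regular_analgesics = 0.05,
                                              recent_analgesics = 0.05,
                                              pregnancy = 0.02,
                                              pain_condition = 0.05,
                                              anxiety_depression = 0.04,
                                              allergy = 0.02,
                                              recreational_drugs = 0.03),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(prevalences < 0 | prevalences > 1))
    stop("prevalences must lie in [0, 1].", call. = FALSE)
  n <- nrow(records)
  flags <- vapply(prevalences,
                  function(p) stats::runif(n) < p, logical(n))
  if (is.null(dim(flags))) flags <- matrix(flags, nrow = n)
  keep <- rowSums(flags) == 0
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- colSums(flags)
  out
}

#' Generate quantitative-sensory-testing phenotypes for a recalled cohort
#'
#' Attaches baseline and post-sensitization endpoints. The primary
#' endpoint, heat pain threshold (HPT), is modelled as
#' `baseline = mean + z + e1` and
#' `post = mean + sensitization_shift + effect + z + e2`, where `z` is a
#' participant trait shared between visits (test-retest correlation `cor`)
#' and both marginals have standard deviation `sd`. `effect` is the
#' group effect in degrees C from `effect_map` (0 for unlisted groups).
#' Secondary endpoints are drawn with configurable means/SDs and load on
#' the same trait through a single common factor; the sensitization pain
#' rating is an integer 0-10.
#'
#' @param cohort Data frame with a `recall_group` column (e.g. from
#'   [recall_sample()]).
#' @param effect_map Named numeric vector of post-sensitization group
#'   effects in degrees C, e.g. `c(group1 = 4)`.
#' @param noise_config List with elements `mean` (baseline HPT mean, degC,
#'   default 42), `sd` (marginal SD, default 2.5), `cor` (between-visit
#'   correlation, default 0.7), `sensitization_shift` (mean HPT change after
#'   sensitization, default -3 degC), `factor_loading` (correlation of
#'   secondary endpoints with the latent trait, default 0.3).
#' @param seed Optional RNG seed.
#' @param censor_50c If `TRUE`, HPT values are censored at the 50 degC
#'   thermode safety cap (default `FALSE`: censoring distorts the normal
#'   model the design math assumes).
#' @return `cohort` with added columns `hpt_baseline`, `hpt_post`, the
#'   secondary QST endpoints (`cdt`, `wdt`, `cpt`, `mdt`, `mpt`,
#'   `pressure_pain`, baseline and `_post`), and `cinnamaldehyde_rating`.
#' @export
generate_qst <- function(cohort, effect_map = c(group1 = 0),
                         noise_config = list(), seed = NULL,
                         censor_50c = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (!"recall_group" %in% names(cohort))
    stop("cohort must carry a recall_group column.", call. = FALSE)
  cfg <- utils::modifyList(list(mean = 42, sd = 2.5, cor = 0.7,
                                sensitization_shift = -3,
                                factor_loading = 0.3), noise_config)
  if (cfg$sd <= 0) stop("noise_config$sd must be positive.", call. = FALSE)
  if (cfg$cor < 0 || cfg$cor >= 1)
    stop("noise_config$cor must lie in [0, 1).", call. = FALSE)
  n <- nrow(cohort)
  eff <- effect_map[cohort$recall_group]
  eff[is.na(eff)] <- 0
  z <- stats::rnorm(n, 0, cfg$sd * sqrt(cfg$cor))          # shared trait
  e_sd <- cfg$sd * sqrt(1 - cfg$cor)
  cohort$hpt_baseline <- cfg$mean + z + stats::rnorm(n, 0, e_sd)
  cohort$hpt_post <- cfg$mean + cfg$sensitization_shift + eff + z +
    stats::rnorm(n, 0, e_sd)
  if (censor_50c) {
    cohort$hpt_baseline <- pmin(cohort$hpt_baseline, 50)
    cohort$hpt_post <- pmin(cohort$hpt_post, 50)
  }
  # secondary endpoints: configurable (mean, sd) with a common-factor link
  sec <- list(cdt = c(30.5, 1.2), wdt = c(34.3, 1.2), cpt = c(12, 8),
              mdt = c(2.5, 1.5), mpt = c(80, 40), pressure_pain = c(320, 120))
  zstd <- z / (cfg$sd * sqrt(cfg$cor))
  lam <- cfg$factor_loading
  for (nm in names(sec)) {
    mu <- sec[[nm]][1]; s <- sec[[nm]][2]
    cohort[[nm]] <- mu + s * (lam * zstd +
                                sqrt(1 - lam^2) * stats::rnorm(n))
    cohort[[paste0(nm, "_post")]] <- cohort[[nm]] +
      stats::rnorm(n, 0, s * 0.5)
  }
  cohort$cinnamaldehyde_rating <-
    as.integer(pmin(10, pmax(0, round(stats::rnorm(n, 4, 2)))))
  cohort
}

#' Write a cohort to CSV
#'
#' One row per participant with the documented column set.
#'
#' @param cohort Data frame (e.g. from [generate_qst()]).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Write the design SNP genotypes of a cohort as VCF
#'
#' Emits a minimal VCF 4.2 file with one record per design SNP and one
#' diploid unphased GT sample column per participant (alleles coded REF =
#' major, ALT = minor; placeholder chromosome/position/allele fields, rsids
#' as IDs) for interoperability with standard genetics tooling.
#'
#' @param cohort Data frame containing the per-SNP dosage columns.
#' @param path Output file path.
#' @param snps SNP table (for rsids and order).
#' @return The path, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path, snps = trpa1_snps()) {
  ids <- cohort$participant_id
  hdr <- c("##fileformat=VCFv4.2",
           "##source=rbgadapt synthetic cohort (genotypes are simulated)",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  rows <- vapply(seq_len(nrow(snps)), function(i) {
    rsid <- snps$rsid[i]
    dos <- cohort[[rsid]]
    if (is.null(dos)) stop("cohort lacks dosage column ", rsid, call. = FALSE)
    paste(c("8", as.character(1000 * i), rsid, "A", "C", ".", "PASS",
            paste0("AF=", snps$maf[i]), "GT", gt_code[dos + 1L]),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Generate a complete synthetic recall cohort
#'
#' Convenience wrapper chaining [sample_genotypes()],
#' [screen_exclusions()], [recall_sample()] and [generate_qst()].
#'
#' @param pool_n Size of the genotyped pool to simulate recruitment from
#'   (default 8000, the approximate size of a young-adult genotyped cohort
#'   available for recall).
#' @param group_sizes Named recall sizes (default 15 control + 15 group1).
#' @param effect_map Group effects in degrees C for the post-sensitization
#'   heat pain threshold.
#' @param seed RNG seed governing the whole generation.
#' @inheritParams generate_qst
#' @param screen If `TRUE` (default) apply telephone-screening exclusions
#'   to the pool before recall.
#' @return A phenotyped cohort data frame.
#' @examples
#' coh <- synthesize_cohort(seed = 1, effect_map = c(group1 = 4))
#' table(coh$recall_group)
#' @export
synthesize_cohort <- function(pool_n = 8000,
                              group_sizes = c(control = 15, group1 = 15),
                              effect_map = c(group1 = 0),
                              noise_config = list(), seed = NULL,
                              screen = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  pool <- sample_genotypes(pool_n)
  if (screen) pool <- screen_exclusions(pool)
  cohort <- recall_sample(pool, group_sizes)
  generate_qst(cohort, effect_map = effect_map, noise_config = noise_config)
}
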