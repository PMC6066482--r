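# Validation-cohort genotype counts (n_AA, n_AG, n_GG) used throughout:
# heroin abusers 202/511/319, controls 688/1409/766.
ha_counts <- c(202, 511, 319)
hc_counts <- c(688, 1409, 766)

test_that("HWE chi-squared matches the reported cohort p-values", {
  expect_equal(round(hwe_chisq(ha_counts)$p, 2), 0.92)
  expect_equal(round(hwe_chisq(hc_counts)$p, 2), 0.42)
})

test_that("HWE test is exact at perfect proportions and flags monomorphism", {
  h <- hwe_chisq(c(25, 50, 25))
  expect_equal(h$chisq, 0)
  expect_equal(h$p, 1)
  expect_true(hwe_chisq(c(40, 0, 0))$monomorphic)
  expect_true(is.na(hwe_chisq(c(0, 0, 40))$chisq))
  # chi-squared is never negative
  set.seed(2)
  for (i in 1:20) {
    cnt <- rmultinom(1, 200, runif(3, 0.05, 1))[, 1]
    expect_gte(hwe_chisq(cnt)$chisq, 0)
  }
})

test_that("case-control association reproduces the printed arithmetic", {
  a <- case_control_association(ha_counts, hc_counts)
  expect_equal(round(a$chisq_allelic, 2), 11.28)
  expect_equal(round(a$chisq_genotypic, 2), 11.31)
  expect_equal(round(a$or, 2), 0.84)
  expect_equal(round(a$ci, 2), c(0.76, 0.93))
  # independent oracle: Pearson chi-squared from chisq.test
  expect_equal(a$chisq_genotypic,
               unname(chisq.test(rbind(ha_counts, hc_counts),
                                 correct = FALSE)$statistic))
  expect_equal(a$chisq_allelic,
               unname(chisq.test(a$allele_table, correct = FALSE)$statistic))
})

test_that("association degenerates and inverts as expected", {
  same <- case_control_association(c(10, 20, 10), c(10, 20, 10))
  expect_equal(same$chisq_allelic, 0)
  expect_equal(same$or, 1)
  sw1 <- case_control_association(c(5, 10, 3), c(2, 9, 9))
  sw2 <- case_control_association(c(2, 9, 9), c(5, 10, 3))
  expect_equal(sw1$or, 1 / sw2$or)
  expect_error(case_control_association(c(0, 0, 10), c(0, 0, 8)), "marginal")
})

test_that("allele frequencies follow the gene-counting formula", {
  expect_equal(round(allele_frequencies(ha_counts)["freq_A"], 2),
               c(freq_A = 0.44))
  expect_equal(sum(allele_frequencies(ha_counts)), 1)
  expect_equal(unname(allele_frequencies(c(7, 0, 0))["freq_A"]), 1)
  expect_equal(unname(allele_frequencies(c(0, 12, 0))["freq_A"]), 0.5)
})

test_that("call-rate filter drops exactly the SNPs at or below threshold", {
  set.seed(14)
  gt <- simulate_genotypes(100, default_snp_specs(), list(), seed = 1)
  out <- call_rate_filter(gt, 0.98)
  expect_identical(out$table$geno, gt$geno)  # no missing data -> unchanged
  # one SNP with 3/100 missing (0.97 <= 0.98) is dropped
  g2 <- gt$geno
  g2[1:3, "rs4680"] <- NA
  gt2 <- genotype_table(g2, gt$snps)
  out2 <- call_rate_filter(gt2, 0.98)
  expect_false("rs4680" %in% colnames(out2$table$geno))
  expect_equal(sum(out2$report$dropped), 1)
  # 5% missingness: dropped set equals an independent recount
  gt3 <- simulate_genotypes(400, default_snp_specs(), list(), seed = 2,
                            missing_rate = 0.05)
  out3 <- call_rate_filter(gt3, 0.98)
  brute <- colnames(gt3$geno)[colSums(!is.na(gt3$geno)) / 400 <= 0.98]
  expect_setequal(out3$report$snp[out3$report$dropped], brute)
})

test_that("a duplicated SNP column is in perfect LD with itself", {
  set.seed(15)
  d <- rbinom(300, 2, 0.4)
  gt <- gt_from_dosage(s1 = d, s2 = d)
  ld <- ld_pairwise(gt, "s1", "s2")
  expect_equal(ld$Dprime, 1)
  expect_equal(ld$r2, 1)
})

test_that("independent SNPs show near-zero r2", {
  set.seed(16)
  gt <- gt_from_dosage(s1 = rbinom(5000, 2, 0.5), s2 = rbinom(5000, 2, 0.3))
  expect_lt(ld_pairwise(gt, "s1", "s2")$r2, 0.01)
})

test_that("EM recovers known-phase haplotype frequencies and the direct MLE", {
  # phased truth: 100 subjects from haplotype counts AB=40, Ab=10, aB=10,
  # ab=40 (A/B = allele 'A' at each SNP), paired at random then collapsed
  set.seed(17)
  haps <- rep(1:4, c(80, 20, 20, 80))  # 1=AB 2=Ab 3=aB 4=ab
  haps <- sample(haps)
  h1 <- haps[1:100]; h2 <- haps[101:200]
  dA <- (h1 %in% c(1, 2)) + (h2 %in% c(1, 2))
  dB <- (h1 %in% c(1, 3)) + (h2 %in% c(1, 3))
  gt <- gt_from_dosage(s1 = dA, s2 = dB)
  ld <- ld_pairwise(gt, "s1", "s2", tol = 1e-10)
  expect_lt(max(abs(ld$haplotypes - c(0.4, 0.1, 0.1, 0.4))), 0.05)
  # independent oracle: direct numerical maximisation of the genotype
  # likelihood over the haplotype simplex
  tab <- matrix(0, 3, 3)
  for (i in 1:100) tab[dA[i] + 1, dB[i] + 1] <- tab[dA[i] + 1, dB[i] + 1] + 1
  nll <- function(par) {
    h <- exp(c(par, 0)); h <- h / sum(h)
    -rewardconn:::ld_loglik(h, tab)
  }
  opt <- optim(c(0, 0, 0), nll, method = "BFGS")
  h_mle <- exp(c(opt$par, 0)); h_mle <- h_mle / sum(h_mle)
  expect_lt(max(abs(ld$haplotypes - h_mle)), 1e-4)
  # EM improves on the linkage-equilibrium start
  pA <- mean(dA) / 2; pB <- mean(dB) / 2
  ll0 <- rewardconn:::ld_loglik(c(pA * pB, pA * (1 - pB), (1 - pA) * pB,
                                  (1 - pA) * (1 - pB)), tab)
  expect_gte(ld$loglik, ll0)
})

test_that("r2 <= Dprime^2 and both lie in [0,1] across random tables", {
  set.seed(18)
  for (i in 1:15) {
    gt <- gt_from_dosage(s1 = rbinom(150, 2, runif(1, 0.2, 0.8)),
                         s2 = rbinom(150, 2, runif(1, 0.2, 0.8)))
    ld <- tryCatch(ld_pairwise(gt, "s1", "s2"), error = function(e) NULL)
    if (is.null(ld)) next
    expect_gte(ld$Dprime, 0); expect_lte(ld$Dprime, 1)
    expect_gte(ld$r2, 0);     expect_lte(ld$r2, 1)
    expect_lte(ld$r2, ld$Dprime^2 + 1e-12)
  }
})

test_that("screen finds a planted main effect and no spurious interaction", {
  set.seed(19)
  n <- 300
  d <- rbinom(n, 2, 0.4)
  g <- rep(c("HA", "HC"), each = n / 2)
  covs <- cbind(age = rnorm(n, 37, 4))
  y <- 0.5 * d + rnorm(n)
  gt <- gt_from_dosage(snp = 2 - d)  # dosage counts risk allele G = 2 - #A
  sc <- snp_screen(y, gt, g, covs)$results
  expect_lt(sc$p_main, 1e-4)
  expect_gt(sc$p_interaction, 0.01)
})

test_that("a group-specific slope is detected as an interaction", {
  set.seed(20)
  n <- 300
  d <- rbinom(n, 2, 0.45)
  g <- rep(c("HA", "HC"), each = n / 2)
  y <- ifelse(g == "HC", 0.8, 0) * d + rnorm(n)
  gt <- gt_from_dosage(snp = 2 - d)
  sc <- snp_screen(y, gt, g)$results
  expect_lt(sc$p_interaction, 1e-4)
  expect_lt(sc$p_HC, 1e-6)
  expect_gt(sc$p_HA, 0.05)
})

test_that("recoding dosage to the other allele leaves screen p unchanged", {
  set.seed(21)
  n <- 120
  d <- rbinom(n, 2, 0.4)
  g <- rep(c("HA", "HC"), each = n / 2)
  y <- 0.3 * d + rnorm(n)
  sc_g <- snp_screen(y, gt_from_dosage(snp = 2 - d), g)$results
  sc_a <- snp_screen(y, gt_from_dosage(snp = 2 - d, risk = "A"), g)$results
  expect_equal(sc_g$p_main, sc_a$p_main, tolerance = 1e-10)
})

test_that("monomorphic strata are flagged rather than tested", {
  n <- 40
  g <- rep(c("HA", "HC"), each = n / 2)
  d <- c(rep(0, n / 2), rbinom(n / 2, 2, 0.5))  # monomorphic in HA
  gt <- gt_from_dosage(snp = 2 - d)
  sc <- snp_screen(rnorm(n), gt, g)$results
  expect_true(is.na(sc$p_HA))
  expect_false(is.na(sc$p_HC))
})
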