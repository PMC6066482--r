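test_that("same seed and config give a bit-identical cohort", {
  cfg <- small_config(n_per_group = 4, seed = 21)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$genotypes$geno, c2$genotypes$geno)
  expect_identical(c1$fa, c2$fa)
  expect_identical(c1$voxel_data[[5]]$values, c2$voxel_data[[5]]$values)
})

test_that("generated genotypes sit in Hardy-Weinberg proportions", {
  specs <- data.frame(id = "s1", maf = 0.5, allele1 = "A", allele2 = "G",
                      risk = "A", stringsAsFactors = FALSE)
  ps <- vapply(1:5, function(sd) {
    gt <- simulate_genotypes(1e4, specs, list(), seed = 100 + sd)
    hwe_chisq(genotype_counts(gt, "s1"))$p
  }, numeric(1))
  expect_true(all(ps > 0.01))
})

test_that("invalid frequencies and infeasible LD targets are rejected", {
  bad <- data.frame(id = "s1", maf = 0, allele1 = "A", allele2 = "G",
                    risk = "A", stringsAsFactors = FALSE)
  expect_error(simulate_genotypes(10, bad, list()), "in \\(0,1\\)|> 0")
  two <- data.frame(id = c("s1", "s2"), maf = c(0.3, 0.5), allele1 = "A",
                    allele2 = "G", risk = "A", stringsAsFactors = FALSE)
  expect_error(
    simulate_genotypes(10, two, list(list(snps = c("s1", "s2"), r = 1))),
    "infeasible")
  expect_error(sim_config(snp_specs = transform(default_snp_specs(),
                                                maf = c(1.2, .5, .5, .5, .5, .5))),
               "(0,1)", fixed = TRUE)
})

test_that("perfect LD at equal MAF duplicates the genotype column", {
  two <- data.frame(id = c("s1", "s2"), maf = c(0.5, 0.5), allele1 = "A",
                    allele2 = "G", risk = "A", stringsAsFactors = FALSE)
  gt <- simulate_genotypes(200, two, list(list(snps = c("s1", "s2"), r = 1)),
                           seed = 5)
  expect_identical(unname(gt$geno[, "s1"]), unname(gt$geno[, "s2"]))
})

test_that("EM r2 recovers the target haplotype correlation squared", {
  two <- data.frame(id = c("s1", "s2"), maf = c(0.5, 0.5), allele1 = "A",
                    allele2 = "G", risk = "A", stringsAsFactors = FALSE)
  gt <- simulate_genotypes(5000, two,
                           list(list(snps = c("s1", "s2"), r = 0.9)), seed = 6)
  ld <- ld_pairwise(gt, "s1", "s2")
  expect_lt(abs(ld$r2 - 0.81), 0.05)
})

test_that("missingness is injected at the configured per-SNP rate", {
  gt <- simulate_genotypes(2000, default_snp_specs(), list(), seed = 7,
                           missing_rate = 0.05)
  cr <- call_rates(gt)
  expect_true(all(abs(cr - 0.95) < 0.03))
})

test_that("null configuration leaves no group difference on any edge", {
  cfg <- sim_config(n_per_group = 20,
                    affected_edges = data.frame(edge = character(0),
                                                effect = numeric(0)),
                    genetic_effect = NULL, seed = 31)
  co <- simulate_cohort(cfg)
  conn <- build_connectivity(co$voxel_data, co$fa, co$subjects)
  dmean <- colMeans(conn$strengths[co$subjects$group == "HA", ]) -
    colMeans(conn$strengths[co$subjects$group == "HC", ])
  expect_lt(max(abs(dmean)), 0.045)  # ~4.5 SE of a null mean difference
})

test_that("planted deficit yields negative t growing in magnitude with n", {
  edges <- atlas_edges(reward_atlas())$edge
  tvals <- vapply(c(10, 80), function(n) {
    cfg <- sim_config(n_per_group = n,
                      affected_edges = data.frame(edge = edges[1],
                                                  effect = -1.5),
                      genetic_effect = NULL, seed = 41)
    co <- simulate_cohort(cfg)
    conn <- build_connectivity(co$voxel_data[edges[1]], co$fa, co$subjects)
    adjusted_t(conn$strengths[, 1], co$subjects$group)
  }, numeric(1))
  expect_true(all(tvals < 0))
  expect_gt(abs(tvals[2]), abs(tvals[1]))
})

test_that("noiseless, direct-effect-free cognition is affine in the mediator", {
  cfg <- small_config(
    n_per_group = 8, seed = 51,
    mediation = list(b = 100, c_prime = 0, noise_sd = 0, beta_age = 0))
  co <- simulate_cohort(cfg)
  med <- co$truth$mediator[co$subjects$id]
  pred_gap <- co$subjects$MoCA -
    (ifelse(co$subjects$group == "HA", 21.9, 25.7) + 100 * (med - 0.5))
  expect_lt(max(abs(pred_gap)), 0.051)  # MoCA rounded to 1 dp
})

test_that("truth records exactly the planted edges and effects", {
  cfg <- small_config(n_per_group = 4, n_edges = 5, effect = -0.7, seed = 61)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$truth$affected_edges), 5)
  expect_true(all(co$truth$affected_edges$effect == -0.7))
  expect_true(all(co$truth$affected_edges$edge %in% names(co$voxel_data)))
  # planted regions are disjoint across edges
  regs <- co$truth$regions
  expect_false(anyDuplicated(unlist(regs)) > 0)
})

test_that("grid too small to host disjoint regions is rejected", {
  expect_error(sim_config(grid_shape = c(12, 12, 12)), "enlarge the grid")
})
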