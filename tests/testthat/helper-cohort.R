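# Shared fixture builders: small cohorts and genotype tables generated in
# code, seconds-scale.

tiny_atlas <- function(n = 4) reward_atlas()[seq_len(n), , drop = FALSE]

# Small cohort config: few subjects, handful of planted edges.
small_config <- function(n_per_group = 12, effect = -1.5, n_edges = 3,
                         seed = 11, ...) {
  edges <- atlas_edges(reward_atlas())$edge
  sim_config(
    n_per_group = n_per_group,
    affected_edges = data.frame(edge = edges[seq_len(n_edges)],
                                effect = effect),
    seed = seed, ...)
}

# Genotype table built directly from dosage vectors (allele1 = "A",
# allele2 = "G", risk "G" unless stated).
gt_from_dosage <- function(..., risk = NULL) {
  ds <- list(...)
  n <- length(ds[[1]])
  ids <- sprintf("S%03d", seq_len(n))
  snp_ids <- names(ds)
  if (is.null(risk)) risk <- rep("G", length(ds))
  geno <- sapply(ds, function(d)
    c("G/G", "A/G", "A/A")[d + 1])  # d = copies of A
  geno <- matrix(geno, nrow = n, dimnames = list(ids, snp_ids))
  genotype_table(geno, data.frame(id = snp_ids, allele1 = "A", allele2 = "G",
                                  risk = risk, stringsAsFactors = FALSE))
}
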