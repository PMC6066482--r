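# Synthetic-cohort generator: two groups with covariates, HWE genotypes with
# LD-block structure, planted edge effects on a voxel grid, and cognition
# generated as a mediated linear function of network strength.

#' Simulation configuration
#'
#' Assembles and validates the generative parameters for a synthetic cohort.
#' Defaults emulate the imaging arm of a heroin-addiction reward-connectome
#' study: 78 subjects per group; HA subjects smoke more and are slightly
#' younger; one focal risk SNP (rs279858-like, risk allele G) inside an LD
#' block of highly correlated GABRA2-like SNPs plus independent null SNPs; a
#' group-level FA deficit planted on the VTA-linked edges; a per-allele
#' genotype effect on those same edges that is present in controls and
#' abolished in the addiction group (the gene-by-addiction interaction); and
#' MoCA generated from the mediated path.
#'
#' Effect sizes are standardized: units of the between-subject SD of an edge
#' strength under the null.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param grid_shape 3-D voxel grid; must tile into enough 2x2x2 blocks to
#'   host one disjoint region per edge.
#' @param atlas node atlas (default [reward_atlas()]).
#' @param snp_specs data frame: \code{id}, \code{maf} (frequency of
#'   \code{allele1}, in (0,1)), \code{allele1}, \code{allele2}, \code{risk}.
#' @param ld_blocks list of \code{list(snps = <ids>, r = <target haplotype
#'   correlation in [0,1]>)}; SNPs outside any block are independent.
#' @param affected_edges data frame \code{edge}, \code{effect} (standardized
#'   mean FA change in HA; negative = deficit).
#' @param genetic_effect list \code{snp}, \code{beta} (standardized per-allele
#'   effect on affected-edge strength in the control group), \code{interaction}
#'   (added to \code{beta} in the HA group).
#' @param mediation list \code{b} (MoCA points per unit mediator FA),
#'   \code{c_prime} (direct MoCA points per risk allele), \code{noise_sd}
#'   (MoCA residual SD), \code{beta_age} (MoCA points per year).
#' @param covariate_model per-group means/sds for age and cigarettes/day.
#' @param baseline_fa mean FA inside streamline regions.
#' @param sigma_subject between-subject SD of region FA (shared across the
#'   region's voxels).
#' @param sigma_voxel voxel-level FA noise SD.
#' @param streamline_mean,streamline_sd distribution of positive streamline
#'   values inside a region.
#' @param missing_rate per-SNP genotype missingness rate (default 0).
#' @param seed RNG seed; the same seed and config give bit-identical cohorts.
#' @return Object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_per_group = 78,
                       grid_shape = c(14, 14, 14),
                       atlas = reward_atlas(),
                       snp_specs = default_snp_specs(),
                       ld_blocks = default_ld_blocks(),
                       affected_edges = default_affected_edges(atlas),
                       genetic_effect = list(snp = "rs279858", beta = -0.25,
                                             interaction = 0.25),
                       mediation = list(b = 150, c_prime = -0.2,
                                        noise_sd = 2, beta_age = -0.05),
                       covariate_model = list(
                         age = list(HA = c(36.2, 3.9), HC = c(37.5, 5.0)),
                         cigarettes = list(HA = c(26.0, 9.1), HC = c(8.7, 9.8))),
                       baseline_fa = 0.5,
                       sigma_subject = 0.03,
                       sigma_voxel = 0.02,
                       streamline_mean = 5, streamline_sd = 1,
                       missing_rate = 0,
                       seed = 1L) {
  stopifnot(n_per_group >= 2, length(grid_shape) == 3, all(grid_shape >= 2),
            is.data.frame(snp_specs),
            all(c("id", "maf", "allele1", "allele2", "risk") %in% names(snp_specs)),
            missing_rate >= 0, missing_rate < 1,
            baseline_fa > 0, baseline_fa < 1)
  if (any(snp_specs$maf <= 0) || any(snp_specs$maf >= 1))
    stop("every minor-allele frequency must lie strictly in (0,1)")
  for (bl in ld_blocks) {
    if (is.null(bl$snps) || is.null(bl$r)) stop("ld block needs $snps and $r")
    if (bl$r < 0 || bl$r > 1) stop("LD target correlation must be in [0,1]")
    if (!all(bl$snps %in% snp_specs$id))
      stop("LD block names unknown SNP(s)")
  }
  edges <- atlas_edges(atlas)
  if (nrow(affected_edges)) {
    unknown <- setdiff(affected_edges$edge, edges$edge)
    if (length(unknown)) stop("unknown affected edge(s): ",
                              paste(unknown, collapse = ", "))
    if (anyDuplicated(affected_edges$edge)) stop("duplicate affected edges")
  }
  n_blocks <- prod(grid_shape %/% 2)
  if (n_blocks < nrow(edges))
    stop("grid ", paste(grid_shape, collapse = "x"), " tiles into ", n_blocks,
         " disjoint 2x2x2 regions but the atlas has ", nrow(edges),
         " edges; enlarge the grid")
  structure(list(n_per_group = as.integer(n_per_group),
                 grid_shape = as.integer(grid_shape), atlas = atlas,
                 snp_specs = snp_specs, ld_blocks = ld_blocks,
                 affected_edges = affected_edges,
                 genetic_effect = genetic_effect, mediation = mediation,
                 covariate_model = covariate_model, baseline_fa = baseline_fa,
                 sigma_subject = sigma_subject, sigma_voxel = sigma_voxel,
                 streamline_mean = streamline_mean,
                 streamline_sd = streamline_sd,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default candidate-SNP panel for simulation
#'
#' One focal risk SNP (rs279858-like, alleles A/G, risk G at frequency ~0.5),
#' three same-gene neighbours destined for its LD block, and two independent
#' null markers.
#' @export
default_snp_specs <- function() {
  data.frame(
    id = c("rs279858", "rs693547", "rs519270", "rs279871",
           "rs1799971", "rs4680"),
    maf = c(0.49, 0.49, 0.49, 0.49, 0.35, 0.48),
    allele1 = c("A", "A", "A", "A", "A", "A"),
    allele2 = c("G", "G", "G", "G", "G", "G"),
    risk = c("G", "G", "G", "G", "G", "G"),
    stringsAsFactors = FALSE
  )
}

#' Default LD-block structure: the four GABRA2-like SNPs at haplotype
#' correlation 0.85 (r^2 ~ 0.72); the null markers stay independent.
#' @export
default_ld_blocks <- function() {
  list(list(snps = c("rs279858", "rs693547", "rs519270", "rs279871"),
            r = 0.85))
}

#' Default planted group effect: a -0.8 SD FA deficit on every VTA-linked
#' edge of the atlas.
#' @param atlas node atlas.
#' @export
default_affected_edges <- function(atlas = reward_atlas()) {
  e <- atlas_edges(atlas)
  vta <- e$edge[grepl("VTA", e$edge)]
  data.frame(edge = vta, effect = -0.8, stringsAsFactors = FALSE)
}

#' Simulate genotypes in Hardy-Weinberg equilibrium with LD blocks
#'
#' Haplotype-based: within each LD block a haplotype is generated as a Markov
#' chain along the block's SNPs, each consecutive pair having disequilibrium
#' \code{D = r * sqrt(p1 q1 p2 q2)} (so the allele-indicator correlation on
#' haplotypes between adjacent SNPs is the target \code{r}); SNPs outside any
#' block are independent. Each subject receives two independently drawn
#' haplotypes, which guarantees HWE at every SNP. Target haplotype
#' frequencies are validated (e.g. r = 1 requires equal allele frequencies).
#'
#' @param n number of subjects.
#' @param snp_specs,ld_blocks see [sim_config()].
#' @param seed RNG seed.
#' @param missing_rate per-SNP missingness rate.
#' @param ids optional subject ids (default S001, ...).
#' @return A [genotype_table()].
#' @export
simulate_genotypes <- function(n, snp_specs = default_snp_specs(),
                               ld_blocks = default_ld_blocks(), seed = NULL,
                               missing_rate = 0, ids = NULL) {
  stopifnot(n >= 1, all(snp_specs$maf > 0), all(snp_specs$maf < 1))
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  S <- nrow(snp_specs)
  with_seed(seed, {
    # haplotype allele1-indicator matrix, 2n haplotypes x S SNPs
    H <- matrix(NA, 2 * n, S, dimnames = list(NULL, snp_specs$id))
    in_block <- unlist(lapply(ld_blocks, `[[`, "snps"))
    if (anyDuplicated(in_block)) stop("a SNP appears in two LD blocks")
    for (s in setdiff(snp_specs$id, in_block))
      H[, s] <- stats::runif(2 * n) < snp_specs$maf[snp_specs$id == s]
    for (bl in ld_blocks) {
      ids_bl <- bl$snps
      p1 <- snp_specs$maf[match(ids_bl[1], snp_specs$id)]
      H[, ids_bl[1]] <- stats::runif(2 * n) < p1
      for (k in seq_along(ids_bl)[-1]) {
        pa <- snp_specs$maf[match(ids_bl[k - 1], snp_specs$id)]
        pb <- snp_specs$maf[match(ids_bl[k], snp_specs$id)]
        D <- bl$r * sqrt(pa * (1 - pa) * pb * (1 - pb))
        p11 <- pa * pb + D
        if (p11 > min(pa, pb) + 1e-12 || pa * (1 - pb) - D < -1e-12)
          stop("LD target r = ", bl$r, " infeasible for frequencies ",
               pa, " and ", pb)
        cond1 <- min(p11 / pa, 1)                # P(allele1 | prev allele1)
        cond0 <- max((pb - p11) / (1 - pa), 0)   # P(allele1 | prev allele2)
        prev <- H[, ids_bl[k - 1]]
        u <- stats::runif(2 * n)
        H[, ids_bl[k]] <- ifelse(prev, u < cond1, u < cond0)
      }
    }
    # pair haplotypes (2i-1, 2i) into subject i
    geno <- matrix(NA_character_, n, S, dimnames = list(ids, snp_specs$id))
    for (s in seq_len(S)) {
      a1 <- snp_specs$allele1[s]; a2 <- snp_specs$allele2[s]
      h1 <- ifelse(H[seq(1, 2 * n, 2), s], a1, a2)
      h2 <- ifelse(H[seq(2, 2 * n, 2), s], a1, a2)
      geno[, s] <- ifelse(h1 <= h2, paste(h1, h2, sep = "/"),
                          paste(h2, h1, sep = "/"))
      if (missing_rate > 0)
        geno[stats::runif(n) < missing_rate, s] <- NA_character_
    }
    genotype_table(geno, snp_specs)
  })
}

#' Simulate the subject table (groups and covariates)
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (default derived from the config seed).
#' @return Data frame: id, group (HA/HC), age, cigarettes_per_day.
#' @export
simulate_subjects <- function(config, seed = config$seed) {
  n <- config$n_per_group
  cm <- config$covariate_model
  with_seed(seed, {
    grp <- rep(c("HA", "HC"), each = n)
    age <- c(stats::rnorm(n, cm$age$HA[1], cm$age$HA[2]),
             stats::rnorm(n, cm$age$HC[1], cm$age$HC[2]))
    cig <- pmax(c(stats::rnorm(n, cm$cigarettes$HA[1], cm$cigarettes$HA[2]),
                  stats::rnorm(n, cm$cigarettes$HC[1], cm$cigarettes$HC[2])), 0)
    data.frame(id = sprintf("S%03d", seq_len(2 * n)), group = grp,
               age = round(age, 1), cigarettes_per_day = round(cig),
               stringsAsFactors = FALSE)
  })
}

# Deterministic edge -> 2x2x2 block assignment: the grid is tiled into
# disjoint 2x2x2 blocks in array order and edge k (in sorted-edge-id order)
# takes block k. Returns a named list of linear voxel-index vectors.
edge_regions <- function(grid_shape, edges) {
  nb <- grid_shape %/% 2
  blocks <- vector("list", prod(nb))
  k <- 0
  for (bz in seq_len(nb[3])) for (by in seq_len(nb[2])) for (bx in seq_len(nb[1])) {
    k <- k + 1
    xs <- (2 * bx - 1):(2 * bx); ys <- (2 * by - 1):(2 * by)
    zs <- (2 * bz - 1):(2 * bz)
    g <- expand.grid(x = xs, y = ys, z = zs)
    blocks[[k]] <- g$x + (g$y - 1) * grid_shape[1] +
      (g$z - 1) * grid_shape[1] * grid_shape[2]
  }
  if (length(edges) > length(blocks)) stop("not enough disjoint regions")
  stats::setNames(blocks[seq_along(edges)], edges)
}

#' Simulate per-edge voxel data and FA maps
#'
#' Every edge gets a disjoint 2x2x2 voxel region carrying positive streamline
#' values (truncated-normal) for all subjects; voxels outside regions have
#' streamline value 0. FA inside a region is baseline + planted group effect
#' + per-allele genotype effect + a subject-level deviation shared across the
#' region + voxel noise, clamped to \[0,1\]; FA elsewhere is baseline + voxel
#' noise. Effects are standardized by the null between-subject SD of an edge
#' strength, \code{sqrt(sigma_subject^2 + sigma_voxel^2 / 8)}.
#'
#' @param config a [sim_config()].
#' @param subjects subject table from [simulate_subjects()].
#' @param dose optional named per-subject risk-allele dosage used for the
#'   genotype effect (0 when omitted).
#' @param seed RNG seed.
#' @return List: \code{voxel_data} (named list of [edge_voxel_data()]),
#'   \code{fa} (subjects x voxels matrix), \code{regions} (true planted voxel
#'   indices per edge), \code{sigma_strength} (the standardization unit).
#' @export
simulate_voxel_data <- function(config, subjects, dose = NULL,
                                seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  edges <- atlas_edges(config$atlas)$edge
  regions <- edge_regions(config$grid_shape, edges)
  V <- prod(config$grid_shape)
  n <- nrow(subjects)
  if (is.null(dose)) dose <- stats::setNames(rep(0, n), subjects$id)
  dose_num <- ifelse(is.na(dose[subjects$id]), 0, dose[subjects$id])
  k_vox <- 8
  sigma_strength <- sqrt(config$sigma_subject^2 + config$sigma_voxel^2 / k_vox)
  eff <- stats::setNames(rep(0, length(edges)), edges)
  if (nrow(config$affected_edges))
    eff[config$affected_edges$edge] <- config$affected_edges$effect
  ge <- config$genetic_effect
  is_ha <- subjects$group == "HA"
  with_seed(seed, {
    fa <- matrix(stats::rnorm(n * V, config$baseline_fa, config$sigma_voxel),
                 n, V, dimnames = list(subjects$id, NULL))
    voxel_data <- vector("list", length(edges))
    names(voxel_data) <- edges
    for (e in edges) {
      vox <- regions[[e]]
      sv <- matrix(pmax(stats::rnorm(n * k_vox, config$streamline_mean,
                                     config$streamline_sd), 0.01),
                   n, k_vox, dimnames = list(subjects$id, NULL))
      voxel_data[[e]] <- edge_voxel_data(e, sv, vox, config$grid_shape)
      subj_dev <- stats::rnorm(n, 0, config$sigma_subject)
      shift <- subj_dev + eff[e] * sigma_strength * is_ha
      if (!is.null(ge) && eff[e] != 0) {
        per_allele <- ge$beta + ifelse(is_ha, ge$interaction, 0)
        shift <- shift + per_allele * sigma_strength * dose_num
      }
      fa[, vox] <- fa[, vox] + shift
    }
    fa[fa < 0] <- 0; fa[fa > 1] <- 1
    list(voxel_data = voxel_data, fa = fa, regions = regions,
         sigma_strength = sigma_strength)
  })
}

#' Simulate cognition (MoCA) from the mediated model
#'
#' MoCA = group intercept + c' * dosage + b * mediator + beta_age * age +
#' Gaussian noise, where the mediator is the subject's mean FA over the true
#' planted regions of the affected edges (the a path is realized physically,
#' through the genotype effect on edge FA). Group intercepts follow the
#' cohort's observed means (HA 21.9, HC 25.7) net of the mediator term.
#'
#' @param subjects subject table.
#' @param mediator per-subject mediator values (named by subject id).
#' @param dose per-subject risk-allele dosage.
#' @param params list \code{b}, \code{c_prime}, \code{noise_sd},
#'   \code{beta_age}.
#' @param baseline_fa mediator centring constant.
#' @param seed RNG seed.
#' @return The subject table with a \code{MoCA} column appended.
#' @export
simulate_phenotypes <- function(subjects, mediator, dose, params,
                                baseline_fa = 0.5, seed = NULL) {
  stopifnot(all(subjects$id %in% names(mediator)))
  d <- ifelse(is.na(dose[subjects$id]), 0, dose[subjects$id])
  mu <- ifelse(subjects$group == "HA", 21.9, 25.7)
  with_seed(seed, {
    moca <- mu + params$c_prime * d +
      params$b * (mediator[subjects$id] - baseline_fa) +
      params$beta_age * (subjects$age - 37) +
      stats::rnorm(nrow(subjects), 0, params$noise_sd)
    subjects$MoCA <- round(unname(moca), 1)
    subjects
  })
}

#' Generate a complete synthetic cohort
#'
#' Runs the full generative chain (subjects -> genotypes -> voxel data ->
#' phenotypes) under a single seed and records the planted truth for
#' recovery tests. Bit-identical under a fixed seed and config.
#'
#' @param config a [sim_config()].
#' @return Object of class \code{"cohort"}: \code{subjects} (with MoCA),
#'   \code{genotypes}, \code{voxel_data}, \code{fa}, \code{truth} (planted
#'   affected edges and effects, genetic effect, true regions, the mediator
#'   used, mediation parameters, \code{sigma_strength}), \code{config}.
#' @examples
#' cfg <- sim_config(n_per_group = 6, atlas = reward_atlas()[1:4, ], seed = 7)
#' cohort <- simulate_cohort(cfg)
#' cohort$subjects[1:3, ]
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  subjects <- simulate_subjects(config, seed = config$seed)
  gt <- simulate_genotypes(2 * config$n_per_group, config$snp_specs,
                           config$ld_blocks, seed = config$seed + 2L,
                           missing_rate = config$missing_rate,
                           ids = subjects$id)
  focal <- config$genetic_effect$snp
  dose <- if (!is.null(focal) && focal %in% config$snp_specs$id)
    dosage(gt, focal) else stats::setNames(rep(0, nrow(subjects)), subjects$id)
  vox <- simulate_voxel_data(config, subjects, dose, seed = config$seed + 1L)
  aff <- config$affected_edges$edge
  mediator <- if (length(aff)) {
    vv <- unlist(vox$regions[aff], use.names = FALSE)
    stats::setNames(rowMeans(vox$fa[, vv, drop = FALSE]), subjects$id)
  } else stats::setNames(rep(config$baseline_fa, nrow(subjects)), subjects$id)
  subjects <- simulate_phenotypes(subjects, mediator, dose, config$mediation,
                                  baseline_fa = config$baseline_fa,
                                  seed = config$seed + 3L)
  structure(list(subjects = subjects, genotypes = gt,
                 voxel_data = vox$voxel_data, fa = vox$fa,
                 truth = list(affected_edges = config$affected_edges,
                              genetic_effect = config$genetic_effect,
                              regions = vox$regions, mediator = mediator,
                              mediation = config$mediation,
                              sigma_strength = vox$sigma_strength),
                 config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$subjects), "subjects (",
      sum(x$subjects$group == "HA"), "HA /", sum(x$subjects$group == "HC"),
      "HC ),", length(x$voxel_data), "edges,",
      ncol(x$genotypes$geno), "SNPs\n")
  cat("  planted group effect on", nrow(x$truth$affected_edges), "edge(s);",
      "focal SNP:", x$truth$genetic_effect$snp, "\n")
  invisible(x)
}
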