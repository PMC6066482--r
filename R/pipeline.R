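# End-to-end orchestration: simulate -> build network -> compare edges ->
# genetic association / screen -> mediation, with every threshold and seed
# logged and all interchange files written as headed TSV.

# Small deterministic config fingerprint (polynomial rolling hash over the
# deparsed config, mod 2^31 - 1).
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full reward-connectome analysis pipeline
#'
#' Generates (or accepts) a cohort, builds the FA-weighted network, runs the
#' covariate-adjusted permutation comparison with Bonferroni correction,
#' performs genotype QC, Hardy-Weinberg tests, case-control association,
#' pairwise LD and the additive imaging-genetics screen, and fits the
#' per-group mediation (dosage -> Diff-connection strength -> MoCA). All
#' stage outputs are written as TSV with '#' header lines recording package
#' version, config hash and seed; rerunning with the same config yields
#' byte-identical files.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed); \code{NULL} skips
#'   file output.
#' @param cohort optional pre-generated \code{"cohort"} (skips simulation).
#' @param B_perm permutations for the edge test (default 10000).
#' @param B_boot bootstrap resamples for mediation (default 10000).
#' @param alpha_voxel voxel-level level for streamline regions (default 0.05).
#' @param alpha_fw family-wise level for edge significance (default 0.05;
#'   applied as alpha_fw / n_edges).
#' @param min_call_rate genotype QC threshold (default 0.98).
#' @param region_mode \code{"group"} or \code{"union"} (see
#'   [build_connectivity()]).
#' @return Invisibly, a list with every stage result: \code{cohort},
#'   \code{connectivity}, \code{perm}, \code{threshold}, \code{diff_edges},
#'   \code{subnetworks}, \code{qc}, \code{hwe}, \code{assoc}, \code{ld},
#'   \code{screen}, \code{mediation} (one fit per group).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL, cohort = NULL,
                         B_perm = 10000, B_boot = 10000,
                         alpha_voxel = 0.05, alpha_fw = 0.05,
                         min_call_rate = 0.98,
                         region_mode = c("group", "union")) {
  region_mode <- match.arg(region_mode)
  stopifnot(alpha_voxel > 0, alpha_voxel < 1, alpha_fw > 0, alpha_fw < 1)
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  meta <- list(package = paste0("rewardconn ",
                                as.character(utils::packageVersion("rewardconn"))),
               config_hash = config_hash(config), seed = config$seed)
  log_lines <- c(sprintf("config_hash=%s seed=%d", meta$config_hash, config$seed))
  emit <- function(df, name) if (!is.null(out_dir))
    write_tsv(df, file.path(out_dir, name), meta)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  subjects <- cohort$subjects
  covs <- as.matrix(subjects[, c("age", "cigarettes_per_day")])
  emit(subjects, "subjects.tsv")

  ## -- network construction ------------------------------------------------
  conn <- tryCatch(
    build_connectivity(cohort$voxel_data, cohort$fa, subjects,
                       alpha = alpha_voxel, region_mode = region_mode),
    error = function(e) stop("stage build-network failed: ", conditionMessage(e)))
  log_lines <- c(log_lines,
                 sprintf("build-network: alpha_voxel=%g region_mode=%s edges=%d",
                         alpha_voxel, region_mode, ncol(conn$strengths)))
  if (!is.null(out_dir)) write_strengths_tsv(conn, file.path(out_dir, "strengths.tsv"), meta)

  ## -- edge-wise permutation comparison ------------------------------------
  perm <- tryCatch(
    permutation_test(conn$strengths, subjects$group, covs, B = B_perm,
                     seed = config$seed + 10L),
    error = function(e) stop("stage compare-edges failed: ", conditionMessage(e)))
  thr <- bonferroni_threshold(alpha_fw, ncol(conn$strengths))
  diff_edges <- diff_connections(perm, thr)
  log_lines <- c(log_lines,
                 sprintf("compare-edges: B=%d threshold=%.8f (=%g/%d) n_diff=%d seed=%d",
                         B_perm, thr, alpha_fw, ncol(conn$strengths),
                         length(diff_edges), config$seed + 10L))
  res <- perm$results
  res$significant <- res$p_perm < thr
  emit(res, "edge_results.tsv")
  emit(data.frame(edge = diff_edges, stringsAsFactors = FALSE), "diff_edges.tsv")
  if (!is.null(out_dir)) {
    nodes <- config$atlas$node
    tm <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
    parts <- strsplit(res$edge, "--", fixed = TRUE)
    for (k in seq_len(nrow(res))) {
      tm[parts[[k]][1], parts[[k]][2]] <- res$t[k]
      tm[parts[[k]][2], parts[[k]][1]] <- res$t[k]
    }
    write_matrix_tsv(tm, file.path(out_dir, "t_matrix.tsv"), meta)
  }

  subnet <- subnetwork_means(conn, config$atlas, diff_edges)
  emit(subnet, "subnetworks.tsv")

  ## -- genetics ------------------------------------------------------------
  qc <- call_rate_filter(cohort$genotypes, min_call_rate)
  gt <- qc$table
  log_lines <- c(log_lines,
                 sprintf("qc: min_call_rate=%g dropped=%d", min_call_rate,
                         sum(qc$report$dropped)))
  emit(qc$report, "qc_report.tsv")
  if (!is.null(out_dir)) {
    write_genotypes_tsv(gt, file.path(out_dir, "genotypes.tsv"), meta)
    write_ped_map(gt, file.path(out_dir, "genotypes"), subjects$group)
  }

  hwe_rows <- do.call(rbind, lapply(gt$snps$id, function(s) {
    do.call(rbind, lapply(c("HA", "HC"), function(g) {
      sel <- subjects$group == g
      cnt <- genotype_counts(
        genotype_table(gt$geno[sel, , drop = FALSE], gt$snps), s)
      h <- hwe_chisq(cnt)
      data.frame(snp = s, group = g, n_AA = cnt[1], n_Aa = cnt[2],
                 n_aa = cnt[3], chisq = h$chisq, p = h$p,
                 monomorphic = h$monomorphic, stringsAsFactors = FALSE)
    }))
  }))
  rownames(hwe_rows) <- NULL
  emit(hwe_rows, "hwe.tsv")

  focal <- config$genetic_effect$snp
  assoc <- NULL
  if (!is.null(focal) && focal %in% gt$snps$id) {
    cnt_of <- function(g) genotype_counts(
      genotype_table(gt$geno[subjects$group == g, , drop = FALSE], gt$snps), focal)
    assoc <- tryCatch(case_control_association(cnt_of("HA"), cnt_of("HC")),
                      error = function(e) NULL)
    if (!is.null(assoc))
      emit(data.frame(snp = focal, chisq_genotypic = assoc$chisq_genotypic,
                      p_genotypic = assoc$p_genotypic,
                      chisq_allelic = assoc$chisq_allelic,
                      p_allelic = assoc$p_allelic, or = assoc$or,
                      ci_lower = assoc$ci[1], ci_upper = assoc$ci[2]),
           "assoc.tsv")
  }

  ld <- NULL
  if (length(config$ld_blocks)) {
    bl <- config$ld_blocks[[1]]$snps
    bl <- intersect(bl, gt$snps$id)
    if (length(bl) >= 2) {
      prs <- utils::combn(bl, 2)
      ld <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
        r <- ld_pairwise(gt, prs[1, k], prs[2, k])
        data.frame(snp1 = r$snp1, snp2 = r$snp2, D = r$D, Dprime = r$Dprime,
                   r2 = r$r2, iterations = r$iterations,
                   stringsAsFactors = FALSE)
      }))
      emit(ld, "ld.tsv")
    }
  }

  phenotype <- subnet$Diff
  pheno_name <- "diff_mean"
  if (all(is.na(phenotype))) {   # no Diff edges: fall back to whole-network mean
    phenotype <- rowMeans(conn$strengths)
    pheno_name <- "network_mean"
  }
  screen <- snp_screen(phenotype, gt, subjects$group, covs)
  log_lines <- c(log_lines, sprintf("screen: phenotype=%s snps=%d",
                                    pheno_name, nrow(screen$results)))
  emit(screen$results, "screen.tsv")

  ## -- mediation, per group ------------------------------------------------
  med <- list()
  if (!is.null(focal) && focal %in% gt$snps$id) {
    d <- dosage(gt, focal)
    for (g in c("HC", "HA")) {
      sel <- subjects$group == g & !is.na(d[subjects$id]) & !is.na(phenotype)
      med[[g]] <- tryCatch(
        mediate(d[subjects$id][sel], phenotype[sel], subjects$MoCA[sel],
                covariates = covs[sel, , drop = FALSE], B = B_boot,
                seed = config$seed + 20L + (g == "HA")),
        error = function(e) NULL)
    }
    mrows <- do.call(rbind, lapply(names(med), function(g) {
      f <- med[[g]]
      if (is.null(f)) return(NULL)
      data.frame(group = g, a = f$a, b = f$b, c = f$c, c_prime = f$c_prime,
                 indirect = f$indirect, ci_lower = f$ci[1], ci_upper = f$ci[2],
                 significant = f$significant, B = f$B,
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(mrows)) emit(mrows, "mediation.tsv")
    log_lines <- c(log_lines,
                   sprintf("mediate: B_boot=%d level=0.95 groups=%s",
                           B_boot, paste(names(med), collapse = ",")))
  }

  emit(cohort$truth$affected_edges, "truth_edges.tsv")
  if (!is.null(out_dir))
    writeLines(c(sprintf("# %s: %s", names(meta), unlist(meta)), log_lines),
               file.path(out_dir, "pipeline_log.txt"))

  invisible(list(cohort = cohort, connectivity = conn, perm = perm,
                 threshold = thr, diff_edges = diff_edges,
                 subnetworks = subnet, qc = qc$report, hwe = hwe_rows,
                 assoc = assoc, ld = ld, screen = screen, mediation = med,
                 phenotype = pheno_name, log = log_lines))
}
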