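# Statistical-genetics stage: QC, HWE, case-control association, additive
# imaging-genetics regression with gene-by-group interaction, pairwise LD.

#' Genotype table
#'
#' Subjects x SNPs genotypes, each an unordered biallelic pair coded
#' \code{"A/G"} (order irrelevant) or \code{NA} when missing.
#'
#' @param geno character matrix, subjects in rows (ids as rownames), SNPs in
#'   columns (ids as colnames).
#' @param snps data frame with columns \code{id}, \code{allele1},
#'   \code{allele2} and \code{risk} (the risk allele whose count is the
#'   additive dosage).
#' @return Object of class \code{"genotype_table"}.
#' @export
genotype_table <- function(geno, snps) {
  geno <- as.matrix(geno)
  stopifnot(is.data.frame(snps),
            all(c("id", "allele1", "allele2", "risk") %in% names(snps)),
            ncol(geno) == nrow(snps), !is.null(rownames(geno)))
  colnames(geno) <- snps$id
  for (k in seq_len(nrow(snps))) {
    ok <- c(snps$allele1[k], snps$allele2[k])
    g <- geno[, k]
    alleles <- unlist(strsplit(g[!is.na(g)], "/", fixed = TRUE))
    if (length(alleles) && !all(alleles %in% ok))
      stop("SNP ", snps$id[k], ": allele outside {",
           paste(ok, collapse = ","), "}")
    if (!snps$risk[k] %in% ok)
      stop("SNP ", snps$id[k], ": risk allele not one of its two alleles")
  }
  structure(list(geno = geno, snps = snps), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("Genotype table:", nrow(x$geno), "subjects x", ncol(x$geno), "SNPs\n")
  cat("  call rates:", paste(sprintf("%s=%.3f", x$snps$id, call_rates(x)),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Per-SNP call rates (non-missing fraction)
#' @param table a [genotype_table()].
#' @export
call_rates <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  colMeans(!is.na(table$geno))
}

#' Additive dosage: count of the risk allele (0/1/2) per subject
#'
#' @param table a [genotype_table()].
#' @param snp SNP id.
#' @param allele count this allele instead of the SNP's recorded risk allele.
#' @return Integer vector (NA where the genotype is missing).
#' @export
dosage <- function(table, snp, allele = NULL) {
  stopifnot(inherits(table, "genotype_table"), snp %in% table$snps$id)
  if (is.null(allele)) allele <- table$snps$risk[table$snps$id == snp]
  g <- table$geno[, snp]
  out <- rep(NA_integer_, length(g))
  ok <- !is.na(g)
  out[ok] <- vapply(strsplit(g[ok], "/", fixed = TRUE),
                    function(a) sum(a == allele), integer(1))
  names(out) <- rownames(table$geno)
  out
}

#' Genotype counts (n_AA, n_Aa, n_aa) for a SNP
#'
#' @inheritParams dosage
#' @param ref reference allele A; defaults to the SNP's \code{allele1}.
#' @export
genotype_counts <- function(table, snp, ref = NULL) {
  if (is.null(ref)) ref <- table$snps$allele1[table$snps$id == snp]
  d <- dosage(table, snp, allele = ref)
  c(n_AA = sum(d == 2, na.rm = TRUE), n_Aa = sum(d == 1, na.rm = TRUE),
    n_aa = sum(d == 0, na.rm = TRUE))
}

#' Drop SNPs failing the genotype call-rate filter
#'
#' Removes every SNP whose call rate (non-missing fraction) is at or below
#' \code{min_rate}; the conventional QC keeps SNPs with call rate > 0.98.
#'
#' @param table a [genotype_table()].
#' @param min_rate minimum call rate in (0, 1].
#' @return List with the filtered \code{table} and a \code{report} data frame
#'   (snp, call_rate, dropped).
#' @export
call_rate_filter <- function(table, min_rate = 0.98) {
  stopifnot(min_rate > 0, min_rate <= 1)
  cr <- call_rates(table)
  drop <- cr <= min_rate
  report <- data.frame(snp = table$snps$id, call_rate = unname(cr),
                       dropped = unname(drop), stringsAsFactors = FALSE)
  keep <- which(!drop)
  out <- genotype_table(table$geno[, keep, drop = FALSE],
                        table$snps[keep, , drop = FALSE])
  list(table = out, report = report)
}

#' Hardy-Weinberg equilibrium chi-squared goodness-of-fit test
#'
#' Estimates the allele frequency from the genotype counts, forms the
#' expected HW counts (n p^2, 2 n p q, n q^2) and computes the Pearson
#' chi-squared statistic on 1 df, without continuity correction.
#'
#' @param counts numeric length-3 vector (n_AA, n_Aa, n_aa).
#' @return List with \code{chisq}, \code{df = 1}, \code{p}, \code{freq} (the
#'   A-allele frequency) and \code{monomorphic}; a monomorphic SNP is flagged
#'   and gets no test (\code{chisq}, \code{p} are NA).
#' @examples
#' hwe_chisq(c(202, 511, 319))$p  # ~0.92
#' @export
hwe_chisq <- function(counts) {
  stopifnot(length(counts) == 3, all(counts >= 0), sum(counts) >= 1)
  n <- sum(counts)
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  if (p == 0 || p == 1)
    return(list(chisq = NA_real_, df = 1L, p = NA_real_, freq = unname(p),
                monomorphic = TRUE))
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  x2 <- sum((counts - e)^2 / e)
  list(chisq = unname(x2), df = 1L,
       p = stats::pchisq(unname(x2), 1, lower.tail = FALSE),
       freq = unname(p), monomorphic = FALSE)
}

#' Allele frequencies from genotype counts
#'
#' @param counts numeric length-3 vector (n_AA, n_Aa, n_aa).
#' @return Named vector \code{c(freq_A, freq_a)}; the two sum to 1.
#' @export
allele_frequencies <- function(counts) {
  stopifnot(length(counts) == 3, sum(counts) > 0)
  fa <- (2 * counts[1] + counts[2]) / (2 * sum(counts))
  c(freq_A = unname(fa), freq_a = 1 - unname(fa))
}

#' Case-control genetic association from genotype counts
#'
#' Genotypic Pearson chi-squared on the 2 groups x 3 genotypes table (2 df)
#' and allelic chi-squared on the 2 x 2 allele table with
#' A-count = 2 n_AA + n_Aa (1 df), both without continuity correction. The
#' odds ratio is for allele A, case odds over control odds, with a Woolf
#' (log-scale) 95% CI using z = 1.96.
#'
#' @param case,control numeric length-3 genotype counts (n_AA, n_Aa, n_aa)
#'   for the case (e.g. HA) and control (HC) group.
#' @return Object of class \code{"assoc_result"} with fields
#'   \code{chisq_genotypic}, \code{p_genotypic}, \code{chisq_allelic},
#'   \code{p_allelic}, \code{or}, \code{ci} (length 2), \code{freq} (per-group
#'   A-allele frequencies) and the allele table.
#' @examples
#' case_control_association(c(202, 511, 319), c(688, 1409, 766))
#' @export
case_control_association <- function(case, control) {
  stopifnot(length(case) == 3, length(control) == 3,
            all(case >= 0), all(control >= 0))
  m <- rbind(case = as.numeric(case), control = as.numeric(control))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero marginal in the genotype table; no continuity correction is applied")
  pearson <- function(tab) {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  x2g <- pearson(m)
  al <- rbind(case = c(A = 2 * case[1] + case[2], a = 2 * case[3] + case[2]),
              control = c(A = 2 * control[1] + control[2],
                          a = 2 * control[3] + control[2]))
  if (any(al == 0)) stop("zero allele count; odds ratio undefined")
  x2a <- pearson(al)
  or <- (al[1, 1] / al[1, 2]) / (al[2, 1] / al[2, 2])
  se <- sqrt(sum(1 / al))
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  structure(list(
    chisq_genotypic = x2g, p_genotypic = stats::pchisq(x2g, 2, lower.tail = FALSE),
    chisq_allelic = x2a, p_allelic = stats::pchisq(x2a, 1, lower.tail = FALSE),
    or = unname(or), ci = unname(ci),
    freq = c(case = unname(al[1, 1] / sum(al[1, ])),
             control = unname(al[2, 1] / sum(al[2, ]))),
    allele_table = al, genotype_table = m
  ), class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat("Case-control association (allele A):\n")
  cat(sprintf("  genotypic chi2 = %.2f (df 2), p = %.3g\n",
              x$chisq_genotypic, x$p_genotypic))
  cat(sprintf("  allelic   chi2 = %.2f (df 1), p = %.3g\n",
              x$chisq_allelic, x$p_allelic))
  cat(sprintf("  OR = %.2f, 95%% CI %.2f-%.2f\n", x$or, x$ci[1], x$ci[2]))
  cat(sprintf("  freq(A): case %.2f, control %.2f\n",
              x$freq["case"], x$freq["control"]))
  invisible(x)
}

#' Pairwise linkage disequilibrium by EM haplotype-frequency estimation
#'
#' Estimates the four haplotype frequencies of two biallelic SNPs from
#' unphased genotypes: only the double-heterozygote class is phase-ambiguous
#' and its two configurations are weighted in the E-step by their current
#' relative likelihood. Subjects missing either genotype are excluded
#' pairwise. From the converged frequencies: \code{D = p_AB - p_A p_B};
#' \code{D' = |D| / Dmax} with \code{Dmax = min(p_A q_b, q_a p_B)} for
#' \code{D > 0} and \code{min(p_A p_B, q_a q_b)} for \code{D < 0} (D' = 0 at
#' D = 0); \code{r^2 = D^2 / (p_A q_a p_B q_b)}.
#'
#' @param table a [genotype_table()].
#' @param snp1,snp2 SNP ids.
#' @param tol convergence tolerance on the max haplotype-frequency change.
#' @param max_iter EM iteration cap; non-convergence is an error.
#' @return Object of class \code{"ld_result"}: \code{D}, \code{Dprime},
#'   \code{r2}, \code{iterations}, \code{haplotypes} (named frequencies),
#'   \code{loglik}, \code{n} subjects used.
#' @export
ld_pairwise <- function(table, snp1, snp2, tol = 1e-8, max_iter = 1000) {
  stopifnot(inherits(table, "genotype_table"))
  dA <- dosage(table, snp1, allele = table$snps$allele1[table$snps$id == snp1])
  dB <- dosage(table, snp2, allele = table$snps$allele1[table$snps$id == snp2])
  ok <- !is.na(dA) & !is.na(dB)
  dA <- dA[ok]; dB <- dB[ok]
  n <- length(dA)
  if (n < 1) stop("no subjects with both genotypes")
  pA <- mean(dA) / 2; pB <- mean(dB) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("monomorphic SNP; LD undefined")
  # 3x3 genotype-pair counts, index = dosage + 1
  tab <- matrix(0, 3, 3)
  for (i in seq_len(n)) tab[dA[i] + 1, dB[i] + 1] <- tab[dA[i] + 1, dB[i] + 1] + 1
  # haplotype order: AB, Ab, aB, ab  (A/B = allele1 of each SNP)
  h <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  n_dh <- tab[2, 2]
  # unambiguous haplotype counts contributed by the 8 phase-known classes
  base <- c(AB = 2 * tab[3, 3] + tab[3, 2] + tab[2, 3],
            Ab = 2 * tab[3, 1] + tab[3, 2] + tab[2, 1],
            aB = 2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
            ab = 2 * tab[1, 1] + tab[1, 2] + tab[2, 1])
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- h[1] * h[4] + h[2] * h[3]
    w <- if (denom > 0) h[1] * h[4] / denom else 0.5  # P(AB/ab | double het)
    cnt <- base + n_dh * c(w, 1 - w, 1 - w, w)
    h_new <- cnt / (2 * n)
    delta <- max(abs(h_new - h))
    h <- h_new
    if (delta < tol) break
    if (iter >= max_iter)
      stop("EM did not converge within ", max_iter, " iterations")
  }
  pA <- h[1] + h[2]; pB <- h[1] + h[3]
  D <- h[1] - pA * pB
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else if (D < 0) min(pA * pB, (1 - pA) * (1 - pB))
          else NA_real_
  dprime <- if (is.na(dmax)) 0 else abs(D) / dmax
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  ll <- ld_loglik(h, tab)
  structure(list(snp1 = snp1, snp2 = snp2, D = unname(D),
                 Dprime = unname(dprime), r2 = unname(r2),
                 iterations = iter,
                 haplotypes = c(AB = h[1], Ab = h[2], aB = h[3], ab = h[4]),
                 loglik = ll, n = n),
            class = "ld_result")
}

# Multinomial log-likelihood of the 3x3 genotype-pair table under haplotype
# frequencies h (random union of gametes).
ld_loglik <- function(h, tab) {
  pr <- matrix(0, 3, 3)
  pr[3, 3] <- h[1]^2;            pr[3, 2] <- 2 * h[1] * h[2]
  pr[3, 1] <- h[2]^2;            pr[2, 3] <- 2 * h[1] * h[3]
  pr[2, 2] <- 2 * (h[1] * h[4] + h[2] * h[3])
  pr[2, 1] <- 2 * h[2] * h[4];   pr[1, 3] <- h[3]^2
  pr[1, 2] <- 2 * h[3] * h[4];   pr[1, 1] <- h[4]^2
  sum(tab[tab > 0] * log(pr[tab > 0]))
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("LD %s ~ %s: D = %.4f, D' = %.3f, r2 = %.3f (EM, %d iter, n = %d)\n",
              x$snp1, x$snp2, x$D, x$Dprime, x$r2, x$iterations, x$n))
  invisible(x)
}

#' Additive imaging-genetics screen over candidate SNPs
#'
#' For each SNP, with dosage the 0/1/2 count of the risk allele and a network
#' phenotype (e.g. the mean strength of Diff-connections): the pooled main
#' effect is the dosage p-value from \code{phenotype ~ dosage + covariates};
#' the gene-by-addiction interaction is the Wald p-value of the product term
#' in \code{phenotype ~ dosage + group + dosage:group + covariates}; the
#' within-group columns are per-group fits of
#' \code{phenotype ~ dosage + covariates}.
#'
#' @param phenotype numeric vector, one value per subject.
#' @param table a [genotype_table()] (rows aligned with \code{phenotype}).
#' @param groups two-level grouping vector.
#' @param covariates optional matrix/data frame of covariates.
#' @param snps SNP ids to screen (default: all in the table).
#' @param main_with_group also adjust the pooled main-effect model for group.
#' @return Object of class \code{"screen_result"}: data frame with one row
#'   per SNP and columns \code{snp}, \code{p_main}, \code{p_interaction} and
#'   one within-group p column per group level (NA where a stratum is
#'   monomorphic).
#' @export
snp_screen <- function(phenotype, table, groups, covariates = NULL,
                       snps = NULL, main_with_group = FALSE) {
  stopifnot(inherits(table, "genotype_table"),
            length(phenotype) == nrow(table$geno))
  if (is.null(snps)) snps <- table$snps$id
  g <- as.factor(groups)
  stopifnot(nlevels(g) == 2)
  covs <- if (is.null(covariates)) NULL else as.matrix(covariates)
  p_of <- function(y, X, term) {
    fit <- stats::lm.fit(X, y)
    if (fit$rank < ncol(X)) return(NA_real_)
    rss <- sum(fit$residuals^2)
    df <- length(y) - ncol(X)
    XtXi <- chol2inv(chol(crossprod(X)))
    se <- sqrt(rss / df * XtXi[term, term])
    if (se == 0) return(NA_real_)
    unname(2 * stats::pt(abs(fit$coefficients[term] / se), df,
                         lower.tail = FALSE))
  }
  rows <- lapply(snps, function(s) {
    d <- dosage(table, s)
    ok <- !is.na(d) & !is.na(phenotype)
    y <- phenotype[ok]; dd <- d[ok]; gg <- g[ok]
    cc <- if (is.null(covs)) NULL else covs[ok, , drop = FALSE]
    mono <- stats::var(dd) == 0
    Xmain <- cbind(1, dd)
    if (main_with_group) Xmain <- cbind(Xmain, as.numeric(gg == levels(g)[2]))
    if (!is.null(cc)) Xmain <- cbind(Xmain, cc)
    p_main <- if (mono) NA_real_ else p_of(y, Xmain, 2L)
    gi <- as.numeric(gg == levels(g)[2])
    Xint <- cbind(1, dd, gi, dd * gi)
    if (!is.null(cc)) Xint <- cbind(Xint, cc)
    p_int <- if (mono) NA_real_ else p_of(y, Xint, 4L)
    p_within <- vapply(levels(g), function(lv) {
      sel <- gg == lv
      if (sum(sel) < 4 || stats::var(dd[sel]) == 0) return(NA_real_)
      Xw <- cbind(1, dd[sel])
      if (!is.null(cc)) Xw <- cbind(Xw, cc[sel, , drop = FALSE])
      p_of(y[sel], Xw, 2L)
    }, numeric(1))
    c(p_main = p_main, p_interaction = p_int, p_within)
  })
  out <- data.frame(snp = snps, do.call(rbind, rows),
                    stringsAsFactors = FALSE)
  names(out)[4:5] <- paste0("p_", levels(g))
  rownames(out) <- NULL
  structure(list(results = out, main_with_group = main_with_group),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Imaging-genetics screen (additive model",
      if (x$main_with_group) "+ group in main-effect fit" else "", "):\n")
  print(format(x$results, digits = 3), row.names = FALSE)
  invisible(x)
}
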