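# Covariate-adjusted edge-wise group comparison with a permutation null.

# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Group indicator (1 = case) from a 2-level grouping vector. "HA" is treated
# as the case level when present; otherwise the second factor level.
group_indicator <- function(groups) {
  g <- as.factor(groups)
  if (nlevels(g) != 2) stop("need exactly two groups, got ", nlevels(g))
  case <- if ("HA" %in% levels(g)) "HA" else levels(g)[2]
  as.numeric(g == case)
}

# t statistics for the group coefficient of strength ~ group + covariates,
# computed for every column of Y at once. `ind` is the 0/1 case indicator.
group_t_stats <- function(Y, ind, covariates = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  X <- cbind(intercept = 1, group = ind)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    X <- cbind(X, covariates)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  XtXi <- chol2inv(chol(crossprod(X)))
  XtY <- crossprod(X, Y)
  beta <- XtXi %*% XtY
  rss <- pmax(colSums(Y * Y) - colSums(beta * XtY), 0)
  df <- n - ncol(X)
  if (df < 1) stop("not enough subjects for the model (df < 1)")
  se <- sqrt(rss / df * XtXi[2, 2])
  b <- beta[2, ]
  t <- ifelse(se == 0, ifelse(b == 0, 0, sign(b) * Inf), b / se)
  unname(t)
}

#' Covariate-adjusted two-sample t statistic for edge strength
#'
#' The group-coefficient t statistic from the linear model
#' \code{strength ~ group + covariates}; with no covariates this equals the
#' classical pooled two-sample t. Sign convention: heroin abusers (HA) minus
#' controls, i.e. a strength deficit in HA gives a negative t.
#'
#' @param strengths numeric vector (one edge) or subjects x edges matrix.
#' @param groups two-level grouping vector; the \code{"HA"} level (or the
#'   second factor level) is the case group.
#' @param covariates optional numeric matrix/data frame of nuisance
#'   covariates (e.g. age, cigarettes per day).
#' @return Numeric t statistic(s), one per edge.
#' @export
adjusted_t <- function(strengths, groups, covariates = NULL) {
  ind <- group_indicator(groups)
  if (sum(ind) < 2 || sum(1 - ind) < 2)
    stop("each group needs at least 2 subjects")
  group_t_stats(as.matrix(strengths), ind,
                if (is.null(covariates)) NULL else as.matrix(covariates))
}

#' Permutation test of group differences for every edge
#'
#' Group labels are permuted while covariates stay attached to their
#' subjects; the covariate-adjusted t is recomputed under each relabelling
#' and the two-sided p-value uses the add-one estimator
#' \code{p = (1 + #\{|t*| >= |t_obs|\}) / (B + 1)}, so p is never 0 and never
#' below \code{1/(B+1)}. With \code{exhaustive = TRUE} all distinct label
#' assignments are enumerated instead and p is the exact proportion of
#' assignments (the observed one included) with \code{|t*| >= |t_obs|}.
#'
#' @inheritParams adjusted_t
#' @param B number of random permutations (default 10000).
#' @param seed integer seed for the permutation stream.
#' @param exhaustive enumerate all label assignments (feasible for small n).
#' @return Object of class \code{"edge_perm_test"}: a results data frame
#'   (\code{edge}, \code{t}, \code{p_perm}) plus the permutation settings.
#' @export
permutation_test <- function(strengths, groups, covariates = NULL,
                             B = 10000, seed = NULL, exhaustive = FALSE) {
  Y <- as.matrix(strengths)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("edge", seq_len(ncol(Y)))
  if (anyDuplicated(colnames(Y))) stop("duplicate edge ids")
  ind <- group_indicator(groups)
  if (sum(ind) < 2 || sum(1 - ind) < 2)
    stop("each group needs at least 2 subjects")
  covs <- if (is.null(covariates)) NULL else as.matrix(covariates)
  t_obs <- group_t_stats(Y, ind, covs)
  n <- length(ind)
  if (exhaustive) {
    picks <- utils::combn(n, sum(ind))
    exceed <- integer(ncol(Y))
    # tie tolerance: a relabelling and its complement give |t*| = |t_obs|
    # only up to floating-point rounding
    for (k in seq_len(ncol(picks))) {
      ip <- numeric(n); ip[picks[, k]] <- 1
      exceed <- exceed + (abs(group_t_stats(Y, ip, covs)) >= abs(t_obs) - 1e-8)
    }
    p <- exceed / ncol(picks)
    B_used <- ncol(picks)
  } else {
    if (!is.numeric(B) || B < 1) stop("B must be >= 1")
    B <- as.integer(B)
    exceed <- with_seed(seed, {
      ex <- integer(ncol(Y))
      for (b in seq_len(B)) {
        ip <- sample(ind)
        ex <- ex + (abs(group_t_stats(Y, ip, covs)) >= abs(t_obs) - 1e-8)
      }
      ex
    })
    p <- (1 + exceed) / (B + 1)
    B_used <- B
  }
  structure(list(results = data.frame(edge = colnames(Y), t = t_obs,
                                      p_perm = p, stringsAsFactors = FALSE),
                 B = B_used, seed = seed, exhaustive = exhaustive),
            class = "edge_perm_test")
}

#' @export
print.edge_perm_test <- function(x, ...) {
  cat("Edge-wise permutation test:", nrow(x$results), "edge(s),",
      if (x$exhaustive) "exhaustive," else "random,", x$B, "permutations\n")
  cat("  min p =", format(min(x$results$p_perm)), "\n")
  invisible(x)
}

#' Bonferroni family-wise threshold
#'
#' @param alpha family-wise level in (0, 1).
#' @param m number of tests (edges), >= 1.
#' @return Per-edge threshold \code{alpha / m}; for the 276 edges of the
#'   24-node network at alpha = 0.05 this is 0.00018116 (8 dp).
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1, is.numeric(m), m >= 1)
  alpha / m
}

#' Identify Diff-connections
#'
#' Edges whose permutation p-value falls below the (typically Bonferroni)
#' threshold, ordered by |t| descending with ties broken by edge id.
#'
#' @param x an \code{"edge_perm_test"} or its results data frame.
#' @param threshold per-edge p threshold.
#' @return Character vector of edge ids.
#' @export
diff_connections <- function(x, threshold) {
  res <- if (inherits(x, "edge_perm_test")) x$results else x
  stopifnot(all(c("edge", "t", "p_perm") %in% names(res)))
  if (anyDuplicated(res$edge)) stop("duplicate edge ids in results")
  sig <- res[res$p_perm < threshold, , drop = FALSE]
  sig$edge[order(-abs(sig$t), sig$edge)]
}
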