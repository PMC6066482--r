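#' Simple mediation with bias-corrected bootstrap CI for the indirect effect
#'
#' Fits the three ordinary-least-squares models of simple mediation
#' (exposure x, mediator m, outcome y, shared covariates):
#' \itemize{
#'   \item \code{m ~ x + covs} giving the a path,
#'   \item \code{y ~ x + m + covs} giving b and the direct effect c',
#'   \item \code{y ~ x + covs} giving the total effect c,
#' }
#' with the indirect effect a*b. Because all three are nested least-squares
#' fits on the same covariate set, c = c' + a*b holds exactly. The sampling
#' distribution of a*b is bootstrapped by resampling subjects (rows of
#' x, m, y and covariates jointly) with replacement; the interval is the
#' bias-corrected (BC, no acceleration) percentile interval with
#' \code{z0 = qnorm(} fraction of resampled indirect effects below the point
#' estimate \code{)}. Mediation is flagged significant when the CI excludes
#' zero.
#'
#' @param x exposure (e.g. risk-allele dosage 0/1/2).
#' @param m mediator (e.g. mean Diff-connection strength).
#' @param y outcome (e.g. MoCA score).
#' @param covariates optional numeric matrix/data frame entering both the
#'   mediator and outcome models.
#' @param B bootstrap resamples (default 10000; must be >= 100).
#' @param level confidence level (default 0.95).
#' @param seed integer seed for the resampling stream.
#' @return Object of class \code{"mediation"} with components \code{a},
#'   \code{b}, \code{c}, \code{c_prime}, \code{indirect}, \code{ci},
#'   \code{significant}, \code{B}, \code{level}, \code{seed}, \code{n} and
#'   the bootstrap draws \code{boot}.
#' @examples
#' set.seed(1)
#' x <- rbinom(120, 2, 0.4)
#' m <- 0.5 * x + rnorm(120)
#' y <- 0.8 * m + 0.2 * x + rnorm(120)
#' fit <- mediate(x, m, y, B = 500, seed = 1)
#' fit
#' @export
mediate <- function(x, m, y, covariates = NULL, B = 10000, level = 0.95,
                    seed = NULL) {
  n <- length(x)
  stopifnot(length(m) == n, length(y) == n, B >= 100, level > 0, level < 1)
  covs <- if (is.null(covariates)) NULL else as.matrix(covariates)
  if (!is.null(covs)) stopifnot(nrow(covs) == n)
  est <- fit_mediation(x, m, y, covs)
  Xm <- cbind(1, x, covs)
  Xy <- cbind(1, x, m, covs)
  boot <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      fm <- stats::.lm.fit(Xm[idx, , drop = FALSE], m[idx])
      fy <- stats::.lm.fit(Xy[idx, , drop = FALSE], y[idx])
      fm$coefficients[2] * fy$coefficients[3]
    }, numeric(1))
  })
  ci <- bc_interval(boot, est$indirect, level)
  structure(c(est, list(ci = ci$ci, significant = ci$ci[1] > 0 | ci$ci[2] < 0,
                        boot = boot, B = as.integer(B), level = level,
                        seed = seed, n = n)),
            class = "mediation")
}

#' Mediation path estimates (no bootstrap)
#'
#' @inheritParams mediate
#' @param covariates optional numeric matrix.
#' @return List with \code{a}, \code{b}, \code{c}, \code{c_prime},
#'   \code{indirect}.
#' @export
fit_mediation <- function(x, m, y, covariates = NULL) {
  n <- length(x)
  covs <- if (is.null(covariates)) NULL else as.matrix(covariates)
  Xm <- cbind(1, x, covs)
  Xy <- cbind(1, x, m, covs)
  Xc <- Xm
  if (n <= ncol(Xy)) stop("need more subjects than predictors")
  fit1 <- stats::lm.fit(Xm, m)
  fit2 <- stats::lm.fit(Xy, y)
  fit3 <- stats::lm.fit(Xc, y)
  if (fit1$rank < ncol(Xm) || fit2$rank < ncol(Xy))
    stop("rank-deficient mediation design")
  a <- unname(fit1$coefficients[2])
  b <- unname(fit2$coefficients[3])
  c_prime <- unname(fit2$coefficients[2])
  cc <- unname(fit3$coefficients[2])
  list(a = a, b = b, c = cc, c_prime = c_prime, indirect = a * b)
}

# Bias-corrected percentile interval from bootstrap draws.
bc_interval <- function(boot, point, level) {
  B <- length(boot)
  if (max(boot) == min(boot)) {
    warning("all bootstrap indirect effects identical; degenerate interval")
    return(list(ci = c(boot[1], boot[1]), z0 = 0))
  }
  frac <- mean(boot < point)
  frac <- min(max(frac, 1 / (B + 1)), B / (B + 1))  # guard z0 = +-Inf
  z0 <- stats::qnorm(frac)
  zlo <- stats::qnorm((1 - level) / 2)
  zhi <- stats::qnorm(1 - (1 - level) / 2)
  probs <- stats::pnorm(c(2 * z0 + zlo, 2 * z0 + zhi))
  ci <- unname(stats::quantile(boot, probs))
  list(ci = ci, z0 = z0)
}

#' @export
print.mediation <- function(x, ...) {
  cat("Simple mediation (x -> m -> y), n =", x$n, "\n")
  cat(sprintf("  a = %.4f, b = %.4f, c = %.4f, c' = %.4f\n",
              x$a, x$b, x$c, x$c_prime))
  cat(sprintf("  indirect a*b = %.4f, %d%% BC bootstrap CI [%.4f, %.4f] (B = %d)\n",
              x$indirect, round(100 * x$level), x$ci[1], x$ci[2], x$B))
  cat("  mediation", if (x$significant) "significant" else "not significant",
      "(CI excludes 0:", x$significant, ")\n")
  invisible(x)
}

#' @export
summary.mediation <- function(object, ...) {
  out <- data.frame(
    path = c("a (x -> m)", "b (m -> y | x)", "c (total)", "c' (direct)",
             "a*b (indirect)"),
    estimate = c(object$a, object$b, object$c, object$c_prime, object$indirect)
  )
  out$ci_lower <- c(NA, NA, NA, NA, object$ci[1])
  out$ci_upper <- c(NA, NA, NA, NA, object$ci[2])
  out
}

#' @export
coef.mediation <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c, c_prime = object$c_prime,
    indirect = object$indirect)
}
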