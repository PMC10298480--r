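# Concordance between sampling arms: PCA of posterior mean dosages, symmetric
# Procrustes superimposition, and the study's summary statistics.

#' PCA of genotype probabilities
#'
#' Column-centers the posterior-mean-dosage matrix (no variance scaling,
#' the conventional treatment of genotype dosages) and extracts principal
#' component scores by singular value decomposition. Constant columns are
#' dropped first.
#'
#' @param x A `geno_prob` or a numeric matrix (individuals x variables).
#' @param n_axes Number of axes to return (default 2).
#' @return An object of class `gbs_pca`: `scores` (individuals x axes) and
#'   `explained` (variance fractions for all axes).
#' @export
gbs_pca <- function(x, n_axes = 2L) {
  if (inherits(x, "geno_prob")) x <- x$dosage
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 individuals", call. = FALSE)
  if (ncol(x) < 1L) stop("need at least 1 variable", call. = FALSE)
  keep <- apply(x, 2L, function(v) var(v) > 0)
  if (!any(keep)) stop("all variables are constant", call. = FALSE)
  pr <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  n_axes <- min(n_axes, ncol(pr$x))
  structure(list(scores = pr$x[, seq_len(n_axes), drop = FALSE],
                 explained = pr$sdev^2 / sum(pr$sdev^2),
                 n_axes = n_axes),
            class = "gbs_pca")
}

#' @export
print.gbs_pca <- function(x, ...) {
  cat(sprintf("gbs_pca: %d individuals, %d axes (%.1f%%, %s%% of variance)\n",
              nrow(x$scores), x$n_axes, 100 * x$explained[1L],
              if (x$n_axes > 1L) sprintf("%.1f", 100 * x$explained[2L]) else ""))
  invisible(x)
}

#' Symmetric Procrustes superimposition of two ordinations
#'
#' Both configurations are centered and scaled to unit sum of squares, the
#' optimal rotation comes from the SVD of the cross-product, and the fit is
#' summarized by `m2 = 1 - (sum of singular values)^2` and the Procrustes
#' correlation `R = sqrt(1 - m2)`. R is invariant to translation, rotation
#' and uniform scaling of either configuration, and symmetric in its
#' arguments.
#'
#' @param scores_a,scores_b Score matrices (same individuals, same order,
#'   same axis count), or `gbs_pca` objects.
#' @return An object of class `procrustes_fit`: `R`, `m2`, the `rotation`,
#'   `scale` and `translation` applied to b, the aligned configurations
#'   `xa` / `yb_rot`, and per-individual `residuals`.
#' @export
procrustes_concordance <- function(scores_a, scores_b) {
  if (inherits(scores_a, "gbs_pca")) scores_a <- scores_a$scores
  if (inherits(scores_b, "gbs_pca")) scores_b <- scores_b$scores
  A <- as.matrix(scores_a)
  B <- as.matrix(scores_b)
  if (!all(dim(A) == dim(B)))
    stop("configurations must have the same dimensions", call. = FALSE)
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B))) {
    miss <- c(setdiff(rownames(A), rownames(B)),
              setdiff(rownames(B), rownames(A)))
    stop(sprintf("row mismatch between configurations: %s",
                 paste(unique(c(miss, "order differs")[seq_len(max(1, length(miss)))]),
                       collapse = ", ")), call. = FALSE)
  }
  ca <- colMeans(A)
  cb <- colMeans(B)
  X <- sweep(A, 2L, ca)
  Y <- sweep(B, 2L, cb)
  sx <- sqrt(sum(X^2))
  sy <- sqrt(sum(Y^2))
  if (sx == 0 || sy == 0)
    stop("degenerate configuration (all points identical)", call. = FALSE)
  X <- X / sx
  Y <- Y / sy
  s <- svd(crossprod(X, Y))
  rot <- s$v %*% t(s$u)            # Y %*% rot aligns b onto a
  scl <- sum(s$d)                  # optimal scaling of unit-SS Y
  m2 <- 1 - scl^2
  R <- sqrt(max(0, 1 - m2))
  yrot <- scl * Y %*% rot
  resid <- X - yrot
  structure(list(R = R, m2 = m2, rotation = rot, scale = scl,
                 translation = list(a = ca, b = cb), xa = X, yb_rot = yrot,
                 residuals = resid,
                 resid_len = sqrt(rowSums(resid^2))),
            class = "procrustes_fit")
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat(sprintf("Symmetric Procrustes: R = %.4f (m2 = %.4g) over %d points\n",
              x$R, x$m2, nrow(x$residuals)))
  invisible(x)
}

#' Permutation test for Procrustes concordance
#'
#' Protest-style significance: rows of the second configuration are permuted
#' `n_perm` times and the observed R compared with the permutation
#' distribution.
#'
#' @inheritParams procrustes_concordance
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List with `R`, `p_value` and the permutation `null` distribution.
#' @export
procrustes_permutation <- function(scores_a, scores_b, n_perm = 999L,
                                   seed = 1L) {
  if (inherits(scores_a, "gbs_pca")) scores_a <- scores_a$scores
  if (inherits(scores_b, "gbs_pca")) scores_b <- scores_b$scores
  obs <- procrustes_concordance(scores_a, scores_b)$R
  null <- with_local_rng({
    set.seed(check_count(seed, "seed"))
    B <- as.matrix(scores_b)
    rownames(B) <- NULL
    A <- as.matrix(scores_a)
    rownames(A) <- NULL
    vapply(seq_len(n_perm), function(i)
      procrustes_concordance(A, B[sample.int(nrow(B)), , drop = FALSE])$R,
      numeric(1))
  })
  list(R = obs, p_value = (1 + sum(null >= obs)) / (n_perm + 1), null = null)
}

#' Paired t-test
#'
#' Two-sided paired t-test on the differences, df = n - 1. When the
#' differences have zero variance the statistic is degenerate: identical
#' vectors report t = 0, p = 1 with `flag = "degenerate"`.
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @return List with `t`, `df`, `p` and `flag`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must be paired vectors of length >= 2", call. = FALSE)
  d <- x - y
  if (var(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, df = length(d) - 1L, p = 1,
                                  flag = "degenerate"))
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1L, p = 0,
                flag = "degenerate"))
  }
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, flag = "ok")
}

#' Two-sided p-value of a t statistic
#'
#' @param t Observed t statistic.
#' @param df Degrees of freedom.
#' @return The two-tailed p-value `2 * pt(-|t|, df)`.
#' @export
#' @examples
#' t_two_sided_p(2.171, 13)  # 0.049
t_two_sided_p <- function(t, df) 2 * pt(-abs(t), df)

#' ANCOVA: response ~ covariate + group
#'
#' Ordinary least squares with an intercept, a continuous covariate and a
#' two-level group indicator; per-coefficient t statistics and two-sided
#' p-values on n - 3 residual degrees of freedom.
#'
#' @param response,covariate Numeric vectors.
#' @param group A two-level factor (or coercible).
#' @return An object of class `ancova_fit`: the coefficient table and the
#'   underlying `lm` fit.
#' @export
ancova_fit <- function(response, covariate, group) {
  group <- factor(group)
  if (nlevels(group) != 2L) stop("`group` must have two levels", call. = FALSE)
  if (length(response) < 3L) stop("need at least 3 observations", call. = FALSE)
  fit <- lm(response ~ covariate + group)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop(sprintf("singular design: collinear term %s", bad[1L]), call. = FALSE)
  }
  structure(list(coefficients = summary(fit)$coefficients, model = fit),
            class = "ancova_fit")
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat("ANCOVA (response ~ covariate + group):\n")
  print(x$coefficients)
  invisible(x)
}

arm_stats <- function(arm) {
  st <- arm$filter$snps
  depth <- colSums(st$ref_depth + st$alt_depth) / st$n_ind
  list(arm = arm$arm,
       n_snps = nrow(st$sites),
       mean_depth = if (length(depth)) mean(depth) else NA_real_,
       sd_depth = if (length(depth) > 1L) sd(depth) else NA_real_,
       total_reads = sum(arm$read_totals),
       reference = arm$reference_label)
}

#' Concordance report between two sampling arms
#'
#' Summarizes two completed pipeline arms for the same individuals: per-arm
#' SNP counts, mean +/- SD per-SNP depth (mean per-individual depth at
#' retained sites), read totals and filter ledgers; runs PCA on each arm's
#' posterior mean dosages and the symmetric Procrustes comparison; and gives
#' the verdict against the concordance criterion (default R > 0.95).
#'
#' @param arm_a,arm_b `gbs_arm` objects from [run_arm()] for the same
#'   individuals.
#' @param threshold Concordance criterion on the Procrustes R.
#' @param n_axes PCA axes fed to Procrustes (default 2, matching 2-D
#'   ordination plots).
#' @return An object of class `gbs_concordance`.
#' @export
concordance_report <- function(arm_a, arm_b, threshold = 0.95, n_axes = 2L) {
  stopifnot(inherits(arm_a, "gbs_arm"), inherits(arm_b, "gbs_arm"))
  if (!identical(rownames(arm_a$geno$dosage), rownames(arm_b$geno$dosage)))
    stop("arms cover different individuals", call. = FALSE)
  pca_a <- gbs_pca(arm_a$geno, n_axes)
  pca_b <- gbs_pca(arm_b$geno, n_axes)
  pf <- procrustes_concordance(pca_a, pca_b)
  structure(list(arms = list(a = arm_stats(arm_a), b = arm_stats(arm_b)),
                 ledgers = list(a = arm_a$filter$ledger,
                                b = arm_b$filter$ledger),
                 pca = list(a = pca_a, b = pca_b),
                 procrustes = pf, R = pf$R, threshold = threshold,
                 concordant = pf$R >= threshold),
            class = "gbs_concordance")
}

#' @export
print.gbs_concordance <- function(x, ...) {
  a <- x$arms$a; b <- x$arms$b
  cat("GBS sampling-method concordance\n")
  cat(sprintf("  arm %-8s (%s ref): %5d SNPs, per-SNP depth %.2f +/- %.2f, %d reads\n",
              a$arm, a$reference, a$n_snps, a$mean_depth, a$sd_depth,
              a$total_reads))
  cat(sprintf("  arm %-8s (%s ref): %5d SNPs, per-SNP depth %.2f +/- %.2f, %d reads\n",
              b$arm, b$reference, b$n_snps, b$mean_depth, b$sd_depth,
              b$total_reads))
  cat(sprintf("  Procrustes R = %.4f (criterion > %.2f): %s\n", x$R,
              x$threshold,
              if (x$concordant) "concordant" else "NOT concordant"))
  invisible(x)
}

#' Plot paired ordinations with residual arrows
#'
#' Draws both aligned configurations; arrows run from each individual's
#' position in arm A's ordination to its position in arm B's (rotated)
#' ordination, so arrow length shows how much an individual's placement
#' depends on the sampling method.
#'
#' @param x A `gbs_concordance`.
#' @param ... Passed to [plot()].
#' @return The input, invisibly.
#' @export
plot.gbs_concordance <- function(x, ...) {
  p <- x$procrustes
  rng <- range(rbind(p$xa, p$yb_rot))
  plot(p$xa, xlim = rng, ylim = rng, pch = 1,
       xlab = "Axis 1", ylab = "Axis 2",
       main = sprintf("Procrustes R = %.3f", x$R), ...)
  graphics::points(p$yb_rot, pch = 2, col = "red")
  graphics::arrows(p$xa[, 1L], p$xa[, 2L], p$yb_rot[, 1L], p$yb_rot[, 2L],
                   length = 0.06, col = "grey40")
  invisible(x)
}
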