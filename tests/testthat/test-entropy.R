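noiseless_gl <- function(dosages, L = length(dosages)) {
  # one site per column of a dosage matrix; likelihood 1 on the true genotype
  g <- array(0, dim = c(nrow(dosages), ncol(dosages), 3))
  for (k in 0:2) g[, , k + 1][dosages == k] <- 1
  g
}

test_that("mcmc_config validates and exposes the heavyweight preset", {
  expect_error(mcmc_config(burn_in = 100, iterations = 50), "burn_in")
  expect_error(mcmc_config(thin = 0), "thin")
  pp <- mcmc_config(preset = "study")
  expect_equal(pp$iterations, 50000L)
  expect_equal(pp$burn_in, 5000L)
  expect_equal(pp$thin, 10L)
  expect_equal(mcmc_config()$iterations, 5000L)
})

test_that("noiseless likelihoods pin the genotype posterior regardless of chain", {
  set.seed(31)
  dos <- matrix(sample(0:2, 6 * 10, replace = TRUE), 6, 10)
  fit <- gibbs_admixture(noiseless_gl(dos),
                         mcmc_config(iterations = 400, burn_in = 50), seed = 2)
  for (ch in fit$chains)
    expect_true(all(abs(apply(ch$gprob, c(1, 2), which.max) - 1 - dos) == 0))
  gp <- average_genotype_probs(fit)
  expect_true(all(gp$prob[cbind(as.vector(row(dos)), as.vector(col(dos)),
                                as.vector(dos) + 1)] > 0.999))
  expect_equal(unname(gp$dosage), dos, tolerance = 1e-3)
})

test_that("probability triplets and admixture rows normalize exactly", {
  set.seed(37)
  gl <- array(runif(8 * 12 * 3, 0.1, 1), dim = c(8, 12, 3))
  fit <- gibbs_admixture(gl, mcmc_config(iterations = 300, burn_in = 50),
                         seed = 4)
  gp <- average_genotype_probs(fit, override = TRUE)
  expect_true(all(abs(apply(gp$prob, c(1, 2), sum) - 1) < 1e-9))
  expect_true(all(abs(rowSums(gp$q) - 1) < 1e-9))
  expect_true(all(gp$dosage >= 0 & gp$dosage <= 2))
})

test_that("k = 1 posterior mean allele frequency matches the Beta closed form", {
  # noiseless genotypes at one site: p | data ~ Beta(1 + alt, 1 + ref copies)
  dos <- matrix(c(0, 1, 1, 2, 2, 2), ncol = 1)
  nalt <- sum(dos)                     # 8 of 12 copies
  fit <- gibbs_admixture(noiseless_gl(dos),
                         mcmc_config(k = 1, iterations = 6000, burn_in = 500),
                         seed = 6)
  pbar <- mean(unlist(lapply(fit$chains, function(ch) ch$p_samples)))
  expect_equal(pbar, (1 + nalt) / (2 + 2 * nrow(dos)), tolerance = 0.02)
  # q degenerates at 1
  expect_true(all(unlist(lapply(fit$chains, `[[`, "q_samples")) == 1))
})

test_that("credible intervals for the allele frequency are calibrated", {
  # f = 0.3, n = 50, depth 20: the 95% interval should cover the realized
  # sample frequency in most replicates
  set.seed(41)
  hits <- 0L
  for (rep in 1:20) {
    g <- rbinom(50, 2, 0.3)
    rd <- rbinom(50, 20, 1 - g / 2 * 0.98 - 0.01)
    ad <- 20 - rd
    gl <- genotype_likelihood(rd, ad, 0.01)
    gl <- array(gl / apply(gl, 1, max), dim = c(50, 1, 3))
    fit <- gibbs_admixture(gl, mcmc_config(k = 1, chains = 1,
                                           iterations = 1500, burn_in = 200),
                           seed = 100 + rep)
    ps <- fit$chains[[1]]$p_samples[, 1]
    ci <- quantile(ps, c(0.025, 0.975))
    f_real <- mean(g) / 2
    if (f_real >= ci[1] && f_real <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("Gelman-Rubin matches hand computation and flags degeneracy", {
  # identical chains: B = 0, so Rhat = sqrt((n-1)/n) -> 1 as n grows
  expect_equal(as.numeric(gelman_rubin(list(c(1, 2, 3, 4), c(1, 2, 3, 4)))),
               sqrt(3 / 4), tolerance = 1e-12)
  long <- list(sin(1:500), sin(1:500))
  expect_equal(as.numeric(gelman_rubin(long)), 1, tolerance = 0.01)
  # B = 4 * var(c(2.5, 102.5)) = 20000, W = 5/3:
  # Rhat = sqrt((0.75 * W + 5000) / W) = 54.7791
  r <- gelman_rubin(list(c(1, 2, 3, 4), c(101, 102, 103, 104)))
  expect_equal(as.numeric(r), sqrt(((3 / 4) * (5 / 3) + 5000) / (5 / 3)),
               tolerance = 1e-9)
  expect_gt(as.numeric(r), 50)
  d <- gelman_rubin(list(rep(2, 5), rep(2, 5)))
  expect_equal(as.numeric(d), 1)
  expect_true(attr(d, "degenerate"))
  # two long chains from the same distribution converge below 1.1
  set.seed(43)
  r2 <- gelman_rubin(list(rnorm(400), rnorm(400)))
  expect_lt(as.numeric(r2), 1.1)
  expect_error(gelman_rubin(list(1:5)), "2 chains")
})

test_that("averaging identical chains is the identity; triplet averaging is exact", {
  set.seed(47)
  gl <- array(runif(5 * 6 * 3, 0.2, 1), dim = c(5, 6, 3))
  cfg <- mcmc_config(iterations = 300, burn_in = 50, chains = 2)
  fit <- gibbs_admixture(gl, cfg, seed = 9)
  # same seed per chain -> identical chains -> average equals either chain
  fit$chains[[2]] <- fit$chains[[1]]
  gp <- average_genotype_probs(fit)
  expect_equal(gp$prob, fit$chains[[1]]$gprob)
  # direct triplet arithmetic
  fit2 <- fit
  fit2$chains[[1]]$gprob[1, 1, ] <- c(1, 0, 0)
  fit2$chains[[2]]$gprob[1, 1, ] <- c(0, 1, 0)
  gp2 <- average_genotype_probs(fit2)
  expect_equal(unname(gp2$prob[1, 1, ]), c(0.5, 0.5, 0))
})

test_that("label switching leaves genotype probabilities invariant", {
  set.seed(53)
  gl <- array(runif(6 * 8 * 3, 0.1, 1), dim = c(6, 8, 3))
  fit <- gibbs_admixture(gl, mcmc_config(iterations = 400, burn_in = 100),
                         seed = 11)
  # permute population labels of chain 2 by hand
  k <- 2; L <- fit$L; n <- fit$n
  sw <- fit
  ch <- sw$chains[[2]]
  ch$p_samples <- ch$p_samples[, c((L + 1):(2 * L), 1:L)]
  ch$p_mean <- ch$p_mean[2:1, ]
  ch$q_samples <- ch$q_samples[, as.vector(rbind(seq(2, 2 * n, 2),
                                                 seq(1, 2 * n, 2)))]
  sw$chains[[2]] <- ch
  gp <- average_genotype_probs(fit, override = TRUE)
  gp_sw <- average_genotype_probs(sw, override = TRUE)
  expect_equal(gp_sw$prob, gp$prob)
  # q is re-aligned before averaging, so it matches too
  expect_equal(gp_sw$q, gp$q, tolerance = 1e-12)
})

test_that("convergence failure is reported with offending parameters", {
  set.seed(59)
  gl <- array(runif(4 * 5 * 3, 0.1, 1), dim = c(4, 5, 3))
  fit <- gibbs_admixture(gl, mcmc_config(iterations = 300, burn_in = 50),
                         seed = 13)
  # sabotage one chain's p samples to force R-hat failure
  fit$chains[[2]]$p_samples <- fit$chains[[2]]$p_samples + 5
  fit$chains[[2]]$p_mean <- fit$chains[[2]]$p_mean + 5
  expect_error(average_genotype_probs(fit), "R-hat")
  expect_s3_class(suppressWarnings(average_genotype_probs(fit, override = TRUE)),
                  "geno_prob")
})

test_that("posterior-mode genotypes recover simulated truth at depth 10", {
  set.seed(61)
  n <- 14; L <- 60
  f <- runif(L, 0.1, 0.5)
  dos <- matrix(rbinom(n * L, 2, rep(f, each = n)), n, L)
  p_alt <- dos / 2 * 0.98 + 0.01
  ad <- matrix(rbinom(n * L, 10, as.vector(p_alt)), n, L)
  rd <- 10 - ad
  gl <- genotype_likelihood(as.vector(rd), as.vector(ad), 0.01)
  gl <- array(gl / apply(gl, 1, max), dim = c(n, L, 3))
  fit <- gibbs_admixture(gl, mcmc_config(iterations = 1500, burn_in = 200),
                         seed = 17)
  gp <- average_genotype_probs(fit, override = TRUE)
  # chains agree on the label-invariant dosages even where q R-hat is noisy
  expect_lt(gp$dosage_agreement$max_abs_diff, 0.2)
  mode <- apply(gp$prob, c(1, 2), which.max) - 1
  expect_gte(mean(mode == dos), 0.98)
})

test_that("zero-depth cells shrink to the admixture-weighted prior, not a fixed call", {
  # site 1 has data only for individuals 1-10 (alt common); individuals
  # 11-12 are flat there and should show the population-informed prior
  n <- 12
  rd <- matrix(5L, n, 4); ad <- matrix(5L, n, 4)
  rd[, 1] <- c(rep(0L, 10), 0L, 0L); ad[, 1] <- c(rep(10L, 10), 0L, 0L)
  gl <- genotype_likelihood(as.vector(rd), as.vector(ad), 0.01)
  gl <- array(gl / apply(gl, 1, max), dim = c(n, 4, 3))
  fit <- gibbs_admixture(gl, mcmc_config(iterations = 1000, burn_in = 200),
                         seed = 19)
  gp <- average_genotype_probs(fit, override = TRUE)
  # alt allele is at high frequency -> flat cells lean toward hom-alt
  expect_gt(gp$dosage[11, 1], 1.2)
  expect_lt(max(gp$prob[11, 1, ]), 0.999)  # genuinely uncertain, not a call
})
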