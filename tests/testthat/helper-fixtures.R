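# Fixtures and independent oracles used across the suite. Everything is
# built in code; the oracles deliberately use a different route than the
# implementation they check.

rand_seq <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_at <- function(seq, pos, base = NULL) {
  for (i in seq_along(pos)) {
    cur <- substr(seq, pos[i], pos[i])
    nb <- if (is.null(base)) setdiff(c("A", "C", "G", "T"), cur)[1L] else base[i]
    substr(seq, pos[i], pos[i]) <- nb
  }
  seq
}

# snp_table built directly from depth matrices (individuals x sites)
make_snp_table <- function(ref_depth, alt_depth,
                           contig_id = sprintf("tigA%d", seq_len(ncol(ref_depth))),
                           pos = rep(10L, ncol(ref_depth)),
                           mq = rep(60, ncol(ref_depth)),
                           biallelic = rep(TRUE, ncol(ref_depth)),
                           bq_ref = NULL, bq_alt = NULL,
                           mq_ref = NULL, mq_alt = NULL) {
  L <- ncol(ref_depth)
  n <- nrow(ref_depth)
  sites <- data.frame(contig_id = contig_id, pos = pos,
                      ref = rep("A", L), alt = rep("C", L),
                      biallelic = biallelic, mq = mq,
                      stringsAsFactors = FALSE)
  mk <- function(given, depth, val)
    if (!is.null(given)) given
    else lapply(colSums(depth), function(d) rep(val, d))
  structure(list(sites = sites,
                 ref_depth = ref_depth, alt_depth = alt_depth,
                 bq_ref = mk(bq_ref, ref_depth, 38),
                 bq_alt = mk(bq_alt, alt_depth, 38),
                 mq_ref = mk(mq_ref, ref_depth, 60),
                 mq_alt = mk(mq_alt, alt_depth, 60),
                 sample_id = sprintf("s%02d", seq_len(n)), n_ind = n),
            class = "snp_table")
}

write_tmp_fastq <- function(seq, qual = strrep("I", nchar(seq)),
                            id = sprintf("r%03d", seq_along(seq))) {
  f <- tempfile(fileext = ".fastq")
  lines <- character(0)
  if (length(seq))
    lines <- as.vector(rbind(paste0("@", id), seq, paste0("+", id), qual))
  writeLines(lines, f)
  f
}

# --- oracles ---------------------------------------------------------------

# matches / min-length identity, brute force over every ungapped offset
oracle_identity <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- 0
  for (off in -(lb - 1):(la - 1)) {
    sa <- max(0L, off); sb <- max(0L, -off)
    n <- min(la - sa, lb - sb)
    if (n <= 0) next
    best <- max(best, sum(av[sa + 1:n] == bv[sb + 1:n]))
  }
  best / min(la, lb)
}

# identity of a full read slid inside a longer sequence
oracle_containment_identity <- function(read, host) {
  lr <- nchar(read); lh <- nchar(host)
  rv <- strsplit(read, "")[[1]]; hv <- strsplit(host, "")[[1]]
  if (lh < lr) return(0)
  best <- 0
  for (off in 0:(lh - lr))
    best <- max(best, sum(rv == hv[off + 1:lr]))
  best / lr
}

# exact permutation moments of the rank-sum U statistic (small groups)
oracle_mw_z <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  u_of <- function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2
  all_ix <- utils::combn(N, n1)
  us <- apply(all_ix, 2, u_of)
  mu <- mean(us)
  sigma <- sqrt(mean((us - mu)^2))   # population SD of the exact null
  (u_of(seq_len(n1)) - mu) / sigma
}

# PCA scores via eigen-decomposition of the covariance (independent route)
oracle_pca_scores <- function(X, k = 2) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)
  (Xc %*% ev$vectors)[, seq_len(k), drop = FALSE]
}

# symmetric Procrustes R by numeric minimization over rotation angle,
# reflection and scale (2-D configurations only)
oracle_procrustes_R <- function(A, B) {
  cs <- function(M) {
    M <- sweep(M, 2, colMeans(M))
    M / sqrt(sum(M^2))
  }
  X <- cs(A); Y <- cs(B)
  ssfun <- function(theta, s, refl) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    if (refl) R <- R %*% diag(c(1, -1))
    sum((X - s * Y %*% R)^2)
  }
  best <- Inf
  for (refl in c(FALSE, TRUE)) {
    o <- optim(c(0, 1), function(p) ssfun(p[1], p[2], refl),
               method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
    for (th0 in seq(0, 2 * pi, length.out = 13)[-13]) {
      o2 <- optim(c(th0, 1), function(p) ssfun(p[1], p[2], refl),
                  method = "Nelder-Mead",
                  control = list(reltol = 1e-14, maxit = 5000))
      if (o2$value < o$value) o <- o2
    }
    best <- min(best, o$value)
  }
  sqrt(max(0, 1 - best))
}

# allele-frequency log-likelihood for the grid-search oracle
oracle_freq_loglik <- function(gl, f) {
  # gl: n x 3 linear likelihoods
  p <- cbind((1 - f)^2, 2 * f * (1 - f), f^2)
  sum(log(gl %*% t(p)))
}
oracle_freq_grid <- function(gl, step = 1e-5) {
  fs <- seq(step, 1 - step, by = step)
  ll <- vapply(fs, function(f)
    sum(log(gl[, 1] * (1 - f)^2 + gl[, 2] * 2 * f * (1 - f) + gl[, 3] * f^2)),
    numeric(1))
  fs[which.max(ll)]
}

# small pipeline settings used by several end-to-end tests
small_config <- function(seed = 1L, n_loci = 250L)
  sim_config(n_individuals = 8L, n_loci = n_loci, site_sizes = c(4L, 4L),
             seed = seed)
small_mcmc <- function() mcmc_config(iterations = 800L, burn_in = 100L)
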