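test_that("genotype likelihood matches closed forms and limits", {
  # near-zero error: hom-ref likelihood 1, het 2^-5, hom-alt ~ 0
  gl <- genotype_likelihood(5, 0, error_rate = 1e-9)
  expect_equal(unname(gl[1, "g0"]), 1, tolerance = 1e-6)
  expect_equal(unname(gl[1, "g1"]), 2^-5, tolerance = 1e-9)
  expect_equal(unname(gl[1, "g2"]), 0, tolerance = 1e-12)
  # (1 ref, 1 alt, e = 0.01): closed-form products
  gl2 <- genotype_likelihood(1, 1, error_rate = 0.01)
  expect_equal(unname(gl2[1, ]), c(0.99 * 0.01, 0.25, 0.99 * 0.01))
  # normalized with a uniform prior: P(het) = 0.25 / (0.25 + 2 * 0.0099)
  expect_equal(unname(gl2[1, "g1"] / sum(gl2[1, ])), 0.9266123,
               tolerance = 1e-6)
  expect_error(genotype_likelihood(1, 1, error_rate = 0.7), "error_rate")
  expect_error(genotype_likelihood(-1, 0), "non-negative")
})

test_that("GL symmetry: swapping depths reverses the triplet", {
  for (d in list(c(3, 1), c(0, 7), c(2, 2))) {
    a <- genotype_likelihood(d[1], d[2], 0.01)
    b <- genotype_likelihood(d[2], d[1], 0.01)
    expect_equal(unname(a[1, ]), unname(rev(b[1, ])))
  }
})

test_that("zero-depth cells give flat normalized triplets", {
  st <- make_snp_table(matrix(c(0L, 5L), 2, 1), matrix(c(0L, 0L), 2, 1))
  gl <- gl_array(st)
  expect_equal(unname(gl[1, 1, ]), c(1, 1, 1))
})

test_that("EM allele frequency matches counting and grid-search oracles", {
  # 14 noiseless individuals with dosages summing to 14 -> f = 0.5
  dos <- c(rep(0, 4), rep(1, 6), rep(2, 4))
  gl <- t(vapply(dos, function(g) {
    v <- c(0, 0, 0); v[g + 1] <- 1; v
  }, numeric(3)))
  f <- estimate_allele_freq(gl)
  expect_equal(as.numeric(f), 0.5, tolerance = 1e-8)
  # random small instances vs grid search
  set.seed(19)
  for (rep in 1:5) {
    rd <- rpois(8, 4)
    ad <- rpois(8, 2)
    g <- genotype_likelihood(rd, ad, 0.01)
    g <- g / apply(g, 1, max)
    f_em <- as.numeric(estimate_allele_freq(g))
    f_grid <- oracle_freq_grid(g)
    expect_lt(abs(f_em - f_grid), 1e-4)
  }
})

test_that("EM is monotone in likelihood and flags all-flat input", {
  set.seed(23)
  g <- genotype_likelihood(rpois(10, 3), rpois(10, 3), 0.01)
  g <- g / apply(g, 1, max)
  # trace the objective along EM iterates
  f <- 0.5
  ll_prev <- -Inf
  for (i in 1:50) {
    p <- c((1 - f)^2, 2 * f * (1 - f), f^2)
    w <- sweep(g, 2, p, `*`)
    ll <- sum(log(rowSums(w)))
    expect_gte(ll, ll_prev - 1e-12)
    ll_prev <- ll
    post <- w / rowSums(w)
    f <- sum(post[, 2] + 2 * post[, 3]) / (2 * nrow(g))
  }
  flat <- matrix(1, 6, 3)
  f0 <- estimate_allele_freq(flat)
  expect_equal(as.numeric(f0), 0.5)
  expect_true(attr(f0, "no_data"))
  # hom-ref at depth: frequency goes to ~0
  hom <- genotype_likelihood(rep(20, 6), rep(0, 6), 0.01)
  expect_lt(as.numeric(estimate_allele_freq(hom / apply(hom, 1, max))), 1e-3)
})

test_that("mapper handles unique hits, ambiguity ties and identity floor", {
  set.seed(51)
  contigs <- greedy_cluster(vapply(1:3, function(i) rand_seq(85),
                                   character(1)))
  csq <- contigs$contigs$seq
  srs <- structure(list(sample_id = "s1",
                        seq = c(substr(csq[1], 1, 84),      # unique exact
                                mutate_at(csq[2], 1:20)),   # 20 mism: < 0.9
                        qual = strrep("I", c(84, 85))),
                   class = "sample_read_set")
  aln <- map_reads(srs, contigs)
  expect_equal(aln$contig[1], 1L)
  expect_equal(aln$mapq[1], 60L)
  expect_equal(aln$contig[2], 0L)
  # a read equally similar to two contigs is left unmapped
  twin <- greedy_cluster(c(csq[1], mutate_at(csq[1], c(10, 20))),
                         identity_threshold = 0.99)
  expect_equal(nrow(twin$contigs), 2L)
  mid <- mutate_at(csq[1], 10)  # 1 mismatch to each twin
  srs2 <- structure(list(sample_id = "s1", seq = mid, qual = strrep("I", 85)),
                    class = "sample_read_set")
  expect_equal(map_reads(srs2, twin)$contig, 0L)
})

test_that("mapper assignments match a brute-force all-contigs scan", {
  set.seed(57)
  contigs <- greedy_cluster(vapply(1:3, function(i) rand_seq(85),
                                   character(1)))
  csq <- contigs$contigs$seq
  reads <- vapply(1:20, function(i) {
    src <- csq[sample(3, 1)]
    mutate_at(src, sample(85, sample(0:4, 1)))
  }, character(1))
  srs <- structure(list(sample_id = "s1", seq = reads,
                        qual = strrep("I", nchar(reads))),
                   class = "sample_read_set")
  aln <- map_reads(srs, contigs, min_identity = 0.9)
  for (i in seq_along(reads)) {
    ident <- vapply(csq, oracle_identity, numeric(1), b = reads[i])
    best <- max(ident)
    expected <- if (best < 0.9 || sum(ident == best) > 1) 0L
                else as.integer(which.max(ident))
    expect_equal(aln$contig[i], expected, info = paste("read", i))
  }
})

test_that("candidate sites recover planted variants with correct depths", {
  # one contig, two individuals: ind1 hom-ref, ind2 hom-alt at position 5
  ctg <- rand_seq(84, seed = 61)
  alt <- mutate_at(ctg, 5, "T")
  ctg <- mutate_at(ctg, 5, "A")
  contigs <- greedy_cluster(c(ctg))
  samples <- list(
    structure(list(sample_id = "i1", seq = rep(ctg, 4),
                   qual = rep(strrep("I", 84), 4)), class = "sample_read_set"),
    structure(list(sample_id = "i2", seq = rep(alt, 3),
                   qual = rep(strrep("5", 84), 3)), class = "sample_read_set"))
  aln <- map_reads(samples, contigs)
  st <- call_variant_sites(aln)
  expect_equal(nrow(st$sites), 1L)
  expect_equal(st$sites$pos, 5L)
  expect_equal(st$sites$ref, "A")   # major allele (4 > 3)
  expect_equal(st$sites$alt, "T")
  expect_equal(unname(st$ref_depth[, 1]), c(4L, 0L))
  expect_equal(unname(st$alt_depth[, 1]), c(0L, 3L))
  # pooled quality lists align with depths ('I' = 40, '5' = 20)
  expect_equal(st$bq_ref[[1]], rep(40L, 4))
  expect_equal(st$bq_alt[[1]], rep(20L, 3))
  expect_equal(st$mq_ref[[1]], rep(60L, 4))
})

test_that("VCF output is valid and round-trips through vcfR", {
  skip_if_not_installed("vcfR")
  set.seed(71)
  st <- make_snp_table(matrix(rpois(12, 5), 3, 4), matrix(rpois(12, 2), 3, 4))
  f <- tempfile(fileext = ".vcf")
  write_vcf(st, f)
  v <- suppressWarnings(vcfR::read.vcfR(f, verbose = FALSE))
  expect_equal(nrow(v@fix), 4L)
  ad <- vcfR::extract.gt(v, "AD")
  rd <- apply(ad, c(1, 2), function(x) as.integer(strsplit(x, ",")[[1]][1]))
  expect_equal(unname(t(rd)), unname(st$ref_depth))
})
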