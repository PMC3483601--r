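nb_matrix <- function(n_genes, samples, mu = 100, alpha = 0.1) {
  m <- matrix(rnbinom(n_genes * length(samples), mu = mu,
                      size = if (alpha > 0) 1 / alpha else Inf),
              nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)), samples))
  if (alpha == 0) m[] <- rpois(length(m), mu)
  m
}

std_design <- function() {
  contrast_design(c("a1", "a2"), c("b1", "b2"), paste0("c", 1:8))
}
std_samples <- c("a1", "a2", "b1", "b2", paste0("c", 1:8))

test_that("size factors follow the median-of-ratios closed forms", {
  set.seed(301)
  m <- nb_matrix(50, c("s1", "s2", "s3"))
  m <- m + 1L  # all-positive
  expect_equal(unname(size_factors(cbind(m[, 1], m[, 1], m[, 1]))),
               rep(1, 3))
  two <- cbind(a = m[, 1], b = 2L * m[, 1])
  expect_equal(unname(size_factors(two)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  # all-zero rows are ignored
  with_zero <- rbind(m, zero = 0L)
  expect_equal(size_factors(with_zero), size_factors(m))
  expect_error(size_factors(rbind(c(0L, 1L), c(1L, 0L))), "all-positive")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(302)
  m <- nb_matrix(100, sprintf("s%d", 1:6), mu = 200) + 1L
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("dispersion estimation recovers the simulated parameter", {
  set.seed(303)
  m <- nb_matrix(200, sprintf("r%02d", 1:10), mu = 500, alpha = 0.2)
  design <- contrast_design(sprintf("r%02d", 1:5), sprintf("r%02d", 6:10))
  disp <- estimate_dispersions(m, design)
  expect_gt(median(disp$final), 0.1)
  expect_lt(median(disp$final), 0.4)
  # sharing mode "maximum" dominates the fitted trend everywhere
  expect_true(all(disp$final >= disp$fitted - 1e-12))
  expect_true(all(disp$final >= 0))
})

test_that("Poisson data yields near-zero gene-wise dispersions", {
  set.seed(304)
  m <- nb_matrix(200, sprintf("r%02d", 1:10), mu = 1000, alpha = 0)
  design <- contrast_design(sprintf("r%02d", 1:5), sprintf("r%02d", 6:10))
  disp <- estimate_dispersions(m, design)
  expect_lte(median(disp$genewise), 0.05)
})

test_that("dispersion estimation demands replicated groups", {
  m <- nb_matrix(10, c("a", "b"))
  design <- contrast_design("a", "b")
  expect_error(estimate_dispersions(m, design), "reference controls")
})

test_that("the exact test is symmetric, calibrated at the Poisson limit", {
  # balanced totals with equal size-factor sums: the observed split is the
  # most probable one, so p = 1
  expect_equal(nb_exact_test(c(10L, 10L), c(12L, 8L), c(1, 1), c(1, 1),
                             alpha = 0.1), 1)
  # alpha -> 0 with equal size factors reduces to the exact binomial test
  set.seed(305)
  for (i in 1:20) {
    ka <- sample(0:30, 1); kb <- sample(0:30, 1)
    p_nb <- nb_exact_test(c(ka), c(kb), 1, 1, alpha = 0)
    p_binom <- oracle_binom_half(ka, ka + kb)
    expect_equal(p_nb, p_binom, tolerance = 1e-6)
  }
  # an extreme split is significant even under overdispersion
  expect_lt(nb_exact_test(c(0L, 0L), c(50L, 50L), c(1, 1), c(1, 1),
                          alpha = 0.1), 0.01)
  # no information -> p = 1 by convention
  expect_equal(nb_exact_test(0L, 0L, 1, 1, alpha = 0.1), 1)
})

test_that("BH adjustment equals the brute-force step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(306)
  for (i in 1:1000) {
    p <- runif(sample(1:30, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("identical conditions give unit fold changes and null p-values", {
  set.seed(307)
  base <- nb_matrix(50, c("x1", "x2"), mu = 200) + 1L
  m <- cbind(a1 = base[, 1], a2 = base[, 2],
             b1 = base[, 1], b2 = base[, 2],
             c1 = base[, 1], c2 = base[, 2])
  design <- contrast_design(c("a1", "a2"), c("b1", "b2"), c("c1", "c2"))
  de <- de_table(m, design)
  expect_equal(de$foldChange, rep(1, nrow(de)))
  expect_equal(de$pval, rep(1, nrow(de)))
  expect_true(all(de$padj >= de$pval))
})

test_that("fold-change arithmetic matches report rounding", {
  expect_identical(fold_change(292, 966), 3.31)
  expect_identical(fold_change(452, 718), 1.59)
  expect_identical(fold_change(0, 5), Inf)
  expect_equal(fold_change(100, 150, digits = NULL), 1.5)
})

test_that("scaling a library rescales its size factor and nothing else", {
  set.seed(308)
  m <- nb_matrix(120, std_samples, mu = 150) + 1L
  m3 <- m
  m3[, "a1"] <- 3L * m3[, "a1"]
  sf <- size_factors(m); sf3 <- size_factors(m3)
  # size factors are defined relative to the geometric-mean reference, so
  # tripling one library triples its size factor relative to the others
  # (all factors share one global rescaling from the shifted reference)
  ratio <- sf3 / sf
  others <- setdiff(std_samples, "a1")
  expect_equal(unname(ratio[["a1"]] / ratio[others[1]]), 3,
               tolerance = 1e-12)
  expect_lt(max(ratio[others]) / min(ratio[others]), 1 + 1e-12)
  # normalized counts agree up to that single global factor
  n1 <- normalize_counts(m, sf); n3 <- normalize_counts(m3, sf3)
  expect_equal(n3 * unname(ratio[others[1]]), n1, tolerance = 1e-9)
  # fold changes are ratios of normalized means: exactly invariant
  de <- de_table(m, std_design())
  de3 <- de_table(m3, std_design())
  expect_equal(de3$foldChange, de$foldChange, tolerance = 1e-9)
  # the exact test conditions on raw totals, whose information content
  # changes with library depth, so p-values are perturbed but boundedly so
  expect_lt(max(abs(log10(de3$pval) - log10(de$pval))), 1)
})

test_that("padj is monotone in p-value ranks", {
  set.seed(309)
  m <- nb_matrix(100, std_samples)
  de <- de_table(m, std_design())
  ord <- order(de$pval)
  expect_true(all(diff(de$padj[ord]) >= -1e-12))
  expect_true(all(de$padj >= de$pval))
})

test_that("a null pipeline rarely reports any significant feature", {
  set.seed(310)
  n_sig <- replicate(20, {
    m <- nb_matrix(300, std_samples, mu = 100, alpha = 0.1)
    de <- de_table(m, std_design())
    sum(de$padj < 0.01)
  })
  expect_gte(mean(n_sig == 0), 0.95)
})

test_that("replicate libraries correlate near one against the median", {
  set.seed(311)
  q <- rlnorm(200, log(100), 2)
  mu <- outer(q, rep(1, 12))
  m <- matrix(rnbinom(length(mu), mu = mu, size = 1 / 0.05), nrow = 200,
              dimnames = list(NULL, sprintf("r%02d", 1:12)))
  r <- sample_correlation_qc(m)
  expect_true(all(r > 0.95))
  # a sample whose control set is copies of itself correlates exactly
  dup <- cbind(x1 = m[, 1], x2 = m[, 1], x3 = m[, 1], y = m[, 2])
  r_dup <- sample_correlation_qc(dup, control_ids = c("x1", "x2", "x3"))
  expect_equal(unname(r_dup["x1"]), 1)
  # a profile that reverses the median's ordering anti-correlates
  ref <- apply(m[, 1:3], 1, median)
  neg <- cbind(m[, 1:3], z = max(ref) - ref)
  r_neg <- sample_correlation_qc(neg, control_ids = colnames(m)[1:3],
                                 log = FALSE)
  expect_lt(unname(r_neg["z"]), 0)
  # degenerate flat sample is reported as missing
  flat <- cbind(m[, 1:3], f = 5)
  expect_true(is.na(sample_correlation_qc(flat)["f"]))
})

test_that("significant ratios classify into enriched and depleted sets", {
  de <- data.frame(id = c("a", "b", "c"),
                   baseMeanA = c(100, 100, 100),
                   baseMeanB = c(50, 200, 120),
                   foldChange = c(0.5, 2, 1.2),
                   pval = c(1e-5, 1e-5, 0.5),
                   padj = c(1e-4, 1e-4, 0.6))
  cls <- classify_head_enrichment(de)
  expect_identical(cls$enriched, "a")
  expect_identical(cls$depleted, "b")
  expect_identical(cls$unclassified, "c")
})

test_that("planted tissue effects are recovered with high sensitivity", {
  set.seed(312)
  n_genes <- 300
  truth_enriched <- sprintf("g%03d", 1:30)   # head-enriched: body 4x lower
  truth_depleted <- sprintf("g%03d", 31:100) # head-depleted: body 4x higher
  samples <- c(sprintf("h%d", 1:3), sprintf("w%d", 1:3))
  mu <- matrix(500, n_genes, 6,
               dimnames = list(sprintf("g%03d", 1:n_genes), samples))
  mu[truth_enriched, 4:6] <- 125
  mu[truth_depleted, 4:6] <- 2000
  m <- matrix(rnbinom(length(mu), mu = mu, size = 1 / 0.05), n_genes, 6,
              dimnames = dimnames(mu))
  design <- contrast_design(sprintf("h%d", 1:3), sprintf("w%d", 1:3))
  de <- de_table(m, design)
  cls <- classify_head_enrichment(de, threshold = 0.01)
  sens <- (sum(truth_enriched %in% cls$enriched) +
             sum(truth_depleted %in% cls$depleted)) / 100
  expect_gte(sens, 0.9)
  null_ids <- sprintf("g%03d", 101:300)
  fp <- sum(null_ids %in% c(cls$enriched, cls$depleted))
  expect_lte(fp, 4)
})

test_that("direction concordance counts sides of unity", {
  r1 <- setNames(c(2, 0.5, 3, 0.2, 1.5, 0.8, 2.5, 0.4, 1.2, 0.9),
                 letters[1:10])
  expect_equal(direction_concordance(r1, r1)$fraction, 1)
  r2 <- r1
  r2["a"] <- 0.5  # one ratio flips across 1
  expect_equal(direction_concordance(r1, r2)$fraction, 0.9)
  set.seed(313)
  null_frac <- mean(replicate(200, {
    a <- setNames(rlnorm(50), paste0("m", 1:50))
    b <- setNames(rlnorm(50), paste0("m", 1:50))
    direction_concordance(a, b)$fraction
  }))
  expect_gt(null_frac, 0.45)
  expect_lt(null_frac, 0.55)
  expect_error(direction_concordance(c(x = 1), c(y = 1)), "shared")
})

test_that("comparative Ct fold changes evaluate the stated formula", {
  expect_equal(ddct_fold_change(c(20, 20), list(c(15, 16), c(15, 16))), 1)
  expect_equal(ddct_fold_change(c(20, 19), list(c(15, 16), c(15, 16))), 2)
  expect_equal(ddct_fold_change(c(20, 18), list(c(15, 15), c(14, 14))), 2)
})
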