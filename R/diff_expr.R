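#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over rows i (restricted
#' to rows with all-positive entries) of `k_ij / g_i`, where `g_i` is the
#' geometric mean of row i across samples. Normalized counts `k_ij / s_j`
#' are comparable across libraries of different depth.
#'
#' @param matrix non-negative integer count matrix, rows features, columns
#'   samples.
#' @return named numeric vector of positive size factors.
#' @export
size_factors <- function(matrix) {
  if (any(matrix < 0)) stop("counts must be non-negative")
  pos <- rowSums(matrix > 0) == ncol(matrix)
  if (!any(pos)) {
    stop(paste0("no row with all-positive entries; size factors are not ",
                "estimable (every feature has a zero in some sample)"))
  }
  logs <- log(matrix[pos, , drop = FALSE])
  loggeo <- rowMeans(logs)
  apply(logs, 2, function(col) exp(median(col - loggeo)))
}

#' Normalized counts
#'
#' @param matrix count matrix.
#' @param sf size factors (default: computed from `matrix`).
#' @return matrix of counts divided by their sample's size factor.
#' @export
normalize_counts <- function(matrix, sf = size_factors(matrix)) {
  sweep(matrix, 2, sf, "/")
}

#' Define a two-condition contrast with reference controls
#'
#' The reference-control set enters only the dispersion estimation — it
#' improves the estimate of between-replicate variation — and never the
#' tested contrast itself; comparisons are always between samples of
#' similar genotype.
#'
#' @param condition_a,condition_b disjoint, non-empty sample id vectors.
#' @param reference_controls additional sample ids used only for dispersion
#'   estimation (may be empty).
#' @param sig_threshold significance threshold applied to adjusted p-values
#'   (default 0.01).
#' @return list of class `contrast_design`.
#' @export
contrast_design <- function(condition_a, condition_b,
                            reference_controls = character(0),
                            sig_threshold = 0.01) {
  if (length(condition_a) == 0 || length(condition_b) == 0) {
    stop("both conditions need at least one sample")
  }
  if (length(intersect(condition_a, condition_b)) > 0) {
    stop("condition groups must be disjoint")
  }
  structure(list(condition_a = condition_a, condition_b = condition_b,
                 reference_controls = setdiff(reference_controls,
                                              c(condition_a, condition_b)),
                 sig_threshold = sig_threshold),
            class = "contrast_design")
}

#' Estimate per-feature NB dispersions with maximum sharing
#'
#' Gene-wise dispersions come from within-group moments of normalized
#' counts: each condition group and the reference-control set is its own
#' replicate group; within-group variances are pooled across groups with
#' at least two samples, the sampling (shot-noise) component `mu *
#' mean(1/s_j)` is subtracted, and the excess is scaled by `mu^2` and
#' floored at zero. A parametric trend `alpha(mu) = a0 + a1/mu` is fitted
#' over features by non-negative least squares (falling back to the median
#' gene-wise value if the fit degenerates). Under `sharing_mode =
#' "maximum"` the final dispersion is the pointwise maximum of the
#' gene-wise and fitted values — a conservative choice that guards against
#' underestimating variability for individual features.
#'
#' @param matrix count matrix.
#' @param design a `contrast_design`; its two condition groups plus the
#'   reference-control set define the replicate groups.
#' @param sharing_mode `"maximum"` (default) or `"fit-only"`.
#' @param sf size factors (default: computed from `matrix`).
#' @return data.frame `id`, `base_mean`, `genewise`, `fitted`, `final`.
#' @export
estimate_dispersions <- function(matrix, design,
                                 sharing_mode = c("maximum", "fit-only"),
                                 sf = NULL) {
  sharing_mode <- match.arg(sharing_mode)
  groups <- list(design$condition_a, design$condition_b,
                 design$reference_controls)
  groups <- Filter(function(g) length(g) >= 2, groups)
  if (length(groups) == 0) {
    stop(paste0("no replicate group with >= 2 samples; supply reference ",
                "controls so that within-group variability is estimable"))
  }
  used <- unlist(groups)
  if (is.null(sf)) sf <- size_factors(matrix[, used, drop = FALSE])
  norm <- normalize_counts(matrix[, used, drop = FALSE], sf[used])

  mu <- rowMeans(norm)
  # Per group: excess of the within-group variance over the shot-noise
  # term, scaled by the group's own squared mean; dispersion is scale-free
  # so group-wise alphas can be pooled even when a true fold change
  # separates the group means.
  alpha_sum <- 0
  df_sum <- numeric(nrow(norm))
  for (g in groups) {
    mu_g <- rowMeans(norm[, g, drop = FALSE])
    v_g <- apply(norm[, g, drop = FALSE], 1, var)
    xi_g <- mean(1 / sf[g])
    a_g <- ifelse(mu_g > 0, (v_g - xi_g * mu_g) / mu_g^2, NA_real_)
    w <- ifelse(is.na(a_g), 0, length(g) - 1L)
    alpha_sum <- alpha_sum + ifelse(is.na(a_g), 0, w * a_g)
    df_sum <- df_sum + w
  }
  genewise <- pmax(0, ifelse(df_sum > 0, alpha_sum / df_sum, 0))

  keep <- mu > 0
  fitted <- rep(NA_real_, length(mu))
  fit_ok <- FALSE
  if (sum(keep) >= 2 && any(genewise[keep] > 0)) {
    X <- cbind(1, 1 / mu[keep])
    coefs <- tryCatch(pracma::lsqnonneg(X, genewise[keep])$x,
                      error = function(e) NULL)
    if (!is.null(coefs)) {
      fitted[keep] <- coefs[1] + coefs[2] / mu[keep]
      fit_ok <- TRUE
    }
  }
  if (!fit_ok) fitted[keep] <- median(genewise[keep])
  fitted[!keep] <- 0

  final <- switch(sharing_mode,
                  maximum = pmax(genewise, fitted),
                  `fit-only` = fitted)
  data.frame(id = rownames(matrix), base_mean = mu, genewise = genewise,
             fitted = fitted, final = final, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Negative binomial conditional exact test for one feature
#'
#' Tests whether the counts of two groups are draws from the same NB law.
#' With group totals `K_A` and `K_B`, the null models the pair `(a, K - a)`
#' as the product of two NB distributions whose means are proportional to
#' the group size-factor sums (`mu_A = q * S_A` with
#' `q = (K_A + K_B) / (S_A + S_B)`), each sample contributing variance
#' `mu + alpha mu^2`, so the group total has variance
#' `mu_A + alpha q^2 sum(s_j^2)`. The two-sided p-value sums the
#' probabilities of all splits of `K` no more likely than the observed one,
#' normalized by the total over all splits. `K_A + K_B = 0` returns p = 1
#' by convention.
#'
#' @param counts_a,counts_b integer count vectors for the two groups.
#' @param sf_a,sf_b size factors of the corresponding samples.
#' @param alpha NB dispersion (>= 0; 0 gives the Poisson limit, which
#'   reduces to the exact binomial conditional test).
#' @return p-value in `[0, 1]`.
#' @export
nb_exact_test <- function(counts_a, counts_b, sf_a, sf_b, alpha) {
  stopifnot(alpha >= 0, length(counts_a) == length(sf_a),
            length(counts_b) == length(sf_b),
            length(counts_a) > 0, length(counts_b) > 0)
  kA <- sum(counts_a); kB <- sum(counts_b)
  kS <- kA + kB
  if (kS == 0) return(1)
  sA <- sum(sf_a); sB <- sum(sf_b)
  q <- kS / (sA + sB)
  muA <- q * sA; muB <- q * sB
  ks <- 0:kS
  if (alpha == 0) {
    pA <- dpois(ks, muA)
    pB <- dpois(kS - ks, muB)
  } else {
    sizeA <- sA^2 / (alpha * sum(sf_a^2))
    sizeB <- sB^2 / (alpha * sum(sf_b^2))
    pA <- dnbinom(ks, mu = muA, size = sizeA)
    pB <- dnbinom(kS - ks, mu = muB, size = sizeB)
  }
  joint <- pA * pB
  total <- sum(joint)
  if (total == 0) return(1)
  obs <- joint[kA + 1L]
  p <- sum(joint[joint <= obs * (1 + 1e-7)]) / total
  min(1, max(0, p))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Differential expression table for one contrast
#'
#' Rows with zero counts across all contrast and reference samples are
#' filtered before testing (recorded in the `"filtered"` attribute). Base
#' means are arithmetic means of normalized counts over each condition's
#' samples; the fold change is `baseMeanB / baseMeanA`, reported as `Inf`
#' when the feature is absent from condition A. p-values come from
#' [nb_exact_test()] with dispersions from [estimate_dispersions()], and
#' are BH-adjusted across all tested rows.
#'
#' @param matrix count matrix including contrast and reference-control
#'   samples.
#' @param design a `contrast_design`.
#' @param sharing_mode dispersion sharing mode (default `"maximum"`).
#' @return data.frame `id`, `baseMeanA`, `baseMeanB`, `foldChange`, `pval`,
#'   `padj`.
#' @export
de_table <- function(matrix, design, sharing_mode = "maximum") {
  all_samples <- c(design$condition_a, design$condition_b,
                   design$reference_controls)
  stopifnot(all(all_samples %in% colnames(matrix)))
  m <- matrix[, all_samples, drop = FALSE]
  zero <- rowSums(m) == 0
  filtered <- rownames(m)[zero]
  m <- m[!zero, , drop = FALSE]
  sf <- size_factors(m)
  disp <- estimate_dispersions(m, design, sharing_mode = sharing_mode,
                               sf = sf)
  norm <- normalize_counts(m, sf)
  a <- design$condition_a; b <- design$condition_b
  baseA <- rowMeans(norm[, a, drop = FALSE])
  baseB <- rowMeans(norm[, b, drop = FALSE])
  pval <- vapply(seq_len(nrow(m)), function(i) {
    nb_exact_test(m[i, a], m[i, b], sf[a], sf[b], disp$final[i])
  }, numeric(1))
  out <- data.frame(id = rownames(m), baseMeanA = baseA, baseMeanB = baseB,
                    foldChange = ifelse(baseA > 0, baseB / baseA, Inf),
                    pval = pval, padj = bh_adjust(pval),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "filtered") <- filtered
  out
}

#' Fold change as a ratio of normalized means
#'
#' The fold-change arithmetic used in reports: the mean normalized count of
#' condition B divided by that of condition A, rounded for table display
#' (full precision is retained internally by [de_table()]).
#'
#' @param mean_a,mean_b normalized mean counts of the two conditions.
#' @param digits decimals for table display (default 2); `NULL` for full
#'   precision.
#' @return `mean_b / mean_a` (Inf when `mean_a` is 0), optionally rounded.
#' @export
fold_change <- function(mean_a, mean_b, digits = 2) {
  fc <- ifelse(mean_a > 0, mean_b / mean_a, Inf)
  if (!is.null(digits)) fc <- round(fc, digits)
  fc
}

#' Per-sample correlation against the median control profile
#'
#' Each sample's normalized counts are correlated (Pearson, on
#' log1p-transformed values by default) against the per-feature median over
#' the control samples — the quality-control view in which homogeneous
#' replicate libraries correlate above 0.99.
#'
#' @param norm_matrix normalized count matrix (at least 3 samples).
#' @param control_ids samples defining the median reference profile
#'   (default: all columns).
#' @param log correlate log1p-transformed values (default TRUE); raw-scale
#'   correlation is available but saturates near `sqrt(1/(1+alpha))` for
#'   overdispersed data.
#' @return named numeric vector of correlations; zero-variance samples get
#'   `NA`.
#' @export
sample_correlation_qc <- function(norm_matrix,
                                  control_ids = colnames(norm_matrix),
                                  log = TRUE) {
  stopifnot(ncol(norm_matrix) >= 3)
  ref <- apply(norm_matrix[, control_ids, drop = FALSE], 1, median)
  f <- if (log) log1p else identity
  vapply(colnames(norm_matrix), function(s) {
    x <- f(norm_matrix[, s]); y <- f(ref)
    if (var(x) == 0 || var(y) == 0) return(NA_real_)
    cor(x, y)
  }, numeric(1))
}

#' Classify head-enriched and head-depleted features
#'
#' Applies the significance threshold to a body-vs-head DE table: for
#' significant rows, a whole-body/head ratio below 1 marks a head-enriched
#' feature, above 1 a head-depleted one; non-significant rows stay
#' unclassified.
#'
#' @param de DE table from [de_table()] on a body-vs-head design (condition
#'   A = head, condition B = whole body, so `foldChange` is the
#'   body/head ratio).
#' @param threshold significance threshold (default 0.01).
#' @param use_adjusted threshold the BH-adjusted values (default TRUE); set
#'   FALSE to threshold raw p-values.
#' @return list `enriched`, `depleted`, `unclassified` of feature ids.
#' @export
classify_head_enrichment <- function(de, threshold = 0.01,
                                     use_adjusted = TRUE) {
  p <- if (use_adjusted) de$padj else de$pval
  sig <- p < threshold
  list(enriched = de$id[sig & de$foldChange < 1],
       depleted = de$id[sig & de$foldChange > 1],
       unclassified = de$id[!sig | de$foldChange == 1])
}

#' Directional concordance between two ratio sets
#'
#' Fraction of shared features whose ratios fall on the same side of 1 in
#' both experiments. Ratios exactly 1 are concordant with either side and
#' reported separately.
#'
#' @param ratios_1,ratios_2 named positive numeric vectors (e.g.
#'   whole-body/head ratios from independent experiments).
#' @return list `fraction`, `n_shared`, `n_ties`.
#' @export
direction_concordance <- function(ratios_1, ratios_2) {
  shared <- intersect(names(ratios_1), names(ratios_2))
  if (length(shared) == 0) stop("no shared feature ids")
  r1 <- ratios_1[shared]; r2 <- ratios_2[shared]
  tie <- r1 == 1 | r2 == 1
  conc <- tie | (r1 > 1) == (r2 > 1)
  list(fraction = mean(conc), n_shared = length(shared),
       n_ties = sum(tie))
}

#' Relative quantification fold change from qPCR cycle values
#'
#' Comparative Ct: per group, `dCt = Ct_target - mean(Ct_normalizers)`
#' (two normalizer genes); the B-vs-A fold change is `2^-(dCt_B - dCt_A)`.
#'
#' @param ct_target numeric of length 2, named or ordered `c(A, B)`: mean
#'   target cycle values per group.
#' @param ct_normalizers 2-row structure of normalizer cycle values: a
#'   matrix/data.frame with one row per group, or a list of per-group
#'   vectors, in the same A, B order.
#' @return fold change of the target in group B relative to group A.
#' @export
ddct_fold_change <- function(ct_target, ct_normalizers) {
  norm_means <- if (is.list(ct_normalizers) && !is.data.frame(ct_normalizers))
    vapply(ct_normalizers, mean, numeric(1))
  else rowMeans(as.matrix(ct_normalizers))
  stopifnot(length(ct_target) == 2, length(norm_means) == 2,
            all(is.finite(ct_target)), all(is.finite(norm_means)))
  dct <- ct_target - norm_means
  2^(-(dct[[2]] - dct[[1]]))
}
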