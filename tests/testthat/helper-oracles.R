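# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# All placements of `query` on both strands of named references with
# Hamming distance <= max_mm, by scanning every offset.
oracle_hamming_hits <- function(query, refs, max_mm = 1L) {
  qc_plus <- strsplit(query, "")[[1]]
  qc_minus <- strsplit(oracle_revcomp(query), "")[[1]]
  w <- length(qc_plus)
  rows <- list()
  for (rid in names(refs)) {
    rc <- strsplit(refs[[rid]], "")[[1]]
    if (length(rc) < w) next
    for (off in 0:(length(rc) - w)) {
      win <- rc[(off + 1):(off + w)]
      for (strand in c("+", "-")) {
        qc <- if (strand == "+") qc_plus else qc_minus
        mm <- sum(qc != win)
        if (mm <= max_mm) {
          rows[[length(rows) + 1L]] <- data.frame(
            ref_id = rid, offset = off, strand = strand,
            mismatches = mm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(ref_id = character(0), offset = integer(0),
               strand = character(0), mismatches = integer(0))
}

# Canonical sort for comparing hit tables.
sort_hits <- function(h) {
  h <- h[order(h$ref_id, h$strand, h$offset, h$mismatches), , drop = FALSE]
  rownames(h) <- NULL
  h
}

# Exhaustive enumeration of every candidate split position, applying the
# documented tie-break (max U+D, then nearest the middle, then smaller s).
oracle_split <- function(starts, ends, L, window = 20L) {
  mid <- L %/% 2L
  cand <- seq(max(1L, mid - window), min(L - 1L, mid + window))
  best <- NULL
  for (s in cand) {
    U <- sum(ends <= s)
    D <- sum(starts >= s)
    rec <- list(s = s, U = U, D = D, score = U + D, dist = abs(s - mid))
    if (is.null(best) || rec$score > best$score ||
        (rec$score == best$score &&
         (rec$dist < best$dist ||
          (rec$dist == best$dist && rec$s < best$s)))) {
      best <- rec
    }
  }
  best
}

# Step-up BH from the closed form: padj_(i) = min over j >= i of
# min(1, m p_(j) / j), mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  padj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    padj_sorted[i] <- min(1, min(m * p[ord][i:m] / (i:m)))
  }
  padj <- numeric(m)
  padj[ord] <- padj_sorted
  padj
}

# Adapter clipping by full scan over all suffix/prefix overlaps.
oracle_trim <- function(read, adapter, min_overlap = 5L) {
  n <- nchar(read)
  for (start in seq_len(max(0L, n - nchar(adapter) + 1L))) {
    if (substr(read, start, start + nchar(adapter) - 1L) == adapter) {
      return(substr(read, 1L, start - 1L))
    }
  }
  for (k in seq(min(nchar(adapter) - 1L, n), 1L)) {
    if (k < min_overlap) break
    if (substr(read, n - k + 1L, n) == substr(adapter, 1L, k)) {
      return(substr(read, 1L, n - k))
    }
  }
  read
}

# Scalar-loop DP for the minimum number of substitutions plus
# read-insertions aligning the full read inside the reference (free ref
# ends, no deletions).
oracle_edit_dp <- function(read, ref) {
  rc <- strsplit(read, "")[[1]]
  fc <- strsplit(ref, "")[[1]]
  m <- length(rc); n <- length(fc)
  M <- matrix(Inf, nrow = m + 1L, ncol = n + 1L)
  M[1L, ] <- 0
  for (i in 1:m) {
    M[i + 1L, 1L] <- i
    for (j in 1:n) {
      M[i + 1L, j + 1L] <- min(M[i, j] + (rc[i] != fc[j]),
                               M[i, j + 1L] + 1)
    }
  }
  min(M[m + 1L, 2:(n + 1L)])
}

oracle_edit_best <- function(read, ref) {
  min(oracle_edit_dp(read, ref), oracle_edit_dp(oracle_revcomp(read), ref))
}

# Two-sided exact binomial test at rate 1/2 by the minimum-likelihood rule.
oracle_binom_half <- function(kA, kS) {
  probs <- dbinom(0:kS, kS, 0.5)
  obs <- probs[kA + 1L]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Fixture conveniences (not oracles): reuse the package's internal
# sequence generators.
random_dna <- function(lengths) mirarms:::random_dna(lengths)
mutate_bases <- function(seq, k, positions = NULL) {
  mirarms:::mutate_bases(seq, k, positions)
}

# Small bundle + design used across tests.
make_test_bundle <- function(n_stemloops = 4, seed = 1, ...) {
  build_toy_reference(
    modifyList(list(n_stemloops = n_stemloops, n_transgenes = 1,
                    repeat_units = 40), list(...)),
    seed = seed)
}

make_test_design <- function(bundle, n_per_group = 2, depth = 500,
                             dispersion = 0.05, effect_map = list(),
                             seed = 2) {
  samples <- data.frame(
    sample = c(sprintf("ind%d", seq_len(n_per_group)),
               sprintf("uni%d", seq_len(n_per_group))),
    condition = rep(c("induced", "uninduced"), each = n_per_group),
    stringsAsFactors = FALSE)
  simulation_design(samples, effect_map = effect_map,
                    dispersion_map = dispersion, depth_map = depth,
                    seed = seed)
}
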