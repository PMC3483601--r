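#' Describe a simulated sequencing study
#'
#' A simulation design couples a sample sheet (sample, genotype, condition,
#' tissue) with per-arm fold-change, dispersion and depth maps. Counts for
#' arm i in sample j are negative binomial with mean
#' `depth_j * q_i * fc_i(group_j)` and variance `mu + alpha_i * mu^2`, where
#' `q_i` is the arm's relative abundance from the bundle.
#'
#' @param samples data.frame with columns `sample`, `genotype`, `condition`
#'   (e.g. induced/uninduced) and `tissue` (head/body). `genotype` and
#'   `tissue` default to a single level when absent.
#' @param effect_map named list: arm id -> named numeric vector of fold
#'   changes per level of `effect_on`. Missing arms and levels default to 1.
#' @param dispersion_map named numeric vector of NB dispersions alpha per
#'   arm, or a single value recycled to all arms (default 0.05).
#' @param depth_map named numeric vector of expected library sizes per
#'   sample, or a single value recycled (default 5e4).
#' @param effect_on which sample-sheet column the effect map keys on
#'   (`"condition"` or `"tissue"`).
#' @param seed integer seed.
#' @return list of class `simulation_design`.
#' @export
simulation_design <- function(samples, effect_map = list(),
                              dispersion_map = 0.05, depth_map = 5e4,
                              effect_on = c("condition", "tissue"),
                              seed = 1L) {
  effect_on <- match.arg(effect_on)
  stopifnot(is.data.frame(samples), "sample" %in% names(samples))
  if (is.null(samples$condition)) samples$condition <- "uninduced"
  if (is.null(samples$tissue)) samples$tissue <- "head"
  if (is.null(samples$genotype)) samples$genotype <- "wt"
  if (anyDuplicated(samples$sample)) stop("duplicate sample ids")
  fc <- unlist(effect_map)
  if (length(fc) && (any(!is.finite(fc)) || any(fc < 0))) {
    stop("fold changes must be finite and non-negative")
  }
  if (any(!is.finite(dispersion_map)) || any(dispersion_map < 0)) {
    stop("dispersions must be finite and non-negative")
  }
  structure(list(samples = samples, effect_map = effect_map,
                 dispersion_map = dispersion_map, depth_map = depth_map,
                 effect_on = effect_on, seed = seed),
            class = "simulation_design")
}

design_mu <- function(design, bundle) {
  arms <- arm_ids(bundle)
  expr <- unlist(lapply(bundle$stemloops, function(sl) {
    c(sl$mean_expr_5p, sl$mean_expr_3p)
  }))
  q <- if (sum(expr) > 0) expr / sum(expr) else expr * 0
  names(q) <- arms
  samples <- design$samples
  depth <- design$depth_map
  if (is.null(names(depth))) {
    depth <- setNames(rep_len(depth, nrow(samples)), samples$sample)
  }
  groups <- samples[[design$effect_on]]
  mu <- outer(q, depth[samples$sample])
  for (arm in names(design$effect_map)) {
    if (!arm %in% arms) stop(sprintf("effect_map arm '%s' not in bundle", arm))
    fc <- design$effect_map[[arm]]
    f <- ifelse(groups %in% names(fc), fc[groups], 1)
    mu[arm, ] <- mu[arm, ] * f
  }
  colnames(mu) <- samples$sample
  mu
}

#' Simulate an arm count matrix under the negative binomial model
#'
#' @param design a `simulation_design`.
#' @param bundle a `reference_bundle`.
#' @return integer matrix of class `matrix`, rows `<stemloop>_5p/_3p`,
#'   columns samples; deterministic for a fixed design seed.
#' @export
simulate_count_matrix <- function(design, bundle) {
  withr::local_seed(design$seed)
  mu <- design_mu(design, bundle)
  alpha <- design$dispersion_map
  if (is.null(names(alpha))) {
    alpha <- setNames(rep_len(alpha, nrow(mu)), rownames(mu))
  }
  counts <- mu
  for (i in seq_len(nrow(mu))) {
    a <- alpha[rownames(mu)[i]]
    if (is.na(a)) a <- 0
    counts[i, ] <- if (a == 0) {
      rpois(ncol(mu), mu[i, ])
    } else {
      rnbinom(ncol(mu), mu = mu[i, ], size = 1 / a)
    }
  }
  storage.mode(counts) <- "integer"
  counts
}

arm_interval <- function(bundle, arm) {
  sl_id <- sub("_(5p|3p)$", "", arm)
  sl <- Filter(function(s) s$id == sl_id, bundle$stemloops)[[1]]
  if (grepl("_5p$", arm)) sl$arm5p else sl$arm3p
}

make_read <- function(insert, adapter, read_length) {
  full <- paste0(insert, adapter)
  if (nchar(full) < read_length) {
    full <- paste0(full, random_dna(read_length - nchar(full)))
  }
  substr(full, 1L, read_length)
}

#' Synthesize adapter-bearing FASTQ read sets from a count matrix
#'
#' Each count in `counts` becomes one read: an insert sampled from the
#' declared arm interval of its stem-loop (with optional +/- 1 nt end
#' wobble), optionally carrying at most one substitution at rate
#' `error_rate`, followed by the 3' adapter, padded with random bases or
#' truncated to a fixed read length. A truth sidecar records the origin of
#' every read; it is never written into the FASTQ itself.
#'
#' @param counts arm x sample integer matrix (as from
#'   [simulate_count_matrix()]).
#' @param bundle a `reference_bundle`.
#' @param adapter 3' adapter sequence (default the library adapter
#'   `CTGTAGGCACCATCAAT`).
#' @param error_rate per-read probability of one substitution in the
#'   insert; must be in `[0, 0.5)`.
#' @param seed integer seed.
#' @param read_length sequencer read length before trimming (default 36).
#' @param wobble maximum end wobble in nt (default 1; set 0 for exact arm
#'   intervals).
#' @param out_dir if non-NULL, write one `<sample>.fastq` per sample
#'   (Phred+33, constant quality "I") plus `truth.tsv` under this
#'   directory.
#' @return list with `reads` (named list per sample of data.frames
#'   `id`, `seq`, `qual`) and `truth` (data.frame `read_id`, `sample`,
#'   `origin_type`, `origin_id`, `start`, `end`, `errors`).
#' @export
synthesize_fastq <- function(counts, bundle,
                             adapter = "CTGTAGGCACCATCAAT",
                             error_rate = 0, seed = 1L, read_length = 36L,
                             wobble = 1L, out_dir = NULL) {
  assert_dna(adapter, allow_n = FALSE, what = "adapter")
  if (error_rate < 0 || error_rate >= 0.5) {
    stop("error_rate must be in [0, 0.5)")
  }
  withr::local_seed(seed)
  samples <- colnames(counts)
  reads <- setNames(vector("list", length(samples)), samples)
  truth <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    s <- samples[si]
    arm_n <- counts[, s]
    arm_n <- arm_n[arm_n > 0L]
    n_tot <- sum(arm_n)
    if (n_tot == 0L) {
      reads[[s]] <- data.frame(id = character(0), seq = character(0),
                               qual = character(0),
                               stringsAsFactors = FALSE)
      next
    }
    arm_of <- rep(names(arm_n), arm_n)
    starts <- integer(n_tot); ends <- integer(n_tot)
    inserts <- character(n_tot)
    offs <- c(0L, cumsum(arm_n))
    for (ai in seq_along(arm_n)) {
      arm <- names(arm_n)[ai]
      n <- arm_n[[ai]]
      iv <- arm_interval(bundle, arm)
      sl_seq <- Filter(function(x) x$id == sub("_(5p|3p)$", "", arm),
                       bundle$stemloops)[[1]]$sequence
      L <- nchar(sl_seq)
      w <- if (wobble > 0) seq(-wobble, wobble) else 0L
      st <- pmax(0L, iv[1] + w[sample.int(length(w), n, replace = TRUE)])
      en <- pmin(L, iv[2] + w[sample.int(length(w), n, replace = TRUE)])
      idx <- (offs[ai] + 1L):offs[ai + 1L]
      starts[idx] <- st; ends[idx] <- en
      inserts[idx] <- substring(sl_seq, st + 1L, en)
    }
    errs <- if (error_rate > 0) runif(n_tot) < error_rate else
      rep(FALSE, n_tot)
    for (i in which(errs)) inserts[i] <- mutate_bases(inserts[i], 1L)
    ids <- sprintf("%s_r%06d", s, seq_len(n_tot))
    full <- paste0(inserts, adapter)
    pad <- pmax(0L, read_length - nchar(full))
    if (any(pad > 0L)) {
      full[pad > 0L] <- paste0(full[pad > 0L], random_dna(pad[pad > 0L]))
    }
    seqs <- substr(full, 1L, read_length)
    reads[[s]] <- data.frame(id = ids, seq = seqs,
                             qual = strrep("I", nchar(seqs)),
                             stringsAsFactors = FALSE)
    truth[[si]] <- data.frame(
      read_id = ids, sample = s, origin_type = "arm", origin_id = arm_of,
      start = starts, end = ends, errors = as.integer(errs),
      stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else NULL
  if (is.null(truth)) truth <-
    data.frame(read_id = character(0), sample = character(0),
               origin_type = character(0), origin_id = character(0),
               start = integer(0), end = integer(0), errors = integer(0))
  out <- list(reads = reads, truth = truth)
  if (!is.null(out_dir)) write_fastq_set(out, out_dir)
  out
}

#' Add synthetic background reads from non-miRNA categories
#'
#' Draws `n` reads per reference from random positions of category
#' references (plus strand), appends the adapter, and extends the truth
#' sidecar. Used to exercise the annotation cascade beyond the miRNA tier.
#'
#' @param fastq_set output of [synthesize_fastq()].
#' @param bundle a `reference_bundle`.
#' @param category one of the five non-intergenic background categories or
#'   `"intergenic"`.
#' @param n reads per reference per sample.
#' @param insert_length insert size (default 22).
#' @param adapter,read_length,seed as in [synthesize_fastq()].
#' @return the augmented fastq set.
#' @export
add_background_reads <- function(fastq_set, bundle, category, n = 5L,
                                 insert_length = 22L,
                                 adapter = "CTGTAGGCACCATCAAT",
                                 read_length = 36L, seed = 1L) {
  refs <- bundle$categories[[category]]
  if (is.null(refs)) stop(sprintf("unknown category '%s'", category))
  withr::local_seed(seed)
  for (s in names(fastq_set$reads)) {
    ids <- character(0); seqs <- character(0); tr <- list()
    k <- 0L
    for (rid in names(refs)) {
      L <- nchar(refs[rid])
      for (j in seq_len(n)) {
        st <- sample.int(L - insert_length + 1L, 1L) - 1L
        insert <- substr(refs[rid], st + 1L, st + insert_length)
        k <- k + 1L
        id <- sprintf("%s_%s_b%04d", s, category, k)
        ids <- c(ids, id)
        seqs <- c(seqs, make_read(insert, adapter, read_length))
        tr[[length(tr) + 1L]] <- data.frame(
          read_id = id, sample = s, origin_type = category,
          origin_id = rid, start = st, end = st + insert_length,
          errors = 0L, stringsAsFactors = FALSE)
      }
    }
    if (k > 0L) {
      fastq_set$reads[[s]] <- rbind(
        fastq_set$reads[[s]],
        data.frame(id = ids, seq = seqs, qual = strrep("I", nchar(seqs)),
                   stringsAsFactors = FALSE))
      fastq_set$truth <- rbind(fastq_set$truth, do.call(rbind, tr))
    }
  }
  fastq_set
}

#' Spike CAG-repeat reads into a FASTQ set
#'
#' Samples `n` short reads from the declared repeat region of a transgene,
#' on either strand, applies the requested number of edits (substitutions)
#' per read, appends the adapter and adds them to every sample (or to the
#' samples named in `samples`). Spiked read ids carry a `_scag` tag in the
#' truth sidecar for downstream truth tracking; the FASTQ records are
#' indistinguishable from genuine reads.
#'
#' @param fastq_set output of [synthesize_fastq()].
#' @param transgene one element of `bundle$transgenes` (list with
#'   `sequence`, `repeat_start`, `repeat_end`).
#' @param n number of reads to spike per sample; `n = 0` leaves the set
#'   unchanged.
#' @param length_range integer range of spiked read lengths within
#'   `[15, 30]`.
#' @param edit_profile named integer vector over edit counts `"0"`, `"1"`,
#'   `"2"` summing to `n` (e.g. `c("0" = 2, "1" = 5, "2" = 1)`); reads of
#'   each class carry exactly that many substitutions.
#' @param samples samples to spike (default: all).
#' @param adapter,read_length,seed as in [synthesize_fastq()].
#' @return the augmented fastq set.
#' @export
spike_repeat_reads <- function(fastq_set, transgene, n,
                               length_range = c(18L, 21L),
                               edit_profile = NULL, samples = NULL,
                               adapter = "CTGTAGGCACCATCAAT",
                               read_length = 36L, seed = 1L) {
  if (n < 0) stop("n must be >= 0")
  if (length_range[1] < 15 || length_range[2] > 30) {
    stop("length_range must lie within [15, 30]")
  }
  if (n == 0L) return(fastq_set)
  if (is.null(edit_profile)) edit_profile <- c("0" = n)
  stopifnot(sum(edit_profile) == n)
  edits <- rep(as.integer(names(edit_profile)), edit_profile)
  withr::local_seed(seed)
  if (is.null(samples)) samples <- names(fastq_set$reads)
  rep_seq <- substr(transgene$sequence, transgene$repeat_start,
                    transgene$repeat_end)
  rl <- nchar(rep_seq)
  for (s in samples) {
    ids <- character(0); seqs <- character(0); tr <- list()
    for (k in seq_len(n)) {
      len <- sample_one(seq(length_range[1], length_range[2]))
      st <- sample.int(rl - len + 1L, 1L)
      insert <- substr(rep_seq, st, st + len - 1L)
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") insert <- revcomp(insert)
      e <- edits[k]
      if (e > 0L) {
        # Substitutions at positions >= 3 apart so that, in a period-3
        # repeat, k substitutions cannot collapse into fewer edits under
        # any alternative frame or single-insertion alignment.
        pos <- if (e == 1L) sample.int(len, 1L) else {
          p1 <- sample.int(len - 3L, 1L)
          c(p1, p1 + 3L)
        }
        insert <- mutate_bases(insert, e, positions = pos)
      }
      id <- sprintf("%s_scag%04d", s, k)
      ids <- c(ids, id)
      seqs <- c(seqs, make_read(insert, adapter, read_length))
      tr[[length(tr) + 1L]] <- data.frame(
        read_id = id, sample = s, origin_type = "scag",
        origin_id = transgene$id,
        start = transgene$repeat_start + st - 2L,
        end = transgene$repeat_start + st - 2L + len, errors = e,
        stringsAsFactors = FALSE)
    }
    fastq_set$reads[[s]] <- rbind(
      fastq_set$reads[[s]],
      data.frame(id = ids, seq = seqs, qual = strrep("I", nchar(seqs)),
                 stringsAsFactors = FALSE))
    fastq_set$truth <- rbind(fastq_set$truth, do.call(rbind, tr))
  }
  fastq_set
}

#' Write / read a FASTQ set
#'
#' `write_fastq_set` writes standard 4-line Phred+33 FASTQ per sample plus
#' the truth sidecar as TSV; `read_fastq` parses one FASTQ file into a read
#' data.frame.
#'
#' @param fastq_set list with `reads` and `truth` as returned by
#'   [synthesize_fastq()].
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_fastq_set <- function(fastq_set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (s in names(fastq_set$reads)) {
    df <- fastq_set$reads[[s]]
    path <- file.path(dir, paste0(s, ".fastq"))
    lines <- as.vector(rbind(paste0("@", df$id), df$seq, "+", df$qual))
    writeLines(lines, path)
    paths[s] <- path
  }
  truth_path <- file.path(dir, "truth.tsv")
  write.table(fastq_set$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths["truth"] <- truth_path
  invisible(paths)
}

#' @param path FASTQ file path.
#' @rdname write_fastq_set
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("malformed FASTQ: ", path)
  idx <- seq(1L, length(lines), by = 4L)
  data.frame(id = sub("^@", "", sub(" .*", "", lines[idx])),
             seq = toupper(lines[idx + 1L]),
             qual = lines[idx + 3L], stringsAsFactors = FALSE)
}
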