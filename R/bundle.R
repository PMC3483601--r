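#' Build a seeded toy reference bundle
#'
#' Constructs a small synthetic genome with non-overlapping planted loci for
#' the six annotation categories (miRNA stem-loops, other non-coding RNAs,
#' transposons, introns, mRNAs, intergenic spacers), plus standalone
#' polyglutamine-style transgenes carrying a CAG-repeat tract. Every
#' category reference sequence is an exact substring of the genome, so
#' synthetic reads drawn from a reference also match the genome and the
#' annotation cascade can be exercised without external downloads.
#'
#' Stem-loops are 70-100 nt hairpin precursors; each carries a declared 5p
#' arm interval near its 5' end and a 3p arm interval near its 3' end
#' (0-based half-open, non-overlapping, 5p upstream), together with expected
#' expression levels for the two mature arms. Arm abundances are drawn
#' log-normal so that a few species dominate the library, as in real small
#' RNA data.
#'
#' @param config list of sizes; recognized fields (all optional):
#'   `genome_length` (default 10000), `n_stemloops` (3), `stemloop_length`
#'   (range, default c(70, 100)), `arm_length` (22), `arm_flank` (4),
#'   `n_trna`, `n_rrna`, `n_misc` (ncRNA sub-classes, default 2/1/1),
#'   `n_transposons` (1), `n_introns` (1), `n_mrnas` (1), `n_intergenic`
#'   (1), `ncrna_length` (75), `feature_length` (200), `n_transgenes` (0),
#'   `repeat_units` (30), `transgene_flank` (150), `expr_meanlog` (log(100)),
#'   `expr_sdlog` (2).
#' @param seed integer seed; the bundle is byte-identical for a fixed seed.
#' @return an object of class `reference_bundle`: a list with `genome`
#'   (character scalar), `categories` (named list in cascade order of named
#'   character vectors), `stemloops` (list of stem-loop specs with fields
#'   `id`, `sequence`, `arm5p`, `arm3p`, `mean_expr_5p`, `mean_expr_3p`),
#'   and `transgenes` (list with `id`, `sequence`, `repeat_start`,
#'   `repeat_end`, 1-based inclusive printed coordinates).
#' @export
build_toy_reference <- function(config = list(), seed = 1L) {
  cfg <- modifyList(list(
    genome_length = 10000L, n_stemloops = 3L, stemloop_length = c(70L, 100L),
    arm_length = 22L, arm_flank = 4L,
    n_trna = 2L, n_rrna = 1L, n_misc = 1L,
    n_transposons = 1L, n_introns = 1L, n_mrnas = 1L, n_intergenic = 1L,
    ncrna_length = 75L, feature_length = 200L,
    n_transgenes = 0L, repeat_units = 30L, transgene_flank = 150L,
    expr_meanlog = log(100), expr_sdlog = 2
  ), config)
  counts <- c(cfg$n_stemloops, cfg$n_trna, cfg$n_rrna, cfg$n_misc,
              cfg$n_transposons, cfg$n_introns, cfg$n_mrnas,
              cfg$n_intergenic)
  if (any(counts < 0)) stop("category sizes must be >= 0")
  if (cfg$n_stemloops < 1L) stop("at least one stem-loop is required")

  withr::local_seed(seed)

  # Draw stem-loop specs first so their lengths are known for sizing.
  sl_range <- seq(cfg$stemloop_length[1], cfg$stemloop_length[2])
  sl_len <- sl_range[sample.int(length(sl_range), cfg$n_stemloops,
                                replace = TRUE)]
  loci <- data.frame(
    category = c(rep("miRNA", cfg$n_stemloops),
                 rep("ncRNA", cfg$n_trna + cfg$n_rrna + cfg$n_misc),
                 rep("transposon", cfg$n_transposons),
                 rep("intron", cfg$n_introns),
                 rep("mRNA", cfg$n_mrnas),
                 rep("intergenic", cfg$n_intergenic)),
    id = c(sprintf("sl%02d", seq_len(cfg$n_stemloops)),
           sprintf("trna_%d", seq_len(cfg$n_trna)),
           sprintf("rrna_%d", seq_len(cfg$n_rrna)),
           sprintf("misc_%d", seq_len(cfg$n_misc)),
           sprintf("tp_%d", seq_len(cfg$n_transposons)),
           sprintf("intr_%d", seq_len(cfg$n_introns)),
           sprintf("mrna_%d", seq_len(cfg$n_mrnas)),
           sprintf("ig_%d", seq_len(cfg$n_intergenic))),
    len = c(sl_len,
            rep(cfg$ncrna_length, cfg$n_trna + cfg$n_rrna + cfg$n_misc),
            rep(cfg$feature_length,
                cfg$n_transposons + cfg$n_introns + cfg$n_mrnas +
                  cfg$n_intergenic)),
    stringsAsFactors = FALSE
  )

  min_gap <- 10L
  need <- sum(loci$len) + (nrow(loci) + 1L) * min_gap
  if (need > cfg$genome_length) {
    stop(sprintf(paste0("requested loci need %d nt but the genome is only ",
                        "%d nt; increase genome_length"),
                 need, cfg$genome_length))
  }

  # Plant loci left-to-right with random gaps; spare length is distributed
  # uniformly so loci never overlap and every reference is a genome
  # substring.
  spare <- cfg$genome_length - sum(loci$len) - (nrow(loci) + 1L) * min_gap
  gaps <- min_gap + diff(c(0L, sort(sample.int(spare + 1L, nrow(loci),
                                               replace = TRUE) - 1L)))
  seqs <- random_dna(loci$len)
  pieces <- character(0)
  pos <- 0L
  starts <- integer(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    pieces <- c(pieces, random_dna(gaps[i]), seqs[i])
    pos <- pos + gaps[i]
    starts[i] <- pos  # 0-based start of locus i
    pos <- pos + loci$len[i]
  }
  tail_len <- cfg$genome_length - pos
  pieces <- c(pieces, random_dna(tail_len))
  genome <- paste(pieces, collapse = "")

  categories <- lapply(setNames(nm = CATEGORY_ORDER), function(cat) {
    idx <- which(loci$category == cat)
    setNames(seqs[idx], loci$id[idx])
  })

  # Stem-loop arm intervals: 5p hugs the 5' end, 3p the 3' end, both well
  # clear of the hairpin middle so the split search has a clean optimum.
  stemloops <- lapply(seq_len(cfg$n_stemloops), function(i) {
    L <- sl_len[i]
    a5 <- c(cfg$arm_flank, cfg$arm_flank + cfg$arm_length)
    a3 <- c(L - cfg$arm_flank - cfg$arm_length, L - cfg$arm_flank)
    stopifnot(a5[2] < a3[1])
    list(id = loci$id[i], sequence = seqs[i],
         arm5p = a5, arm3p = a3,
         mean_expr_5p = rlnorm(1, cfg$expr_meanlog, cfg$expr_sdlog),
         mean_expr_3p = rlnorm(1, cfg$expr_meanlog, cfg$expr_sdlog))
  })

  transgenes <- lapply(seq_len(cfg$n_transgenes), function(i) {
    # flanks end in a repeat-breaking T-run so that leftmost best
    # alignments of repeat-derived reads cannot creep past the declared
    # repeat boundary via coincidental phase-extending flank bases
    flank5 <- paste0(random_dna(cfg$transgene_flank - 6L), "TTTTTT")
    flank3 <- paste0("TTTTTT", random_dna(cfg$transgene_flank - 6L))
    rep_seq <- strrep("CAG", cfg$repeat_units)
    list(id = sprintf("tg%d", i),
         sequence = paste0(flank5, rep_seq, flank3),
         repeat_start = nchar(flank5) + 1L,
         repeat_end = nchar(flank5) + nchar(rep_seq))
  })

  structure(list(genome = genome, categories = categories,
                 stemloops = stemloops, transgenes = transgenes,
                 config = cfg, seed = seed),
            class = "reference_bundle")
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat(sprintf("reference_bundle: %d nt genome\n", nchar(x$genome)))
  for (cat_name in names(x$categories)) {
    cat(sprintf("  %-10s %d reference(s)\n", cat_name,
                length(x$categories[[cat_name]])))
  }
  cat(sprintf("  %d transgene(s)\n", length(x$transgenes)))
  invisible(x)
}

#' Arm identifiers of a reference bundle
#'
#' @param bundle a `reference_bundle`.
#' @return character vector `<stemloop>_5p`, `<stemloop>_3p` in stem-loop
#'   order.
#' @export
arm_ids <- function(bundle) {
  unlist(lapply(bundle$stemloops, function(sl) paste0(sl$id, c("_5p", "_3p"))))
}

#' Write bundle references as multi-FASTA files
#'
#' One FASTA per category plus `genome.fa` and, when present,
#' `transgenes.fa`, under `dir`.
#'
#' @param bundle a `reference_bundle`.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
write_bundle_fasta <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  write_one <- function(seqs, file) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs),
                                filepath = file.path(dir, file))
    file.path(dir, file)
  }
  paths["genome"] <- write_one(c(genome = bundle$genome), "genome.fa")
  for (cat_name in names(bundle$categories)) {
    if (length(bundle$categories[[cat_name]]) > 0) {
      paths[cat_name] <- write_one(bundle$categories[[cat_name]],
                                   paste0(cat_name, ".fa"))
    }
  }
  if (length(bundle$transgenes) > 0) {
    tg <- setNames(vapply(bundle$transgenes, `[[`, "", "sequence"),
                   vapply(bundle$transgenes, `[[`, "", "id"))
    paths["transgenes"] <- write_one(tg, "transgenes.fa")
  }
  invisible(paths)
}
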