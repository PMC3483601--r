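#' Run the small RNA profiling pipeline end to end
#'
#' Orchestrates the stages from a single configuration: (optionally)
#' synthetic data generation, adapter trimming and length filtering,
#' hierarchical annotation, stem-loop arm splitting, differential
#' expression per declared contrast, correlation QC, head/body enrichment
#' classification when a two-tissue design is present, and the sCAG scan
#' when transgenes are declared. All tabular outputs are TSV under
#' `out_dir`; a YAML manifest records the package version, seed and
#' parameter values so any report can be reproduced from scratch. All
#' stages are pure functions of the declared inputs and the seed, so two
#' runs with the same configuration give byte-identical reports.
#'
#' @param config a named list or the path of a YAML file. Recognized
#'   fields: `out_dir` (required); `seed` (default 1); `adapter`,
#'   `min_overlap`, `min_length`, `max_mismatches`, `split_window`,
#'   `sig_threshold`, `scag_max_edits`, `scag_min_len` (parameters with
#'   the module defaults); `simulate` (list passed to the synthetic
#'   generator: `reference` config for [build_toy_reference()],
#'   `n_replicates`, `depth`, `dispersion`, `effect_map`, `error_rate`,
#'   `wobble`, `background_per_ref`, `spike` with `n`/`edit_profile`); or
#'   `fastq_dir` plus `reference_dir` and `sample_sheet` for pre-existing
#'   inputs; `contrasts`: list of lists with `name`, `condition_a`,
#'   `condition_b`, `reference_controls`.
#' @return invisibly, a list of in-memory stage results (`bundle`,
#'   `annotation`, `arm_counts`, `de`, `qc`, `enrichment`, `scag`,
#'   `paths`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(list(
    seed = 1L, adapter = "CTGTAGGCACCATCAAT", min_overlap = 5L,
    min_length = 18L, max_mismatches = 1L, split_window = 20L,
    sig_threshold = 0.01, scag_max_edits = 2L, scag_min_len = 15L
  ), config)
  if (is.null(cfg$out_dir)) stop("config error: out_dir is required")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  # --- inputs: simulate or load -------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim <- simulate_inputs(cfg)
    bundle <- sim$bundle
    samples <- sim$samples
    fastq <- sim$fastq
    contrasts <- cfg$contrasts %||% sim$contrasts
  } else {
    loaded <- load_inputs(cfg)
    bundle <- loaded$bundle
    samples <- loaded$samples
    fastq <- loaded$fastq
    contrasts <- cfg$contrasts
  }
  write.table(samples, file.path(cfg$out_dir, "sample_sheet.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # --- preprocess ---------------------------------------------------------
  pooled <- do.call(rbind, lapply(names(fastq$reads), function(s) {
    cbind(fastq$reads[[s]][, c("id", "seq")], sample = s)
  }))
  trimmed <- trim_adapter(pooled, cfg$adapter, min_overlap = cfg$min_overlap)
  trimmed$sample <- pooled$sample
  kept <- filter_by_length(trimmed, min_exclusive = cfg$min_length)

  # --- annotate -----------------------------------------------------------
  ann <- cascade_assign(kept, bundle, max_mismatches = cfg$max_mismatches)
  n_in <- table(factor(kept$sample, levels = ann$table$sample))
  conserved <- ann$table$total_matched + ann$table$unmatched ==
    as.integer(n_in)
  if (!all(conserved)) {
    warning("read-count conservation violated for sample(s): ",
            paste(ann$table$sample[!conserved], collapse = ", "))
  }
  paths["annotation"] <- file.path(cfg$out_dir, "annotation.tsv")
  write_annotation_tsv(ann$table, paths["annotation"])

  # --- arm assignment -----------------------------------------------------
  profiles <- profiles_from_assignments(ann$assignments, kept, bundle)
  arms <- arm_count_matrix(profiles, window = cfg$split_window)
  paths["arm_counts"] <- file.path(cfg$out_dir, "arm_counts.tsv")
  write.table(data.frame(arm = rownames(arms$counts), arms$counts,
                         check.names = FALSE),
              paths["arm_counts"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths["split_diagnostics"] <- file.path(cfg$out_dir,
                                          "split_diagnostics.tsv")
  write.table(arms$diagnostics, paths["split_diagnostics"], sep = "\t",
              quote = FALSE, row.names = FALSE)

  # --- differential expression -------------------------------------------
  de_results <- list()
  for (ct in contrasts %||% list()) {
    design <- contrast_design(ct$condition_a, ct$condition_b,
                              ct$reference_controls %||% character(0),
                              sig_threshold = cfg$sig_threshold)
    de <- de_table(arms$counts, design)
    de_results[[ct$name]] <- de
    p <- file.path(cfg$out_dir, paste0("de_", ct$name, ".tsv"))
    de_out <- de
    de_out$foldChange <- round(de_out$foldChange, 2)
    write.table(de_out, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[paste0("de_", ct$name)] <- p
  }

  # --- correlation QC -----------------------------------------------------
  qc <- NULL
  if (ncol(arms$counts) >= 3 && any(rowSums(arms$counts > 0) ==
                                    ncol(arms$counts))) {
    norm <- normalize_counts(arms$counts)
    controls <- samples$sample[samples$condition %in%
                                 c("uninduced", "control")]
    if (length(controls) < 2) controls <- colnames(norm)
    qc <- sample_correlation_qc(norm, control_ids = controls)
    paths["qc"] <- file.path(cfg$out_dir, "qc_correlations.tsv")
    write.table(data.frame(sample = names(qc), r = qc), paths["qc"],
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- head/body enrichment ----------------------------------------------
  enrichment <- NULL
  if (all(c("head", "body") %in% samples$tissue)) {
    heads <- samples$sample[samples$tissue == "head"]
    bodies <- samples$sample[samples$tissue == "body"]
    if (length(heads) >= 2 && length(bodies) >= 2) {
      design <- contrast_design(heads, bodies,
                                sig_threshold = cfg$sig_threshold)
      de <- de_table(arms$counts, design)
      enrichment <- classify_head_enrichment(de,
                                             threshold = cfg$sig_threshold)
      paths["enrichment"] <- file.path(cfg$out_dir, "enrichment.tsv")
      write.table(
        data.frame(arm = c(enrichment$enriched, enrichment$depleted),
                   class = c(rep("head_enriched",
                                 length(enrichment$enriched)),
                             rep("head_depleted",
                                 length(enrichment$depleted)))),
        paths["enrichment"], sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # --- sCAG scan ----------------------------------------------------------
  scag <- NULL
  if (length(bundle$transgenes) > 0) {
    tg <- bundle$transgenes[[1]]
    hit_rows <- list()
    summaries <- list()
    for (s in names(fastq$reads)) {
      sample_trimmed <- trimmed[trimmed$sample == s, , drop = FALSE]
      hits <- align_to_transgene(sample_trimmed, tg$sequence,
                                 repeat_region = tg,
                                 max_edits = cfg$scag_max_edits,
                                 min_len = cfg$scag_min_len)
      summaries[[s]] <- scag_summary(hits, tg, nchar(tg$sequence))
      if (nrow(hits)) hit_rows[[s]] <- cbind(sample = s, hits)
    }
    hits_all <- if (length(hit_rows)) do.call(rbind, hit_rows) else
      data.frame(sample = character(0))
    scag <- list(hits = hits_all, summaries = summaries)
    sp <- write_scag_report(hits_all, summaries, cfg$out_dir)
    paths["scag_hits"] <- sp["hits"]
    paths["scag_summary"] <- sp["summary"]
  }

  # --- manifest -----------------------------------------------------------
  manifest <- list(
    package = "mirarms",
    version = as.character(packageVersion("mirarms")),
    seed = cfg$seed,
    parameters = cfg[c("adapter", "min_overlap", "min_length",
                       "max_mismatches", "split_window", "sig_threshold",
                       "scag_max_edits", "scag_min_len")],
    simulate = cfg$simulate)
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))

  invisible(list(bundle = bundle, samples = samples,
                 annotation = ann$table, assignments = ann$assignments,
                 arm_counts = arms$counts, diagnostics = arms$diagnostics,
                 de = de_results, qc = qc, enrichment = enrichment,
                 scag = scag, paths = paths))
}

# Build synthetic inputs from the `simulate` block of a pipeline config.
simulate_inputs <- function(cfg) {
  sim <- modifyList(list(
    reference = list(), n_replicates = 2L, n_controls = 4L, depth = 2000,
    dispersion = 0.05, effect_map = list(), error_rate = 0, wobble = 1L,
    background_per_ref = 0L, spike = NULL
  ), cfg$simulate)
  sim$effect_map <- lapply(sim$effect_map, unlist)
  bundle <- build_toy_reference(sim$reference, seed = cfg$seed)
  nr <- sim$n_replicates
  nc <- sim$n_controls
  samples <- data.frame(
    sample = c(sprintf("ind%02d", seq_len(nr)),
               sprintf("uni%02d", seq_len(nr)),
               sprintf("ctl%02d", seq_len(nc))),
    genotype = c(rep("model", 2L * nr), rep("control", nc)),
    condition = c(rep("induced", nr), rep("uninduced", nr),
                  rep("control", nc)),
    tissue = "head", stringsAsFactors = FALSE)
  design <- simulation_design(samples, effect_map = sim$effect_map,
                              dispersion_map = sim$dispersion,
                              depth_map = sim$depth, seed = cfg$seed + 1L)
  counts <- simulate_count_matrix(design, bundle)
  fastq <- synthesize_fastq(counts, bundle, adapter = cfg$adapter,
                            error_rate = sim$error_rate,
                            seed = cfg$seed + 2L, wobble = sim$wobble,
                            out_dir = file.path(cfg$out_dir, "fastq"))
  if (sim$background_per_ref > 0L) {
    for (cat_name in c("ncRNA", "transposon", "intron", "mRNA",
                       "intergenic")) {
      if (length(bundle$categories[[cat_name]]) > 0) {
        fastq <- add_background_reads(fastq, bundle, cat_name,
                                      n = sim$background_per_ref,
                                      adapter = cfg$adapter,
                                      seed = cfg$seed + 3L)
      }
    }
  }
  if (!is.null(sim$spike) && length(bundle$transgenes) > 0) {
    fastq <- spike_repeat_reads(
      fastq, bundle$transgenes[[1]], n = sim$spike$n,
      edit_profile = unlist(sim$spike$edit_profile),
      adapter = cfg$adapter, seed = cfg$seed + 4L)
  }
  contrasts <- list(list(
    name = "induced_vs_uninduced",
    condition_a = samples$sample[samples$condition == "uninduced"],
    condition_b = samples$sample[samples$condition == "induced"],
    reference_controls = samples$sample[samples$condition == "control"]))
  list(bundle = bundle, samples = samples, fastq = fastq,
       contrasts = contrasts, truth = fastq$truth, counts = counts)
}

# Load FASTQ + FASTA references + sample sheet from disk.
load_inputs <- function(cfg) {
  stopifnot(!is.null(cfg$fastq_dir), !is.null(cfg$reference_dir),
            !is.null(cfg$sample_sheet))
  samples <- read.delim(cfg$sample_sheet, stringsAsFactors = FALSE)
  reads <- lapply(setNames(nm = samples$sample), function(s) {
    read_fastq(file.path(cfg$fastq_dir, paste0(s, ".fastq")))
  })
  read_fa <- function(name) {
    p <- file.path(cfg$reference_dir, paste0(name, ".fa"))
    if (!file.exists(p)) return(setNames(character(0), character(0)))
    x <- Biostrings::readDNAStringSet(p)
    setNames(as.character(x), names(x))
  }
  categories <- lapply(setNames(nm = CATEGORY_ORDER), read_fa)
  genome <- read_fa("genome")
  if (length(genome) != 1) stop("reference_dir must contain genome.fa")
  stemloops <- lapply(names(categories$miRNA), function(id) {
    seq <- categories$miRNA[[id]]
    list(id = id, sequence = seq, arm5p = NULL, arm3p = NULL)
  })
  tg_seqs <- read_fa("transgenes")
  transgenes <- lapply(names(tg_seqs), function(id) {
    tg <- list(id = id, sequence = tg_seqs[[id]])
    if (!is.null(cfg$repeat_regions[[id]])) {
      tg$repeat_start <- cfg$repeat_regions[[id]]$start
      tg$repeat_end <- cfg$repeat_regions[[id]]$end
    }
    tg
  })
  bundle <- structure(list(genome = unname(genome), categories = categories,
                           stemloops = stemloops, transgenes = transgenes),
                      class = "reference_bundle")
  list(bundle = bundle, samples = samples,
       fastq = list(reads = reads, truth = NULL))
}
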