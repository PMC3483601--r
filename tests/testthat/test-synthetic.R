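test_that("toy reference bundles satisfy their construction contract", {
  b <- build_toy_reference(list(n_stemloops = 2, n_trna = 1, n_rrna = 0,
                                n_misc = 0, genome_length = 5000),
                           seed = 1)
  expect_identical(names(b$categories),
                   c("miRNA", "ncRNA", "transposon", "intron", "mRNA",
                     "intergenic"))
  # every planted reference is a genome substring
  for (s in unlist(b$categories)) {
    expect_true(grepl(s, b$genome, fixed = TRUE))
  }
  # stem-loop invariants: 70-100 nt, 5p upstream of and disjoint from 3p
  for (sl in b$stemloops) {
    expect_true(nchar(sl$sequence) >= 70 && nchar(sl$sequence) <= 100)
    expect_lt(sl$arm5p[2], sl$arm3p[1])
    expect_lte(sl$arm3p[2], nchar(sl$sequence))
  }
  # transgene repeat coordinates are internally consistent
  b2 <- make_test_bundle()
  tg <- b2$transgenes[[1]]
  expect_lt(tg$repeat_start, tg$repeat_end)
  expect_lte(tg$repeat_end, nchar(tg$sequence))
  expect_identical(substr(tg$sequence, tg$repeat_start, tg$repeat_start + 5),
                   "CAGCAG")
})

test_that("bundle generation is deterministic and rejects oversized configs", {
  cfg <- list(n_stemloops = 3, n_transgenes = 1)
  expect_identical(build_toy_reference(cfg, seed = 7),
                   build_toy_reference(cfg, seed = 7))
  expect_false(identical(build_toy_reference(cfg, seed = 7),
                         build_toy_reference(cfg, seed = 8)))
  expect_error(build_toy_reference(list(n_stemloops = 50,
                                        genome_length = 1000)),
               "genome")
})

test_that("empty categories are kept and the cascade still runs", {
  b <- build_toy_reference(list(n_transposons = 0, n_introns = 0), seed = 2)
  expect_identical(length(b$categories$transposon), 0L)
  expect_true("transposon" %in% names(b$categories))
  reads <- data.frame(id = "r1",
                      seq = substr(b$categories$mRNA[[1]], 1, 22))
  ann <- cascade_assign(reads, b)
  expect_identical(ann$assignments$category, "mRNA")
  expect_identical(ann$table$transposon, 0L)
})

test_that("simulated counts follow the declared NB mean model", {
  b <- make_test_bundle(n_stemloops = 1)
  # zero expression everywhere -> all-zero matrix
  b0 <- b
  b0$stemloops[[1]]$mean_expr_5p <- 0
  b0$stemloops[[1]]$mean_expr_3p <- 0
  d <- make_test_design(b0)
  expect_true(all(simulate_count_matrix(d, b0) == 0))

  # a 4-fold condition effect shows up as a ~4x empirical mean ratio
  n <- 400
  samples <- data.frame(sample = sprintf("s%03d", 1:(2 * n)),
                        condition = rep(c("induced", "uninduced"), each = n))
  d4 <- simulation_design(samples,
                          effect_map = list(sl01_5p = c(induced = 4)),
                          dispersion_map = 0.1, depth_map = 300, seed = 11)
  cm <- simulate_count_matrix(d4, b)
  ratio <- mean(cm["sl01_5p", 1:n]) / mean(cm["sl01_5p", n + 1:n])
  expect_gt(ratio, 3.4)
  expect_lt(ratio, 4.6)
})

test_that("NB draws reproduce the stated mean-variance relationship", {
  b <- make_test_bundle(n_stemloops = 1)
  n <- 10000
  samples <- data.frame(sample = sprintf("s%05d", 1:n),
                        condition = "uninduced")
  for (alpha in c(0, 0.2)) {
    d <- simulation_design(samples, dispersion_map = alpha,
                           depth_map = 1000, seed = 21)
    cm <- simulate_count_matrix(d, b)
    x <- cm[1, ]
    mu <- mean(x)
    expected_var <- mu + alpha * mu^2
    # empirical variance within 3 standard errors of mu + alpha mu^2
    se_var <- sqrt((mean((x - mu)^4) - var(x)^2) / n)
    expect_lt(abs(var(x) - expected_var), 3 * se_var + 1e-9)
    if (alpha == 0) {
      expect_lt(abs(var(x) / mu - 1), 0.05)
    }
  }
})

test_that("simulation rejects invalid effect and dispersion maps", {
  b <- make_test_bundle()
  samples <- data.frame(sample = c("a", "b"),
                        condition = c("induced", "uninduced"))
  expect_error(simulation_design(samples, dispersion_map = -0.1),
               "non-negative")
  d <- simulation_design(samples, effect_map = list(nosuch_5p = c(induced = 2)))
  expect_error(simulate_count_matrix(d, b), "not in bundle")
})

test_that("synthesized FASTQ reads carry the adapter and exact counts", {
  b <- make_test_bundle(n_stemloops = 2)
  d <- make_test_design(b, depth = 200)
  cm <- simulate_count_matrix(d, b)
  fq <- synthesize_fastq(cm, b, error_rate = 0, seed = 3)
  for (s in colnames(cm)) {
    expect_identical(nrow(fq$reads[[s]]), sum(cm[, s]))
    expect_true(all(nchar(fq$reads[[s]]$seq) == 36))
  }
  # truth sidecar covers every read exactly once
  expect_identical(nrow(fq$truth), sum(cm))
  expect_false(any(duplicated(fq$truth$read_id)))
  # empty matrix -> empty FASTQ set
  fq0 <- synthesize_fastq(cm[, 0, drop = FALSE], b, seed = 3)
  expect_length(fq0$reads, 0)
  expect_error(synthesize_fastq(cm, b, adapter = "CTGXA"), "A/C/G/T")
  expect_error(synthesize_fastq(cm, b, error_rate = 0.7), "error_rate")
})

test_that("FASTQ writing and reading round-trip", {
  b <- make_test_bundle(n_stemloops = 2)
  d <- make_test_design(b, depth = 100)
  cm <- simulate_count_matrix(d, b)
  dir <- withr::local_tempdir()
  fq <- synthesize_fastq(cm, b, seed = 4, out_dir = dir)
  back <- read_fastq(file.path(dir, "ind1.fastq"))
  expect_identical(back$id, fq$reads[["ind1"]]$id)
  expect_identical(back$seq, fq$reads[["ind1"]]$seq)
  expect_true(file.exists(file.path(dir, "truth.tsv")))
})

test_that("spiked repeat reads are exact repeat substrings when edit-free", {
  b <- make_test_bundle(n_stemloops = 2)
  d <- make_test_design(b, depth = 50)
  cm <- simulate_count_matrix(d, b)
  fq <- synthesize_fastq(cm, b, seed = 5)
  tg <- b$transgenes[[1]]
  rep_seq <- substr(tg$sequence, tg$repeat_start, tg$repeat_end)

  expect_identical(spike_repeat_reads(fq, tg, n = 0), fq)

  sp <- spike_repeat_reads(fq, tg, n = 6, length_range = c(21, 21),
                           edit_profile = c("0" = 6), seed = 6)
  spiked <- sp$truth[sp$truth$origin_type == "scag", ]
  expect_identical(nrow(spiked), 6L * length(fq$reads))
  for (id in spiked$read_id[spiked$sample == "ind1"]) {
    insert <- substr(sp$reads[["ind1"]]$seq[sp$reads[["ind1"]]$id == id],
                     1, 21)
    expect_true(grepl(insert, rep_seq, fixed = TRUE) ||
                  grepl(oracle_revcomp(insert), rep_seq, fixed = TRUE))
  }
  expect_error(spike_repeat_reads(fq, tg, n = -1), ">= 0")
  expect_error(spike_repeat_reads(fq, tg, n = 2, length_range = c(10, 21)),
               "15")
})
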