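#' Build a stem-loop read profile from match hits
#'
#' Collects the alignment intervals of the reads retained for one
#' stem-loop. Hits are deduplicated by read id, keeping the best placement
#' (fewest mismatches, then smallest offset), so a read contributes exactly
#' one interval. Minus-strand hits are included as their interval on the
#' stem-loop.
#'
#' @param hits data.frame with columns `read_id`, `offset` (0-based start),
#'   `mismatches`, and either `width` or an implicit read length from
#'   `seq`/`end`.
#' @param stemloop the stem-loop sequence (or its length).
#' @param stemloop_id identifier used in reports.
#' @return list of class `stemloop_profile`: `stemloop_id`, `length`,
#'   `starts`, `ends` (parallel integer vectors, 0-based half-open),
#'   `total`.
#' @export
profile_stemloop <- function(hits, stemloop, stemloop_id = "stemloop") {
  L <- if (is.character(stemloop)) nchar(stemloop) else as.integer(stemloop)
  if (nrow(hits) == 0L) {
    return(structure(list(stemloop_id = stemloop_id, length = L,
                          starts = integer(0), ends = integer(0),
                          total = 0L), class = "stemloop_profile"))
  }
  if (is.null(hits$end)) {
    w <- if (!is.null(hits$width)) hits$width else nchar(hits$seq)
    hits$end <- hits$offset + w
  }
  if (any(hits$offset < 0 | hits$end > L | hits$offset >= hits$end)) {
    stop("hit interval exceeds stem-loop bounds")
  }
  if (is.null(hits$mismatches)) hits$mismatches <- 0L
  ord <- order(hits$read_id, hits$mismatches, hits$offset)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits$read_id), , drop = FALSE]
  structure(list(stemloop_id = stemloop_id, length = L,
                 starts = as.integer(hits$offset),
                 ends = as.integer(hits$end),
                 total = nrow(hits)), class = "stemloop_profile")
}

#' Choose the optimal 5p/3p split position of a stem-loop
#'
#' The stem-loop is iteratively split at every integer position within 20
#' nt of its middle (window clipped into `[1, L-1]`). For a candidate split
#' `s`, reads mapping entirely upstream (`end <= s`) count as `U`, reads
#' entirely downstream (`start >= s`) as `D`, and reads spanning the split
#' are discarded. The retained split maximizes `U + D`, i.e. makes the sum
#' of upstream and downstream reads nearest the total; `U` becomes the 5p
#' count and `D` the 3p count. Ties are broken by smallest distance to the
#' middle, then by the smaller position.
#'
#' @param profile a `stemloop_profile`.
#' @param window half-width of the split search window (default 20).
#' @return list of class `split_result`: `split`, `count5p` (U), `count3p`
#'   (D), `discarded` (= total - U - D), `total`.
#' @export
choose_split <- function(profile, window = 20L) {
  L <- profile$length
  mid <- L %/% 2L
  cand <- seq(max(1L, mid - window), min(L - 1L, mid + window))
  U <- vapply(cand, function(s) sum(profile$ends <= s), integer(1))
  D <- vapply(cand, function(s) sum(profile$starts >= s), integer(1))
  score <- U + D
  best <- which(score == max(score))
  best <- best[order(abs(cand[best] - mid), cand[best])][1L]
  s <- cand[best]
  structure(list(stemloop_id = profile$stemloop_id, split = s,
                 count5p = U[best], count3p = D[best],
                 discarded = profile$total - score[best],
                 total = profile$total),
            class = "split_result")
}

#' Assemble the arm count matrix across samples
#'
#' @param profiles named list (by sample) of named lists (by stem-loop id)
#'   of `stemloop_profile` objects.
#' @param window split search half-width passed to [choose_split()].
#' @return list with `counts` (integer matrix, rows `<stemloop>_5p` /
#'   `<stemloop>_3p`, one column per sample; stem-loops absent from a
#'   sample get zero counts) and `diagnostics` (data.frame per sample and
#'   stem-loop: split position, U, D, discarded).
#' @export
arm_count_matrix <- function(profiles, window = 20L) {
  samples <- names(profiles)
  sl_ids <- sort(unique(unlist(lapply(profiles, names))))
  rows <- as.vector(rbind(paste0(sl_ids, "_5p"), paste0(sl_ids, "_3p")))
  counts <- matrix(0L, nrow = length(rows), ncol = length(samples),
                   dimnames = list(rows, samples))
  diag_rows <- list()
  for (s in samples) {
    for (sl in names(profiles[[s]])) {
      sp <- choose_split(profiles[[s]][[sl]], window = window)
      counts[paste0(sl, "_5p"), s] <- sp$count5p
      counts[paste0(sl, "_3p"), s] <- sp$count3p
      diag_rows[[length(diag_rows) + 1L]] <- data.frame(
        sample = s, stemloop = sl, split = sp$split, count5p = sp$count5p,
        count3p = sp$count3p, discarded = sp$discarded, total = sp$total,
        stringsAsFactors = FALSE)
    }
  }
  diagnostics <- if (length(diag_rows)) do.call(rbind, diag_rows) else
    data.frame(sample = character(0), stemloop = character(0),
               split = integer(0), count5p = integer(0),
               count3p = integer(0), discarded = integer(0),
               total = integer(0))
  list(counts = counts, diagnostics = diagnostics)
}

# Build per-sample stem-loop profiles from cascade assignments (miRNA tier
# only); read length comes from the read table.
profiles_from_assignments <- function(assignments, reads, bundle) {
  reads <- as_read_frame(reads)
  if (is.null(reads$sample)) reads$sample <- "sample1"
  len_by_id <- setNames(nchar(reads$seq), reads$id)
  mir <- assignments[assignments$category == "miRNA", , drop = FALSE]
  sl_seqs <- bundle$categories$miRNA
  out <- list()
  for (s in unique(reads$sample)) {
    a <- mir[mir$sample == s, , drop = FALSE]
    out[[s]] <- lapply(setNames(nm = names(sl_seqs)), function(sl) {
      h <- a[a$ref_id == sl, , drop = FALSE]
      h$width <- len_by_id[h$read_id]
      profile_stemloop(h, sl_seqs[[sl]], stemloop_id = sl)
    })
  }
  out
}
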