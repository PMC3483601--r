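#' Trim the 3' adapter from raw reads
#'
#' Clips each read at the first occurrence of the full adapter. When the
#' full adapter is absent, a terminal prefix of the adapter of length at
#' least `min_overlap` that is a suffix of the read is clipped instead (the
#' longest such overlap wins); reads whose insert plus adapter exceeds the
#' sequencer read length carry only such truncated adapters. Reads with no
#' qualifying adapter are returned unchanged with `trimmed = FALSE` and,
#' by default, kept.
#'
#' @param reads data.frame with columns `id`, `seq` (A/C/G/T/N), or a
#'   character vector of sequences.
#' @param adapter adapter sequence, e.g. `"CTGTAGGCACCATCAAT"`.
#' @param min_overlap minimum terminal adapter-prefix overlap (default 5).
#' @param discard_untrimmed drop reads in which no adapter was found
#'   (default FALSE).
#' @return data.frame `id`, `seq` (clipped insert), `trimmed` (logical),
#'   `original_length`.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5L,
                         discard_untrimmed = FALSE) {
  stopifnot(nchar(adapter) >= 1, min_overlap >= 1)
  reads <- as_read_frame(reads)
  assert_dna(reads$seq, allow_n = TRUE, what = "read")
  assert_dna(adapter, allow_n = FALSE, what = "adapter")
  n <- nchar(reads$seq)
  pos <- regexpr(adapter, reads$seq, fixed = TRUE)
  clip <- ifelse(pos > 0L, pos - 1L, n)
  trimmed <- pos > 0L
  # Partial terminal adapter: longest adapter prefix that is a read suffix.
  todo <- which(!trimmed)
  max_k <- min(nchar(adapter) - 1L, max(n, 0L))
  if (max_k >= min_overlap) {
    for (k in seq(max_k, min_overlap, by = -1L)) {
      if (length(todo) == 0L) break
      pref <- substr(adapter, 1L, k)
      hit <- substr(reads$seq[todo], n[todo] - k + 1L, n[todo]) == pref &
        n[todo] >= k
      if (any(hit)) {
        clip[todo[hit]] <- n[todo[hit]] - k
        trimmed[todo[hit]] <- TRUE
        todo <- todo[!hit]
      }
    }
  }
  out <- data.frame(id = reads$id,
                    seq = substr(reads$seq, 1L, clip),
                    trimmed = trimmed, original_length = n,
                    stringsAsFactors = FALSE)
  if (discard_untrimmed) out <- out[out$trimmed, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Retain reads longer than a length cutoff
#'
#' The profiling cascade only considers reads of more than 18 nt; the
#' cutoff is exclusive (a 19-nt read is kept, an 18-nt read is removed).
#'
#' @param reads data.frame with a `seq` column.
#' @param min_exclusive exclusive minimum length (default 18).
#' @return the retained rows, original order preserved.
#' @export
filter_by_length <- function(reads, min_exclusive = 18L) {
  stopifnot(min_exclusive >= 0)
  out <- reads[nchar(reads$seq) > min_exclusive, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a both-strand reference index for mismatch-tolerant matching
#'
#' @param refs named character vector of reference sequences, or a
#'   data.frame with `id` and `seq` columns.
#' @return an opaque index of class `mismatch_index` usable with
#'   [find_matches()].
#' @export
build_index <- function(refs) {
  if (is.data.frame(refs)) refs <- setNames(refs$seq, refs$id)
  if (length(refs) > 0) {
    if (is.null(names(refs)) || any(names(refs) == "")) {
      stop("all references must be named")
    }
    if (anyDuplicated(names(refs))) stop("duplicate reference ids")
    if (any(nchar(refs) == 0)) stop("empty reference sequence")
  }
  structure(list(refs = Biostrings::DNAStringSet(refs),
                 lens = nchar(refs)),
            class = "mismatch_index")
}

empty_hits <- function() {
  data.frame(ref_id = character(0), offset = integer(0),
             strand = character(0), mismatches = integer(0),
             stringsAsFactors = FALSE)
}

match_one_strand <- function(pattern, index, max_mismatches, strand) {
  hits <- list()
  pat <- Biostrings::DNAString(pattern)
  w <- nchar(pattern)
  for (i in seq_along(index$refs)) {
    if (index$lens[i] < w) next
    m <- Biostrings::matchPattern(pat, index$refs[[i]],
                                  max.mismatch = max_mismatches,
                                  fixed = TRUE)
    if (length(m) == 0L) next
    starts <- Biostrings::start(m)
    mm <- vapply(starts, function(st) {
      Biostrings::neditStartingAt(pat, index$refs[[i]], starting.at = st,
                                  fixed = TRUE)
    }, integer(1))
    hits[[length(hits) + 1L]] <- data.frame(
      ref_id = names(index$refs)[i], offset = starts - 1L,
      strand = strand, mismatches = mm, stringsAsFactors = FALSE)
  }
  if (length(hits)) do.call(rbind, hits) else empty_hits()
}

#' Find all 0/1-mismatch placements of a query on both strands
#'
#' Returns every (reference, offset, strand) placement with Hamming
#' distance at most `max_mismatches`. Minus-strand hits are placements of
#' the reverse complement on the forward reference, reported in forward
#' coordinates. `N` in the query never counts as a match.
#'
#' @param query a single A/C/G/T/N sequence.
#' @param index a `mismatch_index` from [build_index()].
#' @param max_mismatches 0 or 1 (default 1).
#' @return data.frame `ref_id`, `offset` (0-based), `strand` (`"+"`/`"-"`),
#'   `mismatches`.
#' @export
find_matches <- function(query, index, max_mismatches = 1L) {
  stopifnot(inherits(index, "mismatch_index"), nchar(query) >= 1,
            max_mismatches %in% c(0L, 1L))
  if (length(index$refs) == 0L) return(empty_hits())
  plus <- match_one_strand(query, index, max_mismatches, "+")
  minus <- match_one_strand(revcomp(query), index, max_mismatches, "-")
  out <- rbind(plus, minus)
  out <- out[out$mismatches <= max_mismatches, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Best single placement per sequence: fewest mismatches, then plus strand,
# then lexicographically smallest ref id, then smallest offset. Returns one
# row (or NULL if no hit).
best_hit <- function(query, index, max_mismatches = 1L) {
  hits <- find_matches(query, index, max_mismatches)
  if (nrow(hits) == 0L) return(NULL)
  ord <- order(hits$mismatches, hits$strand != "+", hits$ref_id,
               hits$offset)
  hits[ord[1L], , drop = FALSE]
}

#' Export match hits as a 1-based TSV table
#'
#' @param hits data.frame from [find_matches()] with an extra `read_id`
#'   column.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- hits
  out$offset_1based <- out$offset + 1L
  out$offset <- NULL
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
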