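#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor dnbinom dpois median optim p.adjust rbinom rlnorm
#'   rnbinom rpois runif var
#' @importFrom utils write.table read.delim packageVersion
NULL

# The six mutually exclusive annotation tiers, in cascade order.
CATEGORY_ORDER <- c("miRNA", "ncRNA", "transposon", "intron", "mRNA",
                    "intergenic")

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x character vector of A/C/G/T/N sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random DNA of given lengths; relies on the caller having seeded the RNG.
random_dna <- function(lengths) {
  vapply(lengths, function(n) {
    paste(sample(DNA_ALPHABET, n, replace = TRUE), collapse = "")
  }, character(1))
}

# Draw one element uniformly; safe when x has length 1 (unlike sample()).
sample_one <- function(x) x[sample.int(length(x), 1L)]

# Substitute exactly `k` positions of `seq` with different bases.
mutate_bases <- function(seq, k, positions = NULL) {
  if (k == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  if (is.null(positions)) {
    positions <- sample.int(length(chars), k)
  }
  for (p in positions) {
    chars[p] <- sample(setdiff(DNA_ALPHABET, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

assert_dna <- function(x, allow_n = TRUE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside %s: e.g. '%s'",
                 what, if (allow_n) "A/C/G/T/N" else "A/C/G/T",
                 x[which(bad)[1L]]), call. = FALSE)
  }
  invisible(x)
}

# Normalize a read container to data.frame(id, seq); accepts a character
# vector (ids from names or generated) or a data.frame with id/seq columns.
as_read_frame <- function(reads) {
  if (is.character(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("read", seq_along(reads))
    return(data.frame(id = ids, seq = unname(reads),
                      stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  reads
}
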