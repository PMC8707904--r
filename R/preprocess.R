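## Adapter removal and basic read QC (cutadapt-style 3' trim).

#' Trim a 3' adapter from reads
#'
#' Finds the lowest-error occurrence of a prefix of the adapter at the 3'
#' end of each read (substitution errors only), requiring at least
#' `min_overlap` compared bases and an error fraction of at most `max_err`;
#' ties are broken in favour of the longest match. The read and its quality
#' string are truncated at the match start; reads without a match are
#' returned unchanged.
#'
#' @param reads a single read (`list(id=, mate=, seq=, qual=)`) or a read
#'   set data.frame with `seq` and `qual` columns.
#' @param adapter adapter sequence (non-empty).
#' @param min_overlap minimum compared bases (default 3, the classical
#'   cutadapt default).
#' @param max_err maximum error fraction (default 0.1).
#' @return the trimmed read / read set, same shape as the input.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 3L, max_err = 0.1) {
  if (!nzchar(adapter)) stop_fmt("adapter must be non-empty")
  if (max_err < 0 || max_err >= 0.5) stop_fmt("max_err must be in [0, 0.5)")
  single <- !is.data.frame(reads)
  df <- if (single) data.frame(seq = reads$seq, qual = reads$qual,
                               stringsAsFactors = FALSE) else reads
  keep <- cpp_trim_lengths(df$seq, toupper(adapter), as.integer(min_overlap),
                           max_err)
  df$seq <- substring(df$seq, 1L, keep)
  df$qual <- substring(df$qual, 1L, keep)
  if (single) {
    reads$seq <- df$seq
    reads$qual <- df$qual
    reads
  } else df
}

#' Length-filter mate pairs
#'
#' Drops a pair when either trimmed mate is shorter than `min_len`.
#'
#' @param pairs list with data.frames `r1`, `r2` (one row per pair).
#' @param min_len minimum mate length (default 30).
#' @return the filtered pair list.
#' @export
qc_filter <- function(pairs, min_len = 30L) {
  keep <- nchar(pairs$r1$seq) >= min_len & nchar(pairs$r2$seq) >= min_len
  list(r1 = pairs$r1[keep, , drop = FALSE],
       r2 = pairs$r2[keep, , drop = FALSE])
}
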