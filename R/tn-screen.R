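## Transposon screen of the unmapped pool: keep reads that share enough
## canonical k-mers with the cassette. Two hits require >= k_scr + 1 genuine
## cassette bases, so a lone chance k-mer in an error-bearing read is not
## enough to retain it.

#' Screen reads for transposon sequence
#'
#' Keeps a read when at least `min_hits` of its k-mer positions carry a
#' canonical k-mer that occurs in the cassette. Input order is preserved.
#'
#' @param unmapped read set data.frame (the unmapped pool).
#' @param cas a [cassette_record()].
#' @param k_scr screening k-mer size (default 21).
#' @param min_hits minimum shared k-mer count (default 2).
#' @return the retained read set, with a `tn_kmer_hits` column appended.
#' @export
screen_reads <- function(unmapped, cas, k_scr = 21L, min_hits = 2L) {
  if (is.null(cas$seq) || !nzchar(cas$seq)) stop_fmt("empty cassette")
  if (nrow(unmapped) == 0L) {
    unmapped$tn_kmer_hits <- integer(0)
    return(unmapped)
  }
  hits <- cpp_screen_counts(unmapped$seq, cas$seq, as.integer(k_scr))
  out <- unmapped[hits >= min_hits, , drop = FALSE]
  out$tn_kmer_hits <- hits[hits >= min_hits]
  rownames(out) <- NULL
  out
}

#' Add mates of screened reads
#'
#' Optionally enriches the screened set with the mates of kept reads even
#' when the mate itself carries no cassette k-mer, lengthening the genomic
#' flanks available to the assembler. Duplicates are never emitted.
#'
#' @param kept screened read set (from [screen_reads()]).
#' @param all_unmapped read set holding all unmapped reads of both mates.
#' @param enabled logical flag; `FALSE` returns `kept` unchanged.
#' @return the (possibly) extended read set.
#' @export
screen_mates <- function(kept, all_unmapped, enabled = TRUE) {
  if (!enabled || nrow(kept) == 0L) return(kept)
  want <- paste(all_unmapped$id, 3L - all_unmapped$mate) %in%
    paste(kept$id, kept$mate)
  mates <- all_unmapped[want, , drop = FALSE]
  already <- paste(mates$id, mates$mate) %in% paste(kept$id, kept$mate)
  mates <- mates[!already, , drop = FALSE]
  if (nrow(mates)) {
    mates$tn_kmer_hits <- 0L
    kept <- rbind(kept, mates[, names(kept), drop = FALSE])
  }
  rownames(kept) <- NULL
  kept
}
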