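## Seed-and-extend local alignment producing HSPs (high-scoring segment
## pairs), the pipeline's blastn-like primitive. Subjects are a single
## genome and a single cassette, so plain score / length / identity
## thresholds replace E-value statistics.

#' Default alignment parameters
#'
#' Integer scoring +1/-2/-2 with an 11-base exact seed (the classical
#' blastn word size, short enough that >= 30 bp genomic flanks on junction
#' contigs are found), ungapped X-drop extension and a banded gapped
#' extension around the best ungapped core.
#'
#' @param seed_len exact seed length.
#' @param match match score.
#' @param mismatch mismatch penalty (positive magnitude).
#' @param gap gap penalty per base (positive magnitude).
#' @param xdrop ungapped extension X-drop threshold.
#' @param min_len minimum alignment length (columns) of a reported HSP.
#' @param min_identity minimum identity of a reported HSP.
#' @param band half-width of the banded gapped extension.
#' @return a named list of parameters.
#' @export
hsp_params <- function(seed_len = 11L, match = 1L, mismatch = 2L, gap = 2L,
                       xdrop = 20L, min_len = 30L, min_identity = 0.90,
                       band = 8L) {
  list(seed_len = as.integer(seed_len), match = as.integer(match),
       mismatch = as.integer(mismatch), gap = as.integer(gap),
       xdrop = as.integer(xdrop), min_len = as.integer(min_len),
       min_identity = min_identity, band = as.integer(band))
}

#' Find HSPs between a query and a subject
#'
#' Exact `seed_len`-mer seeds on both strands are extended ungapped under an
#' X-drop rule; cores are then re-aligned with a banded gapped local
#' alignment and HSPs passing `min_len` and `min_identity` are reported,
#' sorted by descending score (ties by subject start, then query start).
#' Subject intervals are always on the forward subject strand; minus-strand
#' HSPs have mirrored query intervals.
#'
#' @param query a contig (data.frame row or `list(id=, seq=)`).
#' @param subject a [genome_record()] or [cassette_record()].
#' @param params alignment parameters from [hsp_params()].
#' @return HSP data.frame with columns `q_id`, `q_start`, `q_end`, `s_id`,
#'   `s_start`, `s_end`, `strand`, `score`, `length`, `identity`.
#' @export
find_hsps <- function(query, subject, params = hsp_params()) {
  res <- cpp_find_hsps(query$seq, subject$seq, params$seed_len,
                       params$match, params$mismatch, params$gap,
                       params$xdrop, params$min_len, params$min_identity,
                       params$band)
  n <- length(res$q_start)
  data.frame(q_id = rep(query$id %||% "query", n),
             q_start = as.integer(res$q_start),
             q_end = as.integer(res$q_end),
             s_id = rep(subject$id %||% "subject", n),
             s_start = as.integer(res$s_start),
             s_end = as.integer(res$s_end),
             strand = as.character(res$strand),
             score = as.integer(res$score),
             length = as.integer(res$length),
             identity = as.numeric(res$identity), stringsAsFactors = FALSE)
}

# Batch HSP search of many contigs against one subject; the subject seed
# index is built a single time.
find_hsps_batch <- function(contigs, subject, params = hsp_params()) {
  res <- cpp_find_hsps_multi(contigs$seq, subject$seq, params$seed_len,
                             params$match, params$mismatch, params$gap,
                             params$xdrop, params$min_len,
                             params$min_identity, params$band)
  lapply(seq_along(res), function(i) {
    r <- res[[i]]
    n <- length(r$q_start)
    data.frame(q_id = rep(contigs$id[i], n),
               q_start = as.integer(r$q_start), q_end = as.integer(r$q_end),
               s_id = rep(subject$id %||% "subject", n),
               s_start = as.integer(r$s_start), s_end = as.integer(r$s_end),
               strand = as.character(r$strand), score = as.integer(r$score),
               length = as.integer(r$length),
               identity = as.numeric(r$identity), stringsAsFactors = FALSE)
  })
}

#' Select the best non-overlapping HSPs of one query
#'
#' Greedy selection by score: an HSP is kept when its query interval
#' overlaps every previously kept HSP by at most `max_q_overlap` bases.
#'
#' @param hsps HSP data.frame from [find_hsps()] (one query).
#' @param max_q_overlap maximum pairwise query overlap (default 5).
#' @return the selected subset, in the original score order.
#' @export
best_nonoverlapping <- function(hsps, max_q_overlap = 5L) {
  if (nrow(hsps) <= 1L) return(hsps)
  ord <- order(-hsps$score, hsps$s_start, hsps$q_start)
  hsps <- hsps[ord, , drop = FALSE]
  keep <- logical(nrow(hsps))
  for (i in seq_len(nrow(hsps))) {
    ok <- TRUE
    for (j in which(keep)) {
      ov <- min(hsps$q_end[i], hsps$q_end[j]) -
        max(hsps$q_start[i], hsps$q_start[j]) + 1L
      if (ov > max_q_overlap) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  out <- hsps[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
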