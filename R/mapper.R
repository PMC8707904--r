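## Read classification against the reference genome: canonical k-mer seeds
## vote for a (diagonal, strand), which is verified by a banded local
## alignment. Junction reads, whose best local alignment covers only part of
## the read, fall below the coverage threshold and land in the unmapped
## pool -- the pool from which insertion junctions are later assembled.

#' Build a canonical k-mer index of a genome
#'
#' Maps every canonical k-mer to the forward-strand positions of its
#' occurrences; circular genomes also index the wrap-around k-mers.
#'
#' @param g a [genome_record()].
#' @param k_map odd k-mer size in `[11, 31]` (default 21: long enough to be
#'   unique in a multi-megabase genome, short enough to tolerate ~1% read
#'   errors).
#' @return an object of class `kmer_index`.
#' @export
build_index <- function(g, k_map = 21L) {
  k_map <- as.integer(k_map)
  if (k_map < 11L || k_map > 31L || k_map %% 2L == 0L)
    stop_fmt("k_map must be odd and in [11, 31]")
  if (k_map >= nchar(g$seq))
    stop_fmt("k_map %d not smaller than genome length %d", k_map,
             nchar(g$seq))
  structure(list(genome = g, k = k_map), class = "kmer_index")
}

#' Query index positions of k-mers
#'
#' @param idx a [build_index()] object.
#' @param kmers character vector of k-mers (strand-insensitive lookup).
#' @return list of sorted 1-based forward-strand start positions.
#' @export
index_positions <- function(idx, kmers) {
  res <- cpp_index_query(idx$genome$seq, idx$k, idx$genome$circular,
                         as.character(kmers))
  names(res) <- as.character(kmers)
  res
}

#' Map reads against the reference
#'
#' Each read votes with its canonical k-mer seed hits for the best
#' (diagonal, strand), which is verified by a banded local alignment
#' (match +1, mismatch -1, gap -1, band `band`). A read is mapped when the
#' alignment identity is at least `min_identity` over at least `min_cov` of
#' the read; everything else -- including genome--cassette junction reads,
#' whose alignment covers only the genomic part -- is unmapped.
#'
#' @param reads read set data.frame (columns `id`, `mate`, `seq`).
#' @param idx a [build_index()] object.
#' @param min_identity minimum alignment identity (default 0.90).
#' @param min_cov minimum fraction of the read covered (default 0.90).
#' @param band banded-alignment half width (default 8).
#' @return data.frame with columns `read_id`, `mate`, `status`
#'   (`mapped`/`unmapped`), `ref_pos`, `strand`, `identity`.
#' @export
map_reads <- function(reads, idx, min_identity = 0.90, min_cov = 0.90,
                      band = 8L) {
  res <- cpp_map_reads(reads$seq, idx$genome$seq, idx$k,
                       idx$genome$circular, min_identity, min_cov,
                       as.integer(band))
  data.frame(read_id = reads$id, mate = reads$mate,
             status = ifelse(res$mapped == 1L, "mapped", "unmapped"),
             ref_pos = res$ref_pos, strand = res$strand,
             identity = res$identity, stringsAsFactors = FALSE)
}

#' @rdname map_reads
#' @param r a single read (`list(id=, mate=, seq=, ...)`).
#' @return `map_read` returns a one-row MapResult data.frame.
#' @export
map_read <- function(r, idx, min_identity = 0.90, min_cov = 0.90,
                     band = 8L) {
  df <- data.frame(id = r$id, mate = r$mate %||% 1L, seq = r$seq,
                   stringsAsFactors = FALSE)
  map_reads(df, idx, min_identity, min_cov, band)
}
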