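## Desk-scale De Bruijn assembly of the transposon-containing read pool.
## k is chosen by maximizing the number of distinct "solid" canonical k-mers
## (abundance >= 2), and unitigs -- maximal non-branching paths of the
## bidirected graph of solid k-mers -- are emitted without any bubble or tip
## clipping beyond the abundance filter, keeping the assembler verifiable
## against a hand-computed graph.

#' Choose an assembly k-mer size
#'
#' For each candidate k, counts the distinct canonical k-mers with abundance
#' at least 2 ("solid" k-mers) and returns the k maximizing that count; ties
#' go to the smallest k.
#'
#' @param reads read set data.frame.
#' @param k_grid candidate odd k values, each at most the shortest read.
#' @return the selected k.
#' @export
choose_k <- function(reads, k_grid) {
  k_grid <- as.integer(k_grid)
  if (length(k_grid) == 0L) stop_fmt("k_grid must be non-empty")
  if (any(k_grid > 31L) || any(k_grid %% 2L == 0L))
    stop_fmt("k values must be odd and <= 31")
  if (nrow(reads) == 0L) stop_fmt("no reads to assemble")
  if (any(k_grid > min(nchar(reads$seq))))
    stop_fmt("every k in k_grid must be <= the shortest read (%d)",
             min(nchar(reads$seq)))
  counts <- cpp_solid_counts(reads$seq, k_grid, 2L)
  if (all(counts == 0L))
    stop_fmt("assembly infeasible: no solid k-mers at any candidate k")
  best <- max(counts)
  min(k_grid[counts == best])
}

#' Assemble unitigs from reads
#'
#' Builds the bidirected De Bruijn graph on canonical `k_asm`-mers with
#' abundance at least `min_abund` and emits maximal non-branching paths of
#' length at least `k_asm + 10`, each in canonical orientation (the
#' lexicographically smaller of the sequence and its reverse complement),
#' sorted by sequence for deterministic output.
#'
#' @param reads read set data.frame.
#' @param k_asm odd assembly k-mer size.
#' @param min_abund minimum k-mer abundance (default 2; drops most
#'   error-induced k-mers at moderate coverage).
#' @return contig set data.frame with columns `id`, `seq`, `mean_abund`,
#'   `n_kmers`.
#' @export
build_unitigs <- function(reads, k_asm, min_abund = 2L) {
  k_asm <- as.integer(k_asm)
  if (k_asm %% 2L == 0L) stop_fmt("k_asm must be odd")
  if (k_asm > 31L) stop_fmt("k_asm must be <= 31")
  if (min_abund < 1L) stop_fmt("min_abund must be >= 1")
  res <- cpp_build_unitigs(reads$seq, k_asm, as.integer(min_abund))
  n <- length(res$seq)
  data.frame(id = if (n) sprintf("utg%05d", seq_len(n)) else character(0),
             seq = as.character(res$seq),
             mean_abund = as.numeric(res$mean_abund),
             n_kmers = as.integer(res$n_kmers), stringsAsFactors = FALSE)
}
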