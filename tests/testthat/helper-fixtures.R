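# Shared fixture builders. Everything is generated in code under fixed
# seeds; no binary fixtures are stored.

rand_dna <- function(n, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

reads_df <- function(seqs, ids = sprintf("r%d", seq_along(seqs)),
                     mate = 1L) {
  data.frame(id = ids, mate = mate, seq = seqs, qual = strrep("I", nchar(seqs)),
             stringsAsFactors = FALSE)
}

# error-free reads tiling a sequence; each start is emitted twice so every
# k-mer (including the terminal ones) clears an abundance-2 solidity cutoff
tile_reads <- function(seq, len = 100L, step = 5L) {
  starts <- seq(1L, nchar(seq) - len + 1L, by = step)
  starts <- rep(starts, each = 2L)
  reads_df(substring(seq, starts, starts + len - 1L))
}

write_tmp_fasta <- function(records, path = tempfile(fileext = ".fasta")) {
  write_fasta(records, path)
  path
}

write_tmp_fastq <- function(df, path = tempfile(fileext = ".fastq"),
                            mate = 1L) {
  con <- file(path, "wb")
  lines <- as.vector(rbind(paste0("@", df$id, "/", mate), df$seq, "+",
                           df$qual))
  writeLines(lines, con, sep = "\n")
  close(con)
  path
}

# scatter substitutions into a sequence, keeping at least one error-free
# island of >= 12 bases so a word-seeded aligner has an anchor
plant_errors <- function(x, nerr, lo = 5L) {
  n <- nchar(x)
  if (nerr == 0L) return(x)
  repeat {
    pos <- sort(sample(lo:(n - 5), nerr))
    if (max(diff(c(0L, pos, n + 1L))) - 1L >= 12L) break
  }
  for (p in pos)
    substr(x, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(x, p, p)), 1)
  x
}

# brute-force semi-global 3' adapter scan (substitutions only): reference
# oracle for trim_adapter
trim_oracle <- function(seq, adapter, min_overlap = 3L, max_err = 0.1) {
  n <- nchar(seq)
  alen <- nchar(adapter)
  best_off <- NA_integer_
  best_frac <- Inf
  for (off in seq_len(n)) {
    m <- min(n - off + 1L, alen)
    if (m < min_overlap) break
    s <- substring(seq, off, off + m - 1L)
    a <- substring(adapter, 1L, m)
    err <- sum(strsplit(s, "")[[1]] != strsplit(a, "")[[1]])
    frac <- err / m
    if (frac <= max_err && frac < best_frac - 1e-12) {
      best_frac <- frac
      best_off <- off
    }
  }
  if (is.na(best_off)) n else best_off - 1L
}

# independent local-alignment oracle (Biostrings dynamic programming)
sw_score <- function(q, s, match = 1, mismatch = -2, gap = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  a1 <- Biostrings::pairwiseAlignment(q, s, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = gap)
  a2 <- Biostrings::pairwiseAlignment(revcomp(q), s, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = gap)
  max(Biostrings::score(a1), Biostrings::score(a2))
}

# exhaustive mapped/unmapped oracle at the mapper's thresholds: the best
# local alignment (match +1, mismatch -1, gap -1) on either strand must
# reach min_identity over min_cov of the read
map_status_oracle <- function(read, genome, min_identity = 0.9,
                              min_cov = 0.9) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  best <- NULL
  for (q in c(read, revcomp(read))) {
    a <- Biostrings::pairwiseAlignment(q, genome, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 1)
    if (is.null(best) || Biostrings::score(a) > Biostrings::score(best))
      best <- a
  }
  cols <- Biostrings::nchar(best)
  if (cols == 0) return("unmapped")
  ident <- Biostrings::nmatch(best) / cols
  cov <- (Biostrings::end(Biostrings::pattern(best)) -
            Biostrings::start(Biostrings::pattern(best)) + 1) / nchar(read)
  if (ident >= min_identity && cov >= min_cov) "mapped" else "unmapped"
}

# enumeration of canonical k-mers of a string (R-side, for conservation
# checks)
kmers_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  fw <- substring(seq, 1:(n - k + 1), k:n)
  rc <- revcomp(fw)
  unique(pmin(fw, rc))
}
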