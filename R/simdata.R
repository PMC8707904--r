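## Seeded simulation of mutant genomes and Illumina-style paired-end
## libraries. The defaults emulate the sequencing design the pipeline was
## built for: sonication to ~350 bp fragments and 2x150 bp paired-end reads,
## with a canonical 9 bp Tn5 target-site duplication at each insertion.

#' Simulation configuration
#'
#' @param genome_len reference length in bases.
#' @param gc GC fraction of the simulated genome (default 0.64, typical of
#'   the high-GC soil bacteria this pipeline targets).
#' @param n_insertions number of cassette insertions per mutant.
#' @param cassette_len cassette length in bases.
#' @param tsd_len target-site duplication length (9 bp is canonical for Tn5;
#'   0 disables the duplication).
#' @param frag_mean,frag_sd fragment-length distribution (bases); fragments
#'   are Normal(frag_mean, frag_sd), truncated to the representable range.
#' @param read_len read length in bases.
#' @param coverage fold coverage of the mutant genome.
#' @param err_rate per-base substitution probability (no indels).
#' @param adapter 3' adapter sequence appearing by read-through when a
#'   fragment is shorter than the read; empty string disables read-through.
#' @param seed integer seed; all simulator randomness derives from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(genome_len = 100000L, gc = 0.64, n_insertions = 1L,
                       cassette_len = 3000L, tsd_len = 9L, frag_mean = 350,
                       frag_sd = 50, read_len = 150L, coverage = 50,
                       err_rate = 0.01, adapter = "", seed = 1L) {
  cfg <- list(genome_len = as.integer(genome_len), gc = gc,
              n_insertions = as.integer(n_insertions),
              cassette_len = as.integer(cassette_len),
              tsd_len = as.integer(tsd_len), frag_mean = frag_mean,
              frag_sd = frag_sd, read_len = as.integer(read_len),
              coverage = coverage, err_rate = err_rate,
              adapter = toupper(adapter), seed = as.integer(seed))
  if (cfg$gc < 0 || cfg$gc > 1) stop_fmt("gc must be in [0,1]")
  if (cfg$read_len > cfg$frag_mean + 4 * cfg$frag_sd)
    stop_fmt("read_len %d exceeds frag_mean + 4*frag_sd", cfg$read_len)
  if (cfg$coverage <= 0) stop_fmt("coverage must be positive")
  if (cfg$err_rate < 0 || cfg$err_rate >= 0.2)
    stop_fmt("err_rate must be in [0, 0.2)")
  if (cfg$tsd_len < 0 || cfg$tsd_len > 20)
    stop_fmt("tsd_len must be in [0, 20]")
  structure(cfg, class = "sim_config")
}

random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Simulate a random bacterial-like genome
#'
#' Bases are i.i.d. with P(G) + P(C) = `gc`. Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return a [genome_record()] with id `"simref"`.
#' @export
make_genome <- function(cfg) {
  if (cfg$genome_len < 1000L) stop_fmt("genome_len must be >= 1000")
  seq <- with_seed(cfg$seed, random_dna(cfg$genome_len, cfg$gc))
  genome_record("simref", seq, circular = FALSE)
}

#' Simulate a random transposon cassette
#'
#' A seeded random sequence standing in for a real cassette; for real runs
#' the user supplies the actual cassette FASTA instead.
#'
#' @param cfg a [sim_config()].
#' @return a [cassette_record()] with id `"simcassette"`.
#' @export
make_cassette <- function(cfg) {
  seq <- with_seed(cfg$seed + 101L, random_dna(cfg$cassette_len, 0.5))
  cassette_record("simcassette", seq)
}

#' Insert a cassette into a genome with target-site duplication
#'
#' At each position p the bases `[p, p + tsd_len - 1]` are duplicated so they
#' flank the cassette (left copy, cassette, right copy), mimicking the
#' duplication Tn5 leaves at its target site. Positions must be separated by
#' more than `cassette_len + 2 * frag_mean` so that insertions never share
#' fragments.
#'
#' @param g a [genome_record()].
#' @param cas a [cassette_record()].
#' @param positions integer vector of 1-based insertion positions (first base
#'   of the target-site duplication).
#' @param cfg a [sim_config()] (supplies `tsd_len`, spacing check and the
#'   seed used when orientations are drawn).
#' @param orientations optional `+`/`-` vector, one per position; drawn from
#'   the seeded generator when omitted.
#' @param mutant_id identifier recorded in the truth table.
#' @return `list(genome = <mutant genome_record>, truth = <data.frame>)`;
#'   the truth table has columns `mutant_id`, `ref_id`, `position`,
#'   `orientation`, `tsd_len`.
#' @export
insert_cassette <- function(g, cas, positions, cfg, orientations = NULL,
                            mutant_id = "mutant1") {
  positions <- as.integer(positions)
  tsd <- cfg$tsd_len
  L <- nchar(g$seq)
  if (any(positions < 1L) || any(positions + tsd - 1L > L))
    stop_fmt("insertion position out of range")
  if (length(positions) > 1L) {
    d <- diff(sort(positions))
    if (any(d <= cfg$cassette_len + 2 * cfg$frag_mean))
      stop_fmt("insertion positions closer than cassette_len + 2*frag_mean")
  }
  if (is.null(orientations)) {
    orientations <- with_seed(cfg$seed + 1L,
                              sample(c("+", "-"), length(positions),
                                     replace = TRUE))
  }
  stopifnot(length(orientations) == length(positions),
            all(orientations %in% c("+", "-")))
  ord <- order(positions, decreasing = TRUE)
  seq <- g$seq
  for (i in ord) {
    p <- positions[i]
    ins <- if (orientations[i] == "+") cas$seq else revcomp(cas$seq)
    seq <- paste0(substr(seq, 1L, p + tsd - 1L), ins,
                  substr(seq, p, nchar(seq)))
  }
  truth <- data.frame(mutant_id = mutant_id, ref_id = g$id,
                      position = positions, orientation = orientations,
                      tsd_len = tsd, stringsAsFactors = FALSE)
  truth <- truth[order(truth$position), , drop = FALSE]
  rownames(truth) <- NULL
  mut <- genome_record(paste0(g$id, "|", mutant_id), seq,
                       circular = g$circular)
  list(genome = mut, truth = truth)
}

apply_substitutions <- function(seqs, err_rate) {
  if (err_rate <= 0) return(seqs)
  n_err <- rbinom(length(seqs), nchar(seqs), err_rate)
  idx <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(length(s), n_err[i])
    for (p in pos) {
      s[p] <- sample(setdiff(bases, s[p]), 1L)
    }
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Simulate a paired-end read library
#'
#' Fragments are drawn with Normal(frag_mean, frag_sd) lengths (rounded,
#' truncated to the representable range) and uniform start positions
#' (wrapping on circular genomes). Mate 1 is the first `read_len` bases of
#' the fragment; mate 2 is the reverse complement of its last `read_len`
#' bases. When an adapter is configured, fragments are allowed to be shorter
#' than the read and the 3' ends read through into adapter sequence.
#' Substitution errors are applied per base at `err_rate`; qualities are a
#' constant Q40 ("I"). The pair count is
#' `round(coverage * genome_len / (2 * read_len))`.
#'
#' @param g genome to sequence (usually the mutant genome).
#' @param cfg a [sim_config()].
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return `list(r1 =, r2 =, n_pairs =)` with the FASTQ paths (gzip) and the
#'   pair count.
#' @export
simulate_reads <- function(g, cfg, dir, prefix = "sim") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  L <- nchar(g$seq)
  rl <- cfg$read_len
  n_pairs <- as.integer(round(cfg$coverage * L / (2 * rl)))
  lo <- if (nzchar(cfg$adapter)) max(1L, rl - nchar(cfg$adapter)) else rl
  res <- with_seed(cfg$seed + 2L, {
    flen <- pmin(pmax(as.integer(round(rnorm(n_pairs, cfg$frag_mean,
                                             cfg$frag_sd))), lo), L)
    if (g$circular) {
      start <- as.integer(floor(runif(n_pairs) * L)) + 1L
      big <- paste0(g$seq, g$seq)
      frag <- substring(big, start, start + flen - 1L)
    } else {
      start <- as.integer(floor(runif(n_pairs) * (L - flen + 1))) + 1L
      frag <- substring(g$seq, start, start + flen - 1L)
    }
    m1 <- substring(frag, 1L, pmin(rl, flen))
    m2 <- substring(revcomp(frag), 1L, pmin(rl, flen))
    short <- which(flen < rl)
    if (length(short)) {
      pad <- substring(cfg$adapter, 1L, rl - flen[short])
      m1[short] <- paste0(m1[short], pad)
      m2[short] <- paste0(m2[short], pad)
    }
    m1 <- apply_substitutions(m1, cfg$err_rate)
    m2 <- apply_substitutions(m2, cfg$err_rate)
    list(m1 = m1, m2 = m2)
  })
  ids <- sprintf("%s_%d", prefix, seq_len(n_pairs))
  qual1 <- strrep("I", nchar(res$m1))
  qual2 <- strrep("I", nchar(res$m2))
  pairs <- list(r1 = data.frame(id = ids, mate = 1L, seq = res$m1,
                                qual = qual1, stringsAsFactors = FALSE),
                r2 = data.frame(id = ids, mate = 2L, seq = res$m2,
                                qual = qual2, stringsAsFactors = FALSE))
  p1 <- file.path(dir, paste0(prefix, "_R1.fastq.gz"))
  p2 <- file.path(dir, paste0(prefix, "_R2.fastq.gz"))
  write_fastq_pairs(pairs, p1, p2)
  list(r1 = p1, r2 = p2, n_pairs = n_pairs)
}

truth_columns <- c("mutant_id", "ref_id", "position", "orientation",
                   "tsd_len")

#' Write / read a truth table of simulated insertions
#'
#' @param records truth data.frame as produced by [insert_cassette()].
#' @param path TSV path.
#' @export
write_truth <- function(records, path) {
  if (is.null(records) || nrow(records) == 0L) {
    writeLines(paste(truth_columns, collapse = "\t"), path)
    return(invisible(path))
  }
  write.table(records[, truth_columns], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @return `read_truth` returns the truth data.frame.
#' @export
read_truth <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Simulate a complete mutant dataset
#'
#' Generates a reference genome, a cassette, `cfg$n_insertions` insertion
#' positions respecting the spacing constraint, the mutant genome, a read
#' library and the truth table, writing everything under `dir`.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory.
#' @param mutant_id mutant identifier.
#' @return list with paths (`ref`, `cassette`, `mutant`, `r1`, `r2`,
#'   `truth`) and objects (`genome`, `cas`, `mutant_genome`, `truth_df`).
#' @export
simulate_dataset <- function(cfg, dir, mutant_id = "mutant1") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- make_genome(cfg)
  cas <- make_cassette(cfg)
  min_sep <- cfg$cassette_len + 2 * cfg$frag_mean + 1
  positions <- with_seed(cfg$seed + 3L, {
    lim <- cfg$genome_len - cfg$tsd_len - as.integer(cfg$frag_mean)
    for (try in 1:1000) {
      p <- sort(sample(seq(as.integer(cfg$frag_mean), lim),
                       cfg$n_insertions))
      if (cfg$n_insertions < 2L || all(diff(p) >= min_sep)) break
      p <- NULL
    }
    if (is.null(p)) stop_fmt("could not place %d insertions", cfg$n_insertions)
    p
  })
  ins <- if (cfg$n_insertions > 0L)
    insert_cassette(g, cas, positions, cfg, mutant_id = mutant_id)
  else list(genome = g, truth = data.frame(mutant_id = character(),
                                           ref_id = character(),
                                           position = integer(),
                                           orientation = character(),
                                           tsd_len = integer(),
                                           stringsAsFactors = FALSE))
  reads <- simulate_reads(ins$genome, cfg, dir, prefix = mutant_id)
  paths <- list(ref = file.path(dir, "ref.fasta"),
                cassette = file.path(dir, "cassette.fasta"),
                mutant = file.path(dir, paste0(mutant_id, "_genome.fasta")),
                truth = file.path(dir, paste0(mutant_id, "_truth.tsv")))
  write_fasta(list(g), paths$ref)
  write_fasta(list(cas), paths$cassette)
  write_fasta(list(ins$genome), paths$mutant)
  write_truth(ins$truth, paths$truth)
  c(paths, reads[c("r1", "r2")], list(n_pairs = reads$n_pairs, genome = g,
                                      cas = cas, mutant_genome = ins$genome,
                                      truth_df = ins$truth))
}
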