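test_that("make_genome is seed-deterministic with the requested composition", {
  cfg <- sim_config(genome_len = 1000L, seed = 1L)
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  expect_identical(g1$seq, g2$seq)
  expect_equal(g1$id, "simref")

  # extreme GC degenerates to {G,C} only
  gc1 <- make_genome(sim_config(genome_len = 1000L, gc = 1, seed = 2L))
  expect_true(grepl("^[GC]+$", gc1$seq))

  # binomial bound: 100 kb at gc = 0.5 lands within [0.49, 0.51]
  g <- make_genome(sim_config(genome_len = 100000L, gc = 0.5, seed = 3L))
  gc_frac <- (tnscout:::count_char(g$seq, "G") +
                tnscout:::count_char(g$seq, "C")) / nchar(g$seq)
  expect_gt(gc_frac, 0.49)
  expect_lt(gc_frac, 0.51)
})

test_that("insert_cassette duplicates the target site around the cassette", {
  cfg <- sim_config(genome_len = 2000L, cassette_len = 200L, tsd_len = 0L,
                    frag_mean = 100, frag_sd = 10, read_len = 50L, seed = 4L)
  g <- genome_record("g", rand_dna(2000, seed = 4))
  cas <- cassette_record("cas", rand_dna(200, seed = 5))

  # degenerate TSD: plain splice
  res <- insert_cassette(g, cas, 500L, cfg, orientations = "+")
  expect_identical(res$genome$seq,
                   paste0(substr(g$seq, 1, 499), cas$seq,
                          substr(g$seq, 500, 2000)))

  # tsd 9: bases p..p+8 appear on both sides of the cassette
  cfg9 <- sim_config(genome_len = 2000L, cassette_len = 200L, tsd_len = 9L,
                     frag_mean = 100, frag_sd = 10, read_len = 50L, seed = 4L)
  res9 <- insert_cassette(g, cas, 500L, cfg9, orientations = "-")
  m <- res9$genome$seq
  tsd <- substr(g$seq, 500, 508)
  expect_identical(substr(m, 500, 508), tsd)
  expect_identical(substr(m, 500 + 9 + 200, 500 + 9 + 200 + 8), tsd)
  expect_identical(substr(m, 509, 708), revcomp(cas$seq))
  expect_equal(nchar(m), 2000L + 200L + 9L)

  # two insertions: length arithmetic
  cfg2 <- sim_config(genome_len = 5000L, cassette_len = 200L, tsd_len = 9L,
                     frag_mean = 100, frag_sd = 10, read_len = 50L, seed = 4L)
  g2 <- genome_record("g", rand_dna(5000, seed = 6))
  res2 <- insert_cassette(g2, cas, c(1000L, 3000L), cfg2)
  expect_equal(nchar(res2$genome$seq), 5000L + 2L * (200L + 9L))
  expect_equal(res2$truth$position, c(1000L, 3000L))

  # spacing precondition
  expect_error(insert_cassette(g2, cas, c(1000L, 1100L), cfg2), "closer")
})

test_that("error-free reads are exact substrings of the template", {
  cfg <- sim_config(genome_len = 5000L, frag_mean = 300, frag_sd = 0,
                    read_len = 150L, coverage = 5, err_rate = 0, seed = 7L)
  g <- genome_record("g", rand_dna(5000, seed = 7))
  res <- simulate_reads(g, cfg, tempfile("simdir"))
  pairs <- read_fastq_pairs(res$r1, res$r2)
  for (s in pairs$r1$seq) expect_true(grepl(s, g$seq, fixed = TRUE))
  for (s in revcomp(pairs$r2$seq)) expect_true(grepl(s, g$seq, fixed = TRUE))
  expect_true(all(nchar(pairs$r1$seq) == 150L))
})

test_that("pair count follows round(coverage * L / (2 * read_len))", {
  cfg <- sim_config(genome_len = 30000L, coverage = 10, read_len = 150L,
                    err_rate = 0, seed = 8L)
  g <- make_genome(sim_config(genome_len = 30000L, seed = 8L))
  res <- simulate_reads(g, cfg, tempfile("simdir"))
  expect_equal(res$n_pairs, 1000L)
})

test_that("the same seed reproduces byte-identical FASTQ output", {
  cfg <- sim_config(genome_len = 5000L, coverage = 5, seed = 9L)
  g <- make_genome(sim_config(genome_len = 5000L, seed = 9L))
  r1 <- simulate_reads(g, cfg, tempfile("a"))
  r2 <- simulate_reads(g, cfg, tempfile("b"))
  expect_identical(unname(tools::md5sum(r1$r1)), unname(tools::md5sum(r2$r1)))
  expect_identical(unname(tools::md5sum(r1$r2)), unname(tools::md5sum(r2$r2)))
})

test_that("cassette 31-mers are conserved in the mutant genome", {
  cfg <- sim_config(genome_len = 2000L, cassette_len = 120L, tsd_len = 9L,
                    frag_mean = 100, frag_sd = 10, read_len = 50L, seed = 10L)
  g <- genome_record("g", rand_dna(2000, seed = 10))
  cas <- cassette_record("cas", rand_dna(120, seed = 11))
  res <- insert_cassette(g, cas, 700L, cfg)
  expect_true(all(kmers_of(cas$seq, 31) %in% kmers_of(res$genome$seq, 31)))
})

test_that("short fragments read through into the adapter", {
  adapter <- "AGATCGGAAGAGC"
  cfg <- sim_config(genome_len = 3000L, frag_mean = 60, frag_sd = 8,
                    read_len = 60L, coverage = 10, err_rate = 0,
                    adapter = adapter, seed = 12L)
  g <- genome_record("g", rand_dna(3000, seed = 12))
  res <- simulate_reads(g, cfg, tempfile("simdir"))
  pairs <- read_fastq_pairs(res$r1, res$r2)
  expect_true(all(nchar(pairs$r1$seq) == 60L))
  # reads from fragments < read_len end with adapter sequence, and some exist
  from_short <- !vapply(pairs$r1$seq, grepl, TRUE, x = g$seq, fixed = TRUE)
  expect_true(any(from_short))
  ends_in_adapter <- vapply(pairs$r1$seq[from_short], function(s) {
    any(vapply(1:13, function(k)
      endsWith(s, substr(adapter, 1, k)) &&
        grepl(substr(s, 1, 60 - k), g$seq, fixed = TRUE), TRUE))
  }, TRUE)
  expect_true(all(ends_in_adapter))
})

test_that("truth tables round-trip through TSV", {
  p <- tempfile(fileext = ".tsv")
  write_truth(NULL, p)
  expect_length(readLines(p), 1L)
  truth <- data.frame(mutant_id = "m1", ref_id = "simref",
                      position = c(100L, 900L), orientation = c("+", "-"),
                      tsd_len = 9L, stringsAsFactors = FALSE)
  write_truth(truth, p)
  expect_length(readLines(p), 3L)
  expect_equal(read_truth(p), truth)
})
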