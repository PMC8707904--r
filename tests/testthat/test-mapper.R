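test_that("the k-mer index reports canonical positions, including wrap-around", {
  # small-k cases exercise the indexing core directly
  pos <- tnscout:::cpp_index_query("ACGTACGT", 4L, FALSE,
                                   c("ACGT", "AAAA", "TTTT"))
  expect_equal(pos[[1]], c(1L, 5L))
  # canonicality: AAAA and TTTT share one entry
  idx2 <- tnscout:::cpp_index_query("AAAACC", 4L, FALSE, c("AAAA", "TTTT"))
  expect_equal(idx2[[1]], idx2[[2]])

  # circular genome: enumerate all rotations as the oracle
  g <- "ACGTAC"
  k <- 4L
  rot <- vapply(1:nchar(g), function(i)
    substr(paste0(g, g), i, i + k - 1L), "")
  wrap_kmer <- rot[5]  # starts at position 5, wraps
  got <- tnscout:::cpp_index_query(g, k, TRUE, wrap_kmer)[[1]]
  expect_true(5L %in% got)
  lin <- tnscout:::cpp_index_query(g, k, FALSE, wrap_kmer)[[1]]
  expect_false(5L %in% lin)
})

test_that("build_index validates its parameters", {
  g <- genome_record("g", rand_dna(100, seed = 1))
  expect_error(build_index(g, 12L), "odd")
  expect_error(build_index(g, 9L), "odd and in")
  expect_error(build_index(genome_record("g", rand_dna(15, seed = 1)), 21L),
               "genome length")
  idx <- build_index(g, 11L)
  km <- substr(g$seq, 11, 21)
  expect_true(11L %in% index_positions(idx, km)[[1]])
})

test_that("map_read places exact, reverse-complement and junction reads", {
  set.seed(201)
  gseq <- rand_dna(5000)
  cas <- rand_dna(1000)
  g <- genome_record("g", gseq)
  idx <- build_index(g, 21L)

  r <- list(id = "a", mate = 1L, seq = substr(gseq, 1001, 1150))
  res <- map_read(r, idx)
  expect_equal(res$status, "mapped")
  expect_equal(res$ref_pos, 1001L)
  expect_equal(res$strand, "+")
  expect_equal(res$identity, 1.0)

  rrc <- list(id = "b", mate = 1L, seq = revcomp(substr(gseq, 2001, 2150)))
  res2 <- map_read(rrc, idx)
  expect_equal(res2$status, "mapped")
  expect_equal(res2$strand, "-")
  expect_equal(res2$ref_pos, 2001L)

  # junction read: half genome, half cassette -> coverage below threshold
  junc <- list(id = "c", mate = 1L,
               seq = paste0(substr(gseq, 3001, 3075), substr(cas, 1, 75)))
  res3 <- map_read(junc, idx)
  expect_equal(res3$status, "unmapped")
})

test_that("error-free genomic reads map; cassette-bearing reads do not", {
  set.seed(202)
  gseq <- rand_dna(20000)
  cas <- rand_dna(2000)
  g <- genome_record("g", gseq)
  idx <- build_index(g, 21L)

  starts <- sample(1:(20000 - 150), 200)
  genomic <- reads_df(substring(gseq, starts, starts + 149))
  res <- map_reads(genomic, idx)
  expect_true(all(res$status == "mapped"))
  expect_equal(res$ref_pos, starts)

  # reads carrying a solid block of cassette sequence are unmapped; 50 bp
  # leaves the genomic part well below the 90% coverage threshold even
  # allowing for chance micro-extensions into the cassette part
  tn_reads <- reads_df(vapply(1:50, function(i) {
    glen <- sample(50:100, 1)
    paste0(substr(gseq, i * 100, i * 100 + glen - 1),
           substr(cas, 1, 150 - glen))
  }, ""))
  res_tn <- map_reads(tn_reads, idx)
  expect_true(all(res_tn$status == "unmapped"))
})

test_that("mapped/unmapped status matches the exhaustive alignment oracle", {
  set.seed(203)
  gseq <- rand_dna(1500)
  g <- genome_record("g", gseq)
  idx <- build_index(g, 11L)
  other <- rand_dna(800)
  for (i in 1:40) {
    n <- sample(40:60, 1)
    kind <- i %% 4
    s <- if (kind == 0) {           # exact substring
      st <- sample(1500 - n, 1); substr(gseq, st, st + n - 1)
    } else if (kind == 1) {         # substring with up to 3 errors
      st <- sample(1500 - n, 1)
      x <- substr(gseq, st, st + n - 1)
      for (p in sample(n, sample(1:3, 1)))
        substr(x, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(x, p, p)), 1)
      x
    } else if (kind == 2) {         # foreign sequence
      st <- sample(800 - n, 1); substr(other, st, st + n - 1)
    } else {                        # half genome / half foreign junction
      st <- sample(1500 - n, 1)
      paste0(substr(gseq, st, st + n %/% 2 - 1), substr(other, 1, n - n %/% 2))
    }
    r <- list(id = "r", mate = 1L, seq = s)
    got <- map_read(r, idx)$status
    expect_equal(got, map_status_oracle(s, gseq), info = paste(kind, s))
  }
})
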