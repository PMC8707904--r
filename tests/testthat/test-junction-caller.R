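# shared synthetic reference and cassette for contig-level tests
ref_seq <- rand_dna(4000, seed = 601)
cas_seq <- rand_dna(500, seed = 602)
ref <- genome_record("ref", ref_seq)
cas <- cassette_record("cas", cas_seq)
tn_par <- hsp_params(min_len = 16L)

contig_hsps <- function(contig) {
  list(ref = best_nonoverlapping(find_hsps(contig, ref)),
       tn = best_nonoverlapping(find_hsps(contig, cas, tn_par)))
}

test_that("a genome-Tn-genome contig yields left and right evidence", {
  contig <- list(id = "c1",
                 seq = paste0(substr(ref_seq, 1701, 2000), cas_seq,
                              substr(ref_seq, 2001, 2300)))
  h <- contig_hsps(contig)
  ev <- classify_contig(contig, h$ref, h$tn)
  expect_equal(nrow(ev), 2L)
  expect_setequal(ev$side, c("left", "right"))
  expect_equal(ev$coord[ev$side == "left"], 2000L)
  expect_equal(ev$coord[ev$side == "right"], 2001L)
  expect_true(all(ev$orientation == "+"))
})

test_that("a contig inside the cassette yields no evidence", {
  contig <- list(id = "c2", seq = substr(cas_seq, 51, 450))
  h <- contig_hsps(contig)
  ev <- classify_contig(contig, h$ref, h$tn)
  expect_equal(nrow(ev), 0L)
})

test_that("an untemplated 7-base junction gap is tolerated up to max_gap", {
  set.seed(603)
  contig <- list(id = "c3",
                 seq = paste0(substr(ref_seq, 1001, 1300), rand_dna(7),
                              cas_seq))
  h <- contig_hsps(contig)
  ev <- classify_contig(contig, h$ref, h$tn, max_gap = 10L)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$side, "left")
  expect_equal(ev$gap, 7L)
  expect_equal(ev$coord, 1300L)
  # with a tighter gap limit the evidence disappears
  expect_equal(nrow(classify_contig(contig, h$ref, h$tn, max_gap = 5L)), 0L)
})

test_that("a reverse-complemented junction contig gives mirrored evidence", {
  contig_fwd <- paste0(substr(ref_seq, 1701, 2000), cas_seq,
                       substr(ref_seq, 2001, 2300))
  contig <- list(id = "c4", seq = revcomp(contig_fwd))
  h <- contig_hsps(contig)
  ev <- classify_contig(contig, h$ref, h$tn)
  expect_equal(nrow(ev), 2L)
  expect_equal(sort(ev$coord), c(2000L, 2001L))
  expect_setequal(ev$side, c("left", "right"))
  expect_true(all(ev$orientation == "+"))
})

test_that("call_insertions normalizes and merges left/right evidence", {
  ev0 <- data.frame(contig_id = c("a", "b"), side = c("left", "right"),
                    ref_id = "ref", coord = c(4999L, 5000L),
                    orientation = "+", gap = 0L, stringsAsFactors = FALSE)
  # tsd 0: left flank ends at 4999, right starts at 5000, both -> 5000
  calls0 <- call_insertions(ev0, tsd_len = 0L)
  expect_equal(nrow(calls0), 1L)
  expect_equal(calls0$position, 5000L)
  expect_equal(calls0$sides, "both")
  expect_equal(calls0$n_contigs, 2L)

  # tsd 9: left flank ends at p+8, right starts at p, both normalize to p
  p <- 12345L
  ev9 <- data.frame(contig_id = "c", side = c("left", "right"),
                    ref_id = "ref", coord = c(p + 8L, p),
                    orientation = "-", gap = 0L, stringsAsFactors = FALSE)
  calls9 <- call_insertions(ev9, tsd_len = 9L,
                            reads_per_contig = c(c = 42L))
  expect_equal(calls9$position, p)
  expect_equal(calls9$sides, "both")
  expect_equal(calls9$orientation, "-")
  expect_equal(calls9$n_reads, 42L)

  # far-apart insertions are never merged
  ev2 <- data.frame(contig_id = c("a", "a2", "b", "b2"),
                    side = c("left", "right", "left", "right"),
                    ref_id = "ref",
                    coord = c(1008L, 1000L, 101008L, 101000L),
                    orientation = "+", gap = 0L, stringsAsFactors = FALSE)
  calls2 <- call_insertions(ev2, tsd_len = 9L)
  expect_equal(calls2$position, c(1000L, 101000L))
  expect_equal(calls2$sides, c("both", "both"))

  # conflicting orientations are kept but flagged
  evc <- data.frame(contig_id = c("a", "b"), side = c("left", "right"),
                    ref_id = "ref", coord = c(1008L, 1000L),
                    orientation = c("+", "-"), gap = 0L,
                    stringsAsFactors = FALSE)
  callsc <- call_insertions(evc, tsd_len = 9L)
  expect_equal(callsc$flag, "orientation_conflict")
})

# --- end-to-end runs on small simulations --------------------------------

e2e_cfg <- function(seed, n_ins = 1L, err = 0, cov = 35) {
  sim_config(genome_len = 20000L, n_insertions = n_ins, coverage = cov,
             err_rate = err, seed = seed)
}

test_that("run_pipeline recovers a single insertion exactly", {
  cfg <- e2e_cfg(604L)
  d <- simulate_dataset(cfg, tempfile("sim"))
  out <- tempfile("out")
  calls <- suppressMessages(
    run_pipeline("m1", d$r1, d$r2, d$ref, d$cassette, out_dir = out))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$position, d$truth_df$position)
  expect_equal(calls$orientation, d$truth_df$orientation)
  expect_equal(calls$sides, "both")
  expect_true(file.exists(file.path(out, "report.tsv")))
  expect_true(file.exists(file.path(out, "contigs.fasta")))
})

test_that("an insertion-free control produces no calls and a dash row", {
  cfg <- e2e_cfg(605L, n_ins = 0L, cov = 25)
  d <- simulate_dataset(cfg, tempfile("sim"), mutant_id = "Ctrl")
  out <- tempfile("out")
  calls <- suppressMessages(
    run_pipeline("Ctrl", d$r1, d$r2, d$ref, d$cassette, out_dir = out))
  expect_equal(nrow(calls), 0L)
  lines <- readLines(file.path(out, "report.tsv"))
  expect_length(lines, 2L)
  expect_equal(lines[2], "Ctrl\t-\t-\t-\t-\t-\t-\t-")
})

test_that("reverse-complementing the reference maps calls predictably", {
  cfg <- e2e_cfg(606L)
  d <- simulate_dataset(cfg, tempfile("sim"))
  calls <- suppressMessages(
    run_pipeline("m1", d$r1, d$r2, d$ref, d$cassette,
                 out_dir = tempfile("o1")))
  ref_rc <- genome_record("simref", revcomp(d$genome$seq))
  calls_rc <- suppressMessages(
    run_pipeline("m1", d$r1, d$r2, ref_rc, d$cassette,
                 out_dir = tempfile("o2")))
  L <- cfg$genome_len
  expect_equal(calls_rc$position, L - calls$position - cfg$tsd_len + 2L)
  expect_equal(calls_rc$orientation, chartr("+-", "-+", calls$orientation))
})

test_that("a mis-set calling tsd_len shifts positions by a bounded offset", {
  cfg <- e2e_cfg(607L)
  d <- simulate_dataset(cfg, tempfile("sim"))
  config0 <- pipeline_config(tsd_len = 0L)
  calls0 <- suppressMessages(
    run_pipeline("m1", d$r1, d$r2, d$ref, d$cassette, config = config0,
                 out_dir = tempfile("o")))
  p <- d$truth_df$position
  # left evidence lands at p + 9, right evidence at p; neither merges
  expect_setequal(calls0$position, c(p, p + 9L))
  expect_true(all(abs(calls0$position - p) <= 9L))
})
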