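test_that("find_hsps recovers exact and reverse-complement matches", {
  set.seed(501)
  sseq <- rand_dna(6000)
  subject <- list(id = "s", seq = sseq)

  q <- list(id = "q", seq = substr(sseq, 5001, 5200))
  h <- find_hsps(q, subject)
  expect_equal(nrow(h), 1L)
  expect_equal(h$q_start, 1L)
  expect_equal(h$q_end, 200L)
  expect_equal(h$s_start, 5001L)
  expect_equal(h$s_end, 5200L)
  expect_equal(h$identity, 1.0)
  expect_equal(h$score, 200L)
  expect_equal(h$strand, "+")

  qrc <- list(id = "q", seq = revcomp(substr(sseq, 5001, 5200)))
  h2 <- find_hsps(qrc, subject)
  expect_equal(h2$strand[1], "-")
  expect_equal(h2$s_start[1], 5001L)
  expect_equal(h2$s_end[1], 5200L)
  expect_equal(h2$q_start[1], 1L)
  expect_equal(h2$q_end[1], 200L)
})

test_that("scattered mismatches score as matches - 2*mismatches", {
  set.seed(502)
  sseq <- rand_dna(2000)
  x <- substr(sseq, 501, 600)
  for (p in c(20, 50, 80))
    substr(x, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(x, p, p)), 1)
  h <- find_hsps(list(id = "q", seq = x), list(id = "s", seq = sseq))
  expect_equal(h$score[1], 97L - 3L * 2L)
  expect_equal(h$identity[1], 0.97)
  expect_equal(h$length[1], 100L)
  expect_equal(h$score[1], sw_score(x, sseq))
})

test_that("top HSP score equals Smith-Waterman on random planted pairs", {
  set.seed(503)
  for (i in 1:30) {
    sseq <- rand_dna(400)
    n <- sample(40:80, 1)
    st <- sample(400 - n, 1)
    q <- substr(sseq, st, st + n - 1)
    q <- plant_errors(q, sample(0:3, 1), lo = 25L)
    if (i %% 5 == 0) {  # single-base deletion: gapped extension territory
      cut <- sample(15:(n - 15), 1)
      q <- paste0(substr(q, 1, cut - 1), substr(q, cut + 1, n))
    }
    if (i %% 2 == 0) q <- revcomp(q)
    h <- find_hsps(list(id = "q", seq = q), list(id = "s", seq = sseq))
    expect_gt(nrow(h), 0)
    expect_equal(h$score[1], sw_score(q, sseq), info = paste("case", i))
  }
})

test_that("strand symmetry: rc of the query mirrors query intervals only", {
  set.seed(504)
  sseq <- rand_dna(1000)
  q <- paste0(rand_dna(30), substr(sseq, 301, 400), rand_dna(20))
  subject <- list(id = "s", seq = sseq)
  h_fwd <- find_hsps(list(id = "q", seq = q), subject)
  h_rev <- find_hsps(list(id = "q", seq = revcomp(q)), subject)
  expect_equal(h_rev$s_start, h_fwd$s_start)
  expect_equal(h_rev$s_end, h_fwd$s_end)
  expect_setequal(c(h_fwd$strand[1], h_rev$strand[1]), c("-", "+"))
  n <- nchar(q)
  expect_equal(h_rev$q_start, n - h_fwd$q_end + 1L)
  expect_equal(h_rev$q_end, n - h_fwd$q_start + 1L)
})

test_that("best_nonoverlapping keeps compatible HSPs greedily by score", {
  hsp_row <- function(qs, qe, score, ss = qs) {
    data.frame(q_id = "q", q_start = qs, q_end = qe, s_id = "s",
               s_start = ss, s_end = ss + (qe - qs), strand = "+",
               score = score, length = qe - qs + 1L,
               identity = 1, stringsAsFactors = FALSE)
  }
  single <- hsp_row(1L, 100L, 100L)
  expect_equal(best_nonoverlapping(single), single)

  two <- rbind(hsp_row(1L, 100L, 100L), hsp_row(103L, 200L, 98L))
  expect_equal(nrow(best_nonoverlapping(two)), 2L)

  near <- rbind(hsp_row(1L, 100L, 100L), hsp_row(11L, 110L, 95L))
  kept <- best_nonoverlapping(near)  # overlap 90 > 5: keep the better one
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$score, 100L)

  # exhaustive check on a 5-HSP set: the greedy selection is pairwise
  # compatible and always contains the top-scoring HSP
  set.seed(505)
  for (rep in 1:20) {
    qs <- sample(1:150, 5)
    hsps <- do.call(rbind, lapply(seq_along(qs), function(i)
      hsp_row(qs[i], qs[i] + sample(20:60, 1), sample(20:100, 1))))
    sel <- best_nonoverlapping(hsps)
    if (nrow(sel) > 1L) {
      combs <- utils::combn(nrow(sel), 2)
      for (ci in seq_len(ncol(combs))) {
        a <- combs[1, ci]; b <- combs[2, ci]
        ov <- min(sel$q_end[a], sel$q_end[b]) -
          max(sel$q_start[a], sel$q_start[b]) + 1L
        expect_lte(ov, 5L)
      }
    }
    expect_true(max(hsps$score) %in% sel$score)
  }
})
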