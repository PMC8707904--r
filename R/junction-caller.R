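## Junction calling: a contig evidences an insertion when a reference HSP
## and a cassette HSP are adjacent on the contig -- the "double hit"
## criterion; a genome-Tn-genome contig carries two such adjacencies. The
## reference coordinate of a junction is taken from the cassette-side
## boundary projected through the reference HSP: the cassette HSP abuts a
## subject end of the cassette and therefore cannot over-extend, which makes
## the coordinate exact even across microhomology between the cassette tip
## and the flanking genome.

#' Pipeline configuration defaults
#'
#' @param adapter 3' adapter to trim ("" disables trimming).
#' @param min_overlap,max_err adapter-trim parameters ([trim_adapter()]).
#' @param min_read_len minimum mate length after trimming.
#' @param k_map mapping k-mer size ([build_index()]).
#' @param map_min_identity,map_min_cov,map_band mapping thresholds
#'   ([map_reads()]).
#' @param k_scr,min_hits cassette screen parameters ([screen_reads()]).
#' @param include_mates add mates of screened reads ([screen_mates()]).
#' @param k_grid candidate assembly k values for [choose_k()]; `k_asm`
#'   forces a fixed k instead.
#' @param k_asm fixed assembly k (NULL = choose from `k_grid`).
#' @param min_abund minimum k-mer abundance for assembly (default 3: at the
#'   ~50x coverage the pipeline is tuned for, pairs of reads sharing the
#'   same sequencing error are common enough that an abundance-2 cutoff
#'   leaves error k-mers in the graph and fragments the unitigs).
#' @param hsp reference-side alignment parameters ([hsp_params()]).
#' @param tn_min_len minimum cassette-side HSP length. Junction stubs
#'   penetrate the cassette by only k_asm - 1 bases when several insertions
#'   share a cassette end, so the cassette-side length cutoff is lower than
#'   the reference-side one.
#' @param max_q_overlap HSP selection overlap ([best_nonoverlapping()]).
#' @param max_gap,max_overlap junction adjacency tolerances
#'   ([classify_contig()]).
#' @param tsd_len assumed target-site duplication length (9 for Tn5).
#' @param slack coordinate slack when merging left/right evidence.
#' @return named list of parameters.
#' @export
pipeline_config <- function(adapter = "", min_overlap = 3L, max_err = 0.1,
                            min_read_len = 30L, k_map = 21L,
                            map_min_identity = 0.90, map_min_cov = 0.90,
                            map_band = 8L, k_scr = 21L, min_hits = 2L,
                            include_mates = TRUE, k_grid = c(21L, 25L, 31L),
                            k_asm = NULL, min_abund = 3L,
                            hsp = hsp_params(), tn_min_len = 16L,
                            max_q_overlap = 5L, max_gap = 10L,
                            max_overlap = 5L, tsd_len = 9L, slack = 2L) {
  as.list(environment())
}

#' Classify a contig by its double-hit structure
#'
#' Pairs every selected reference HSP with every selected cassette HSP and
#' emits a junction evidence when their query intervals are adjacent on the
#' contig: gap at most `max_gap` and overlap at most `max_overlap`. The
#' evidence records the reference coordinate of the genomic flank base
#' abutting the cassette (`coord`), the side of the insertion the flank
#' represents (`left` = flank precedes the cassette in reference forward
#' orientation) and the cassette orientation. A genome-Tn-genome contig
#' yields two evidences; a contig lying entirely in the cassette or in the
#' genome yields none.
#'
#' @param contig a contig (data.frame row or `list(id=, seq=)`).
#' @param ref_hsps,tn_hsps HSPs of this contig against the reference and the
#'   cassette, after [best_nonoverlapping()].
#' @param max_gap maximum unaligned bases between the two HSPs (default 10).
#' @param max_overlap maximum overlap between the two HSPs (default 5;
#'   overlap arises from microhomology between cassette tip and genome).
#' @return data.frame of junction evidences with columns `contig_id`,
#'   `side`, `ref_id`, `coord`, `orientation`, `gap`.
#' @export
classify_contig <- function(contig, ref_hsps, tn_hsps, max_gap = 10L,
                            max_overlap = 5L) {
  empty <- data.frame(contig_id = character(), side = character(),
                      ref_id = character(), coord = integer(),
                      orientation = character(), gap = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(ref_hsps) == 0L || nrow(tn_hsps) == 0L) return(empty)
  out <- list()
  for (i in seq_len(nrow(ref_hsps))) {
    R <- ref_hsps[i, ]
    for (j in seq_len(nrow(tn_hsps))) {
      T <- tn_hsps[j, ]
      orientation <- if (R$strand == T$strand) "+" else "-"
      if (R$q_end < T$q_end) {   # reference flank precedes cassette
        gap <- T$q_start - R$q_end - 1L
        if (gap > max_gap || -gap > max_overlap) next
        ov <- max(0L, -gap)
        if (R$strand == "+") {
          side <- "left"; coord <- R$s_end - ov
        } else {
          side <- "right"; coord <- R$s_start + ov
        }
      } else {                   # cassette precedes reference flank
        gap <- R$q_start - T$q_end - 1L
        if (gap > max_gap || -gap > max_overlap) next
        ov <- max(0L, -gap)
        if (R$strand == "+") {
          side <- "right"; coord <- R$s_start + ov
        } else {
          side <- "left"; coord <- R$s_end - ov
        }
      }
      out[[length(out) + 1L]] <-
        data.frame(contig_id = contig$id %||% "contig", side = side,
                   ref_id = R$s_id, coord = as.integer(coord),
                   orientation = orientation, gap = as.integer(gap),
                   stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Convert junction evidences into insertion calls
#'
#' Evidence positions are normalized to the first base of the target-site
#' duplication: a left flank ending at reference coordinate e gives
#' position e - tsd_len + 1; a right flank starting at s gives position s.
#' Left and right evidences within `slack` of each other after
#' normalization are merged into a single call with `sides = "both"`;
#' unmerged evidences become single-sided calls. Conflicting cassette
#' orientations within a merged call are kept but flagged.
#'
#' @param evidences evidence data.frame ([classify_contig()] rows of one
#'   mutant).
#' @param tsd_len assumed target-site duplication length.
#' @param reads_per_contig optional named integer vector of supporting read
#'   counts per contig id.
#' @param mutant_id mutant identifier for the calls.
#' @param slack merge slack in bases (default 2, absorbing end trimming by
#'   the gapped extension).
#' @return insertion call data.frame with columns `mutant_id`, `ref_id`,
#'   `position`, `orientation`, `sides`, `n_contigs`, `n_reads`,
#'   `locus_tag`, `product`, `flag`.
#' @export
call_insertions <- function(evidences, tsd_len = 9L,
                            reads_per_contig = NULL,
                            mutant_id = "mutant1", slack = 2L) {
  empty <- data.frame(mutant_id = character(), ref_id = character(),
                      position = integer(), orientation = character(),
                      sides = character(), n_contigs = integer(),
                      n_reads = integer(), locus_tag = character(),
                      product = character(), flag = character(),
                      stringsAsFactors = FALSE)
  if (is.null(evidences) || nrow(evidences) == 0L) return(empty)
  ev <- evidences
  ev$position <- ifelse(ev$side == "left", ev$coord - tsd_len + 1L,
                        ev$coord)
  ev <- ev[order(ev$position), , drop = FALSE]
  cluster <- cumsum(c(1L, diff(ev$position) > slack))
  calls <- lapply(split(ev, cluster), function(e) {
    tab <- table(e$position)
    pos <- as.integer(names(tab)[tab == max(tab)][1])
    sides <- if (all(c("left", "right") %in% e$side)) "both"
             else e$side[1]
    otab <- sort(table(e$orientation), decreasing = TRUE)
    orientation <- names(otab)[1]
    flag <- if (length(otab) > 1L) "orientation_conflict" else ""
    contigs <- unique(e$contig_id)
    n_reads <- if (is.null(reads_per_contig)) NA_integer_
               else sum(reads_per_contig[contigs], na.rm = TRUE)
    data.frame(mutant_id = mutant_id, ref_id = e$ref_id[1], position = pos,
               orientation = orientation, sides = sides,
               n_contigs = length(contigs),
               n_reads = as.integer(n_reads), locus_tag = "-",
               product = "-", flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the complete insertion-site identification pipeline
#'
#' Executes the full chain for one mutant: adapter trim and QC, read
#' classification against the reference, cassette screen of the unmapped
#' pool, unitig assembly, HSP search of every contig against reference and
#' cassette, double-hit junction classification, insertion calling and gene
#' annotation. Intermediate artifacts and a stage log are written under
#' `out_dir`.
#'
#' @param mutant_id mutant identifier (first report column).
#' @param r1,r2 FASTQ paths of the mate pairs.
#' @param ref reference genome: FASTA path or [genome_record()].
#' @param cassette transposon cassette: FASTA path or [cassette_record()].
#' @param gff optional GFF3 annotation path (or a gene data.frame from
#'   [read_gff3()]); NULL leaves gene columns as "-".
#' @param config parameters from [pipeline_config()].
#' @param out_dir output directory for report and intermediates.
#' @return the insertion call data.frame (annotated), invisibly also written
#'   to `<out_dir>/report.tsv`.
#' @export
run_pipeline <- function(mutant_id, r1, r2, ref, cassette, gff = NULL,
                         config = pipeline_config(),
                         out_dir = tempfile("tnscout_")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_fmt("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  if (is.character(ref)) {
    rec <- read_fasta(ref)[[1]]
    ref <- genome_record(rec$id, rec$seq)
  }
  if (is.character(cassette)) {
    rec <- read_fasta(cassette)[[1]]
    cassette <- cassette_record(rec$id, rec$seq)
  }
  genes <- if (is.character(gff)) read_gff3(gff, ref$id) else gff

  pairs <- stage("preprocess", {
    p <- read_fastq_pairs(r1, r2)
    if (nzchar(config$adapter)) {
      p$r1 <- trim_adapter(p$r1, config$adapter, config$min_overlap,
                           config$max_err)
      p$r2 <- trim_adapter(p$r2, config$adapter, config$min_overlap,
                           config$max_err)
    }
    qc_filter(p, config$min_read_len)
  })
  logf("preprocess", "%d pairs after trimming/QC", nrow(pairs$r1))

  reads <- rbind(pairs$r1, pairs$r2)
  unmapped <- stage("classify", {
    idx <- build_index(ref, config$k_map)
    mres <- map_reads(reads, idx, config$map_min_identity,
                      config$map_min_cov, config$map_band)
    write.table(mres, file.path(out_dir, "map_results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    reads[mres$status == "unmapped", , drop = FALSE]
  })
  logf("classify", "%d of %d reads unmapped", nrow(unmapped), nrow(reads))

  screened <- stage("screen", {
    kept <- screen_reads(unmapped, cassette, config$k_scr, config$min_hits)
    screen_mates(kept, unmapped, enabled = config$include_mates)
  })
  logf("screen", "%d transposon-containing reads (mates included: %s)",
       nrow(screened), config$include_mates)
  write_fastq_pairs(list(r1 = screened, r2 = screened[0, , drop = FALSE]),
                    file.path(out_dir, "screened.fastq.gz"),
                    file.path(out_dir, "screened_empty.fastq.gz"))

  calls <- if (nrow(screened) < 2L) {
    logf("assemble", "too few screened reads; no insertions called")
    call_insertions(NULL, config$tsd_len, mutant_id = mutant_id)
  } else {
    contigs <- stage("assemble", {
      k_asm <- config$k_asm
      if (is.null(k_asm)) {
        grid <- config$k_grid[config$k_grid <= min(nchar(screened$seq))]
        k_asm <- choose_k(screened, grid)
      }
      logf("assemble", "k_asm = %d", k_asm)
      build_unitigs(screened, k_asm, config$min_abund)
    })
    logf("assemble", "%d unitigs", nrow(contigs))
    if (nrow(contigs))
      write_fasta(data.frame(
        id = sprintf("%s mean_abund=%.1f", contigs$id, contigs$mean_abund),
        seq = contigs$seq), file.path(out_dir, "contigs.fasta"))

    evidences <- stage("call", {
      tn_params <- config$hsp
      tn_params$min_len <- config$tn_min_len
      ref_hsps <- find_hsps_batch(contigs, ref, config$hsp)
      tn_hsps <- find_hsps_batch(contigs, cassette, tn_params)
      all_hsps <- list()
      evs <- list()
      for (ci in seq_len(nrow(contigs))) {
        contig <- contigs[ci, ]
        rh <- best_nonoverlapping(ref_hsps[[ci]], config$max_q_overlap)
        th <- best_nonoverlapping(tn_hsps[[ci]], config$max_q_overlap)
        all_hsps[[ci]] <- rbind(rh, th)
        evs[[ci]] <- classify_contig(contig, rh, th, config$max_gap,
                                     config$max_overlap)
      }
      hsps <- do.call(rbind, all_hsps)
      if (!is.null(hsps) && nrow(hsps))
        write.table(hsps, file.path(out_dir, "hsps.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
      ev <- do.call(rbind, evs)
      if (!is.null(ev) && nrow(ev))
        write.table(ev, file.path(out_dir, "evidence.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
      ev
    })
    logf("call", "%d junction evidences",
         if (is.null(evidences)) 0L else nrow(evidences))

    rpc <- NULL
    if (nrow(contigs)) {
      rpc <- cpp_assign_reads(screened$seq, contigs$seq,
                              min(21L, min(nchar(contigs$seq))))
      names(rpc) <- contigs$id
    }
    call_insertions(evidences, config$tsd_len, rpc, mutant_id,
                    config$slack)
  }
  calls <- annotate_calls(calls, genes)
  logf("report", "%d insertion call(s)", nrow(calls))
  write_report(calls, file.path(out_dir, "report.tsv"), mutants = mutant_id)
  calls
}
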