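## Sequence, annotation and report I/O.
## Conventions used throughout the package:
##   * all genome coordinates are 1-based inclusive (GFF3 / NCBI style);
##   * sequences are uppercased on load; IUPAC ambiguity codes other than N
##     are rejected;
##   * gzip input is detected by magic bytes, not by file extension.

#' Construct a genome record
#'
#' A genome is a named nucleotide sequence with a circularity flag. The
#' sequence is uppercased; characters outside A,C,G,T,N are rejected and the
#' N fraction must stay below 10%.
#'
#' @param id sequence identifier.
#' @param seq nucleotide string.
#' @param circular logical; is the replicon circular?
#' @return an object of class `tn_genome` with fields `id`, `seq`, `circular`.
#' @export
genome_record <- function(id, seq, circular = FALSE) {
  seq <- toupper(as.character(seq))
  if (!nzchar(seq)) stop_fmt("genome '%s': empty sequence", id)
  check_alphabet(seq, id)
  n_frac <- count_char(seq, "N") / nchar(seq)
  if (n_frac >= 0.10)
    stop_fmt("genome '%s': N fraction %.2f exceeds the 10%% limit", id, n_frac)
  structure(list(id = as.character(id), seq = seq,
                 circular = isTRUE(circular)),
            class = "tn_genome")
}

#' Construct a transposon cassette record
#'
#' @param id sequence identifier.
#' @param seq cassette nucleotide string (at least 50 bp).
#' @return an object of class `tn_cassette` with fields `id`, `seq`, `length`.
#' @export
cassette_record <- function(id, seq) {
  seq <- toupper(as.character(seq))
  check_alphabet(seq, id)
  if (nchar(seq) < 50L)
    stop_fmt("cassette '%s': length %d < 50", id, nchar(seq))
  structure(list(id = as.character(id), seq = seq, length = nchar(seq)),
            class = "tn_cassette")
}

check_alphabet <- function(seq, id) {
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad))
    stop_fmt("sequence '%s': characters outside {A,C,G,T,N}: '%s'",
             id, substr(bad, 1, 10))
  invisible(TRUE)
}

count_char <- function(seq, ch) {
  nchar(seq) - nchar(gsub(ch, "", seq, fixed = TRUE))
}

#' Read a FASTA file
#'
#' Reads plain or gzip FASTA into a list of records. Sequences are
#' uppercased; record order is preserved; duplicate identifiers are an error.
#'
#' @param path path to a FASTA file (optionally gzip-compressed).
#' @return a list of records, each `list(id =, seq =)`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_fmt("FASTA file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop_fmt("FASTA format error in %s: %s", path,
                             conditionMessage(e)))
  if (length(set) == 0L) stop_fmt("FASTA format error: %s is empty", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop_fmt("FASTA format error: duplicate id '%s' in %s", dup[1], path)
  seqs <- toupper(as.character(set))
  mapply(function(i, s) list(id = i, seq = s), ids, unname(seqs),
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param records list of records (`list(id=, seq=)`), or a contig set
#'   (data.frame with `id` and `seq` columns).
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.data.frame(records))
    records <- mapply(function(i, s, ...) c(list(id = i, seq = s), list(...)),
                      records$id, records$seq, SIMPLIFY = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  for (rec in records) {
    hdr <- rec$id
    if (!is.null(rec$desc)) hdr <- paste(hdr, rec$desc)
    body <- gsub(sprintf("(.{%d})", width), "\\1\n", rec$seq)
    body <- sub("\n$", "", body)
    writeLines(c(paste0(">", hdr), body), con, sep = "\n")
  }
  invisible(path)
}

strip_mate_tag <- function(ids) {
  sub("/[12]$", "", sub("\\s.*$", "", ids))
}

parse_fastq <- function(path, mate) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) %% 4L != 0L)
    stop_fmt("FASTQ format error in %s: line count %d not a multiple of 4",
             path, length(lines))
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(data.frame(id = character(), mate = integer(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  if (any(!startsWith(hdr, "@")))
    stop_fmt("FASTQ format error in %s: header without '@'", path)
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    stop_fmt("FASTQ record error in %s at record %d: |seq| %d != |qual| %d",
             path, bad[1], nchar(seq[bad[1]]), nchar(qual[bad[1]]))
  data.frame(id = strip_mate_tag(substring(hdr, 2L)), mate = mate,
             seq = seq, qual = qual, stringsAsFactors = FALSE)
}

#' Read a pair of FASTQ files as mate pairs
#'
#' Both files are read in order; mate identifiers must agree after stripping
#' a trailing `/1`, `/2` or space-delimited tag.
#'
#' @param path1,path2 FASTQ files for mate 1 and mate 2 (gzip allowed).
#' @return a list with data.frames `r1` and `r2` (columns `id`, `mate`,
#'   `seq`, `qual`), row i of each being a mate pair.
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- parse_fastq(path1, 1L)
  r2 <- parse_fastq(path2, 2L)
  if (nrow(r1) != nrow(r2))
    stop_fmt("FASTQ pairing error: %d records in %s but %d in %s",
             nrow(r1), path1, nrow(r2), path2)
  mism <- which(r1$id != r2$id)
  if (length(mism))
    stop_fmt("FASTQ pairing error at record %d: id '%s' vs '%s'",
             mism[1], r1$id[mism[1]], r2$id[mism[1]])
  list(r1 = r1, r2 = r2)
}

#' Write mate pairs to a pair of FASTQ files
#'
#' @param pairs list with data.frames `r1` and `r2` as returned by
#'   [read_fastq_pairs()].
#' @param path1,path2 output paths; `.gz` suffix triggers gzip output.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  write_one <- function(df, path, mate) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con))
    if (nrow(df)) {
      lines <- as.vector(rbind(paste0("@", df$id, "/", mate), df$seq, "+",
                               df$qual))
      writeLines(lines, con, sep = "\n")
    }
  }
  write_one(pairs$r1, path1, 1L)
  write_one(pairs$r2, path2, 2L)
  invisible(c(path1, path2))
}

#' Read gene records from a GFF3 annotation
#'
#' Extracts gene features (CDS features if no genes are present) located on
#' the named sequence. Coordinates are kept 1-based inclusive as in GFF3.
#' Features without a `locus_tag` attribute are skipped with a warning.
#'
#' @param path GFF3 file.
#' @param genome_id sequence (seqid column) to extract features for.
#' @return data.frame with columns `locus_tag`, `start`, `end`, `strand`,
#'   `product`, sorted by `start`.
#' @export
read_gff3 <- function(path, genome_id) {
  if (!file.exists(path)) stop_fmt("GFF3 file not found: %s", path)
  raw <- readLines(path, warn = FALSE)
  body <- raw[!startsWith(raw, "#") & nzchar(raw)]
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) >= 5L && !is.na(suppressWarnings(as.integer(f[4]))) &&
        as.integer(f[5]) < as.integer(f[4]))
      stop_fmt("GFF3 format error in %s: end %s < start %s", path, f[5], f[4])
  }
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stop_fmt("GFF3 format error in %s: %s", path,
                            conditionMessage(e)))
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == genome_id]
  type <- as.character(gr$type)
  keep <- type == "gene"
  if (!any(keep)) keep <- type == "CDS"
  gr <- gr[keep]
  lt <- if ("locus_tag" %in% names(S4Vectors::mcols(gr))) gr$locus_tag
        else rep(NA_character_, length(gr))
  missing_lt <- is.na(lt) | !nzchar(lt)
  if (any(missing_lt))
    warning(sprintf("%d feature(s) without locus_tag skipped",
                    sum(missing_lt)), call. = FALSE)
  gr <- gr[!missing_lt]
  lt <- lt[!missing_lt]
  prod <- if ("product" %in% names(S4Vectors::mcols(gr)))
            ifelse(is.na(gr$product), "", as.character(gr$product))
          else rep("", length(gr))
  out <- data.frame(locus_tag = as.character(lt),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    product = prod, stringsAsFactors = FALSE)
  if (anyDuplicated(out$locus_tag))
    stop_fmt("GFF3 format error in %s: duplicate locus_tag '%s'", path,
             out$locus_tag[duplicated(out$locus_tag)][1])
  out[order(out$start), , drop = FALSE]
}

report_columns <- c("mutant_colony", "insertion_position", "targeted_gene",
                    "annotated_function", "orientation", "evidence_sides",
                    "n_contigs", "n_reads")

#' Write the insertion report
#'
#' One TSV row per insertion call, sorted by (mutant, position). A mutant
#' listed in `mutants` but absent from `calls` is reported as a single row of
#' dashes, the convention used for insertion-free controls.
#'
#' @param calls insertion calls, as returned by [call_insertions()] /
#'   [run_pipeline()].
#' @param path output TSV path.
#' @param mutants character vector of all mutants that were analysed
#'   (defaults to the mutants present in `calls`).
#' @export
write_report <- function(calls, path, mutants = NULL) {
  mutants <- sort(unique(c(as.character(mutants),
                           as.character(calls$mutant_id))))
  rows <- list()
  for (m in mutants) {
    sub <- calls[calls$mutant_id == m, , drop = FALSE]
    if (nrow(sub) == 0L) {
      rows[[length(rows) + 1L]] <-
        data.frame(mutant_colony = m, insertion_position = "-",
                   targeted_gene = "-", annotated_function = "-",
                   orientation = "-", evidence_sides = "-", n_contigs = "-",
                   n_reads = "-", stringsAsFactors = FALSE)
    } else {
      sub <- sub[order(sub$position), , drop = FALSE]
      rows[[length(rows) + 1L]] <-
        data.frame(mutant_colony = m,
                   insertion_position = as.character(sub$position),
                   targeted_gene = sub$locus_tag,
                   annotated_function = sub$product,
                   orientation = sub$orientation,
                   evidence_sides = sub$sides,
                   n_contigs = as.character(sub$n_contigs),
                   n_reads = as.character(sub$n_reads),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(report_columns, collapse = "\t"), con, sep = "\n")
  if (!is.null(out) && nrow(out))
    writeLines(do.call(paste, c(out, sep = "\t")), con, sep = "\n")
  invisible(path)
}
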