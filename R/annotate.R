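## Gene assignment: an insertion coordinate is matched to the gene(s) whose
## interval contains it; otherwise the nearest gene is reported with a
## signed distance. Gene strand is reported but does not affect containment
## (an insertion disrupts a gene regardless of orientation).

#' Locate the gene disrupted by an insertion coordinate
#'
#' @param position 1-based reference coordinate.
#' @param genes gene data.frame from [read_gff3()] (sorted by start).
#' @return list with `locus_tag`, `product`, `relation`
#'   (`"within"`/`"intergenic"`) and `distance` (0 when within; positive
#'   downstream of the nearest gene end, negative upstream of its start).
#'   Multiple overlapping genes are comma-joined in start order.
#' @export
locate_gene <- function(position, genes) {
  if (is.null(genes) || nrow(genes) == 0L)
    return(list(locus_tag = "-", product = "-", relation = "intergenic",
                distance = NA_integer_))
  gr <- IRanges::IRanges(start = genes$start, end = genes$end)
  hit <- IRanges::findOverlaps(IRanges::IRanges(position, position), gr)
  idx <- S4Vectors::subjectHits(hit)
  if (length(idx)) {
    idx <- idx[order(genes$start[idx])]
    return(list(locus_tag = paste(genes$locus_tag[idx], collapse = ","),
                product = paste(genes$product[idx], collapse = ","),
                relation = "within", distance = 0L))
  }
  d <- ifelse(position > genes$end, position - genes$end,
              genes$start - position)
  i <- which.min(d)  # ties resolve to the earliest gene
  dist <- if (position > genes$end[i]) position - genes$end[i]
          else -(genes$start[i] - position)
  list(locus_tag = genes$locus_tag[i], product = genes$product[i],
       relation = "intergenic", distance = as.integer(dist))
}

#' Annotate insertion calls with disrupted genes
#'
#' @param calls insertion call data.frame ([call_insertions()]).
#' @param genes gene data.frame from [read_gff3()], or NULL to leave the
#'   gene columns as "-".
#' @return `calls` with `locus_tag`, `product`, `relation` and `distance`
#'   filled in.
#' @export
annotate_calls <- function(calls, genes = NULL) {
  calls$relation <- rep("-", nrow(calls))
  calls$distance <- rep(NA_integer_, nrow(calls))
  if (is.null(genes) || nrow(calls) == 0L) return(calls)
  for (i in seq_len(nrow(calls))) {
    loc <- locate_gene(calls$position[i], genes)
    calls$locus_tag[i] <- loc$locus_tag
    calls$product[i] <- if (nzchar(loc$product)) loc$product else "-"
    calls$relation[i] <- loc$relation
    calls$distance[i] <- loc$distance
  }
  calls
}
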