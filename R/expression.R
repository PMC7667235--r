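#' Reads per kilobase of transcript per million reads
#'
#' `rpkm = count / ((length_bp / 1000) * (total_reads / 1e6))`. When complete
#' read mappings are not available, the total number of sequenced reads may
#' stand in for total mapped reads as the denominator — the convention used
#' throughout this package's expression tables.
#'
#' @param read_count Mapped (or assigned) read count.
#' @param transcript_len_bp Transcript length, bp (> 0).
#' @param total_reads Library size (> 0).
#' @return RPKM (numeric, vectorized).
#' @examples
#' rpkm(100, 1000, 1e6)  # 100
#' @export
rpkm <- function(read_count, transcript_len_bp, total_reads) {
  if (any(transcript_len_bp <= 0)) stop("transcript length must be positive")
  if (any(total_reads <= 0)) stop("total reads must be positive")
  read_count / ((transcript_len_bp / 1000) * (total_reads / 1e6))
}

#' Build an expression table with derived RPKM
#'
#' @param x `data.frame` with columns `species`, `family`, `copy`, and either
#'   an `rpkm` column or the triplet `count`, `length_bp`, `total_reads`
#'   from which RPKM is derived.
#' @return The table with an `rpkm` column.
#' @export
expressionTable <- function(x) {
  need <- c("species", "family", "copy")
  stopifnot(all(need %in% names(x)))
  if (is.null(x$rpkm)) {
    stopifnot(all(c("count", "length_bp", "total_reads") %in% names(x)))
    x$rpkm <- rpkm(x$count, x$length_bp, x$total_reads)
  }
  x
}

#' Assign the C4-functional gene copy within one family
#'
#' The functional copy in the C4 pathway is taken to be the one with the
#' highest expression. `dominance_ratio` is the top RPKM over the runner-up
#' (`Inf` for a single copy); `co_expression` flags a runner-up at or above
#' `co_expression_frac` of the top — a situation where transcript data alone
#' would suggest co-function and an enzyme assay is needed to adjudicate.
#'
#' @param rows `data.frame` with columns `copy` and `rpkm` (one species, one
#'   gene family), e.g. a subset of [expressionTable()] output.
#' @param co_expression_frac Runner-up/top ratio that triggers the flag
#'   (default 0.5).
#' @return Named list: `copy` (character; length > 1 on a tie), `rpkm`,
#'   `dominance_ratio`, `co_expression`, `tie`.
#' @export
assignFunctionalCopy <- function(rows, co_expression_frac = 0.5) {
  stopifnot(nrow(rows) >= 1, all(c("copy", "rpkm") %in% names(rows)))
  top <- max(rows$rpkm)
  winners <- rows$copy[rows$rpkm == top]
  tie <- length(winners) > 1L
  second <- if (nrow(rows) > 1L) max(rows$rpkm[rank(-rows$rpkm,
                                                    ties.method = "first") > 1])
            else NA_real_
  ratio <- if (nrow(rows) == 1L) Inf else if (second == 0) Inf else top / second
  list(copy = winners, rpkm = top, dominance_ratio = ratio,
       co_expression = !is.na(second) && second >= co_expression_frac * top,
       tie = tie)
}

#' Packaged PEPC / decarboxylase / PPDK expression table
#'
#' RPKM expression of the C4-cycle gene copies (three PEPC, three NAD-ME,
#' three NADP-ME copies) for one C3 and three C4 accessions, as packaged in
#' `extdata`. Note one published naming inconsistency surfaced here rather
#' than resolved: prose in the source study refers to the dominant Boerhavia
#' decarboxylase variously as NADP-ME1 and NADP-ME2, while its table (the one
#' packaged) puts essentially all expression on NADP1.
#'
#' @return A long `data.frame` with columns `species`, `pathway`, `family`,
#'   `copy`, `rpkm`.
#' @export
pepcExpressionTable <- function() {
  x <- read.delim(extdataPath("c4_gene_expression_rpkm.tsv"),
                  stringsAsFactors = FALSE, check.names = FALSE)
  long <- do.call(rbind, lapply(setdiff(names(x), c("species", "pathway")),
                                function(cp) {
    data.frame(species = x$species, pathway = x$pathway,
               family = sub("[0-9]+$", "", cp), copy = cp, rpkm = x[[cp]],
               stringsAsFactors = FALSE)
  }))
  long[order(long$species), , drop = FALSE]
}
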