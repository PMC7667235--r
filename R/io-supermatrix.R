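#' Write a partitioned supermatrix to disk
#'
#' Emits three files from one basepath: `<basepath>.fasta` (the concatenated
#' alignment), `<basepath>.phy` (relaxed PHYLIP: header `"ntaxa ncols"`, then
#' one `name<space>sequence` line per taxon, names up to 250 characters), and
#' `<basepath>.partitions` (one `DATATYPE, name = start-end` line per
#' partition, 1-based inclusive coordinates — the dialect accepted by common
#' maximum-likelihood tree programs).
#'
#' @param x A [PartitionedMatrix-class].
#' @param basepath Output path prefix (no extension).
#' @return Named character vector of the three file paths, invisibly.
#' @export
writeSupermatrix <- function(x, basepath) {
  stopifnot(is(x, "PartitionedMatrix"))
  aln <- alignment(x)
  pt <- partitions(x)
  paths <- c(fasta = paste0(basepath, ".fasta"),
             phylip = paste0(basepath, ".phy"),
             partitions = paste0(basepath, ".partitions"))
  writeFasta(aln, paths["fasta"])
  nm <- names(aln)
  if (any(nchar(nm) > 250L)) stop("taxon name exceeds 250 characters")
  writeLines(c(sprintf("%d %d", length(aln), Biostrings::width(aln)[1]),
               paste(nm, as.character(aln))), paths["phylip"])
  writeLines(sprintf("%s, %s = %d-%d", pt$datatype, pt$name, pt$start, pt$end),
             paths["partitions"])
  invisible(paths)
}

#' Read a supermatrix written by [writeSupermatrix()]
#'
#' @param basepath The basepath the matrix was written with.
#' @param alphabet Passed to [readFasta()].
#' @return A [PartitionedMatrix-class].
#' @export
readSupermatrix <- function(basepath, alphabet = "auto") {
  aln <- readFasta(paste0(basepath, ".fasta"), alphabet = alphabet)
  lines <- readLines(paste0(basepath, ".partitions"), warn = FALSE)
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines, regexec("^\\s*(\\S+)\\s*,\\s*(\\S+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", lines))
  if (any(lengths(m) != 5L)) stop("malformed partition line")
  pt <- data.frame(
    name = vapply(m, `[`, "", 3L),
    start = as.integer(vapply(m, `[`, "", 4L)),
    end = as.integer(vapply(m, `[`, "", 5L)),
    datatype = vapply(m, `[`, "", 2L),
    stringsAsFactors = FALSE
  )
  PartitionedMatrix(aln, pt)
}
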