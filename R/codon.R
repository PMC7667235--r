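#' Back-translate a protein alignment to a codon alignment
#'
#' Each residue column becomes the corresponding codon of that sequence's CDS;
#' gap columns become `"---"`. A trailing stop codon on the CDS is stripped.
#' The CDS must translate exactly to the aligned residues (`X` residues accept
#' any codon); a mismatch is an error naming the sequence and residue index.
#'
#' @param protein_aln [Biostrings::AAStringSet] protein alignment.
#' @param cds Named [Biostrings::DNAStringSet] (or character vector) of
#'   unaligned coding sequences covering every row of the alignment.
#' @return A [Biostrings::DNAStringSet] codon alignment of width
#'   `3 * ncol(protein_aln)`.
#' @examples
#' aln <- Biostrings::AAStringSet(c(s1 = "M-K"))
#' backtranslate(aln, c(s1 = "ATGAAA"))
#' @export
backtranslate <- function(protein_aln, cds) {
  assertAligned(protein_aln, "protein alignment")
  cds <- stats::setNames(toupper(as.character(cds)), names(cds))
  missing <- setdiff(names(protein_aln), names(cds))
  if (length(missing)) {
    stop("no CDS for sequence(s): ", paste(missing, collapse = ", "))
  }
  out <- vapply(names(protein_aln), function(id) {
    row <- strsplit(as.character(protein_aln[[id]]), "")[[1]]
    nongap <- row != "-"
    n_res <- sum(nongap)
    cd <- cds[[id]]
    if (nchar(cd) == 3 * (n_res + 1)) {
      tail3 <- substr(cd, nchar(cd) - 2, nchar(cd))
      if (tail3 %in% STOPS) cd <- substr(cd, 1, nchar(cd) - 3)
    }
    if (nchar(cd) != 3 * n_res) {
      stop(sprintf("CDS length for %s is %d nt; expected %d (3 x %d residues)",
                   id, nchar(cd), 3 * n_res, n_res))
    }
    codons <- substring(cd, seq(1, nchar(cd), 3), seq(3, nchar(cd), 3))
    aa <- unname(Biostrings::GENETIC_CODE[codons])
    aa[is.na(aa)] <- "X"
    res <- row[nongap]
    bad <- which(aa != res & res != "X" & aa != "X")
    if (length(bad)) {
      stop(sprintf("translation mismatch for %s at residue %d: codon %s gives %s, alignment has %s",
                   id, bad[1], codons[bad[1]], aa[bad[1]], res[bad[1]]))
    }
    full <- rep("---", length(row))
    full[nongap] <- codons
    paste(full, collapse = "")
  }, "")
  Biostrings::DNAStringSet(out)
}

#' Trim gappy codon columns from a codon alignment
#'
#' Whole codons are evaluated and removed together so the reading frame is
#' preserved: codon column j is kept iff the fraction of sequences with a
#' non-gap codon there is at least `gap_threshold` (boundary inclusive).
#'
#' @param codon_aln [Biostrings::DNAStringSet] codon alignment, width
#'   divisible by 3.
#' @param gap_threshold Minimum kept fraction of non-gap sequences per codon
#'   column, in `[0, 1]`; 0 removes nothing, 1 keeps only complete columns.
#' @return Named list: `alignment` (trimmed [Biostrings::DNAStringSet]) and
#'   `kept_codons` (integer vector of original 1-based codon-column indices
#'   retained, the coordinate map back to the input).
#' @export
trimCodonColumns <- function(codon_aln, gap_threshold = 0.5) {
  assertAligned(codon_aln, "codon alignment")
  w <- Biostrings::width(codon_aln)[1]
  if (w %% 3 != 0) stop("codon alignment width not a multiple of 3")
  n_codons <- w %/% 3
  chars <- as.character(codon_aln)
  codon_mat <- vapply(chars, function(s) {
    substring(s, seq(1, w, 3), seq(3, w, 3))
  }, character(n_codons))
  if (n_codons == 1L) codon_mat <- matrix(codon_mat, nrow = 1L)
  nongap_frac <- rowMeans(codon_mat != "---")
  keep <- which(nongap_frac >= gap_threshold)
  trimmed <- apply(codon_mat[keep, , drop = FALSE], 2, paste, collapse = "")
  if (length(keep) == 0L) trimmed <- stats::setNames(rep("", ncol(codon_mat)),
                                                     colnames(codon_mat))
  out <- Biostrings::DNAStringSet(trimmed)
  names(out) <- names(codon_aln)
  list(alignment = out, kept_codons = keep)
}

#' Concatenate orthogroup alignments into a partitioned supermatrix
#'
#' Orthogroups are ordered by id; each contributes one partition. A roster
#' species absent from an orthogroup is padded with gaps across that
#' partition's columns.
#'
#' @param alignments Named list (names = orthogroup ids) of equal-width
#'   [Biostrings::XStringSet]s whose row names are species.
#' @param roster Character vector of all taxa; defaults to the union of row
#'   names.
#' @param datatype Partition datatype label written to partition files
#'   (default `"DNA"`).
#' @return A [PartitionedMatrix-class].
#' @export
concatenateAlignments <- function(alignments, roster = NULL, datatype = "DNA") {
  if (is.null(names(alignments)) || any(!nzchar(names(alignments)))) {
    stop("alignments must be named by orthogroup id")
  }
  alignments <- alignments[order(names(alignments))]
  if (is.null(roster)) {
    roster <- sort(unique(unlist(lapply(alignments, names))))
  }
  rows <- stats::setNames(rep("", length(roster)), roster)
  pt <- list()
  pos <- 0L
  for (og_id in names(alignments)) {
    aln <- alignments[[og_id]]
    assertAligned(aln, og_id)
    extra <- setdiff(names(aln), roster)
    if (length(extra)) {
      stop("species not in roster: ", paste(extra, collapse = ", "))
    }
    w <- Biostrings::width(aln)[1]
    chars <- stats::setNames(as.character(aln), names(aln))
    block <- ifelse(roster %in% names(aln),
                    chars[roster], strrep("-", w))
    rows <- paste0(rows, block)
    pt[[length(pt) + 1L]] <- data.frame(
      name = og_id, start = pos + 1L, end = pos + w,
      datatype = datatype, stringsAsFactors = FALSE)
    pos <- pos + w
  }
  names(rows) <- roster
  aln_out <- if (datatype == "DNA") Biostrings::DNAStringSet(rows)
             else Biostrings::AAStringSet(rows)
  PartitionedMatrix(aln_out, do.call(rbind, pt))
}

#' Slice one partition back out of a supermatrix
#'
#' @param x A [PartitionedMatrix-class].
#' @param name Partition name.
#' @param drop_gap_only_rows Drop taxa that are entirely gaps in the
#'   partition (the padding rows), default `TRUE`.
#' @return An [Biostrings::XStringSet] of the partition's columns.
#' @export
extractPartition <- function(x, name, drop_gap_only_rows = TRUE) {
  pt <- partitions(x)
  i <- match(name, pt$name)
  if (is.na(i)) stop("no partition named ", name)
  sub <- Biostrings::subseq(alignment(x), start = pt$start[i], end = pt$end[i])
  if (drop_gap_only_rows) {
    allgap <- vapply(as.character(sub),
                     function(s) all(strsplit(s, "")[[1]] == "-"), TRUE)
    sub <- sub[!allgap]
  }
  sub
}
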