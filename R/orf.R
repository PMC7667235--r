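STOPS <- c("TAA", "TAG", "TGA")

# Codons of one frame of a character sequence (vector of 3-char strings).
frameCodons <- function(seqchars, offset) {
  n <- length(seqchars)
  starts <- seq(offset + 1L, n - 2L, by = 3L)
  if (length(starts) == 0L || starts[1] > n - 2L) return(character(0))
  vapply(starts, function(i) paste(seqchars[i:(i + 2L)], collapse = ""), "")
}

#' Longest open reading frame across all six frames
#'
#' Scans the three forward and three reverse-complement frames. An ORF runs
#' from the first in-frame start codon after a stop (or from the frame edge)
#' through the next stop codon; with `require_start = FALSE` the whole
#' stop-to-stop stretch counts instead. The longest ORF by protein length
#' wins; ties break by frame order (+1, +2, +3, -1, -2, -3) and then by the
#' 5'-most start within the frame. Translation excludes the stop codon.
#' Coordinates are 0-based half-open on the forward strand and cover the CDS
#' including its stop codon when present.
#'
#' @param seq A nucleotide sequence (character or [Biostrings::DNAString]),
#'   alphabet ACGTN.
#' @param require_start If `TRUE` (default) the ORF must begin with ATG; if
#'   `FALSE`, stop-to-stop open stretches are eligible (the dialect of some
#'   ORF finders).
#' @return Named list: `protein`, `cds` (includes trailing stop when present),
#'   `frame` (+1..+3, -1..-3), `strand`, `start`, `end` (0-based half-open,
#'   forward strand).
#' @examples
#' longestOrf("TTTATGAAATAAGG")
#' @export
longestOrf <- function(seq, require_start = TRUE) {
  s <- toupper(as.character(seq))
  if (nchar(s) < 3L) stop("sequence shorter than one codon")
  if (!grepl("^[ACGTN]*$", s)) stop("sequence alphabet must be ACGTN")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  n <- nchar(s)
  best <- NULL
  frame_defs <- list(c(strand = "+", off = 0), c(strand = "+", off = 1),
                     c(strand = "+", off = 2), c(strand = "-", off = 0),
                     c(strand = "-", off = 1), c(strand = "-", off = 2))
  for (fi in seq_along(frame_defs)) {
    fd <- frame_defs[[fi]]
    strand <- fd[["strand"]]
    off <- as.integer(fd[["off"]])
    chars <- strsplit(if (strand == "+") s else rc, "")[[1]]
    codons <- frameCodons(chars, off)
    if (!length(codons)) next
    is_stop <- codons %in% STOPS
    # segment boundaries: stretches between stops (and sequence edges)
    seg_start <- 1L
    k <- length(codons)
    for (j in seq_len(k + 1L)) {
      at_end <- j > k
      if (at_end || is_stop[j]) {
        seg_end <- j - 1L          # last sense codon of the open stretch
        if (seg_end >= seg_start) {
          cand_start <- seg_start
          if (require_start) {
            atg <- which(codons[seg_start:seg_end] == "ATG")
            cand_start <- if (length(atg)) seg_start + atg[1] - 1L else NA_integer_
          }
          if (!is.na(cand_start)) {
            plen <- seg_end - cand_start + 1L
            if (is.null(best) || plen > best$plen) {
              has_stop <- !at_end
              cds_codons <- cand_start:(if (has_stop) j else seg_end)
              best <- list(plen = plen, frame_index = fi, strand = strand,
                           off = off, codon_from = cds_codons[1],
                           codon_to = cds_codons[length(cds_codons)],
                           has_stop = has_stop,
                           codons = codons[cds_codons])
            }
          }
        }
        seg_start <- j + 1L
      }
    }
  }
  if (is.null(best) || best$plen < 1L) stop("no open reading frame found")
  cds <- paste(best$codons, collapse = "")
  prot_codons <- if (best$has_stop) best$codons[-length(best$codons)] else best$codons
  protein <- paste(Biostrings::GENETIC_CODE[prot_codons], collapse = "")
  # frame-local 0-based coords, then map to forward strand
  local_start <- best$off + (best$codon_from - 1L) * 3L
  local_end <- best$off + best$codon_to * 3L
  if (best$strand == "+") {
    start <- local_start; end <- local_end
  } else {
    start <- n - local_end; end <- n - local_start
  }
  frame_label <- c(1L, 2L, 3L, -1L, -2L, -3L)[best$frame_index]
  list(protein = protein, cds = cds, frame = frame_label,
       strand = best$strand, start = start, end = end)
}
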