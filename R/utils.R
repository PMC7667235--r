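# Residue code conversions built on the standard amino-acid code table.

threeToOne <- function(codes) {
  tab <- Biostrings::AMINO_ACID_CODE  # names: 1-letter; values: 3-letter
  rev <- stats::setNames(names(tab), tab)
  out <- rev[codes]
  if (any(is.na(out))) {
    stop("unknown 3-letter residue code(s): ",
         paste(unique(codes[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

oneToThree <- function(codes) {
  out <- Biostrings::AMINO_ACID_CODE[codes]
  if (any(is.na(out))) {
    stop("unknown residue(s): ", paste(unique(codes[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

# Character matrix (rows = sequences) from an equal-width XStringSet.
alignmentMatrix <- function(aln) {
  assertAligned(aln)
  m <- do.call(rbind, strsplit(as.character(aln), ""))
  rownames(m) <- names(aln)
  m
}

extdataPath <- function(file) {
  p <- system.file("extdata", file, package = "c4origins", mustWork = FALSE)
  if (!nzchar(p)) stop("packaged data file not found: ", file)
  p
}
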