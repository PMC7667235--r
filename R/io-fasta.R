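#' @importClassesFrom Biostrings XStringSet AAStringSet DNAStringSet BStringSet
NULL

# Decide nucleotide vs protein from residue content (gaps ignored).
guessAlphabet <- function(chars) {
  letters_only <- gsub("[-]", "", chars)
  nuc <- grepl("^[ACGTUN]*$", letters_only)
  if (all(nuc)) "nucleotide" else "protein"
}

#' Read a FASTA file
#'
#' Reads sequences preserving order. The identifier is the first whitespace
#' token of the header; any remainder is kept as a per-sequence `description`
#' attribute. Residues are uppercased and the alternative gap characters
#' `?` and `.` are normalized to `-`.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"auto"` (default) detects nucleotide vs protein from
#'   residue content; `"nucleotide"` or `"protein"` force the type.
#' @return A [Biostrings::DNAStringSet] or [Biostrings::AAStringSet]; sequence
#'   descriptions (header text after the identifier) are in
#'   `attr(x, "description")`.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a first", "ACGT", ">b", "AC-T"), tf)
#' readFasta(tf)
#' @export
readFasta <- function(path, alphabet = c("auto", "nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate sequence identifier(s): ", paste(unique(dup), collapse = ", "))
  }
  chars <- toupper(as.character(raw))
  chars <- gsub("[?.]", "-", chars)
  if (any(!nzchar(chars))) {
    stop("empty sequence(s): ", paste(ids[!nzchar(chars)], collapse = ", "))
  }
  if (alphabet == "auto") alphabet <- guessAlphabet(chars)
  out <- if (alphabet == "nucleotide") {
    Biostrings::DNAStringSet(chars)
  } else {
    Biostrings::AAStringSet(chars)
  }
  names(out) <- ids
  attr(out, "description") <- stats::setNames(desc, ids)
  out
}

#' Write sequences to FASTA
#'
#' Lines are wrapped at 60 residues. Descriptions stored by [readFasta()] are
#' re-emitted after the identifier.
#'
#' @param x An [Biostrings::XStringSet] (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  desc <- attr(x, "description")
  y <- x
  if (!is.null(desc)) {
    has <- nzchar(desc[names(x)]) & !is.na(desc[names(x)])
    names(y) <- ifelse(has, paste(names(x), desc[names(x)]), names(x))
  }
  Biostrings::writeXStringSet(y, path, width = 60L)
  invisible(path)
}

# All rows equal width, at least one row.
assertAligned <- function(x, what = "alignment") {
  if (length(x) == 0L) stop(what, " is empty")
  if (length(unique(Biostrings::width(x))) != 1L) {
    stop(what, " rows differ in width; not an alignment")
  }
  invisible(x)
}
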