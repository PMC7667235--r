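#' Read a tab-separated orthogroup membership table
#'
#' The expected dialect is the standard orthology-table layout: a header line
#' whose first column names the orthogroup-id column and whose remaining
#' columns are species; each data row holds an orthogroup id followed by one
#' cell per species containing a comma-separated list of sequence ids (empty
#' cell = species absent). Whitespace around ids is stripped.
#'
#' @param path Path to the TSV file.
#' @return A list of [Orthogroup-class] objects, in file order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("Orthogroup\tsp1\tsp2", "OG1\tsp1_g1\tsp2_g1, sp2_g2"), tf)
#' readOrthogroupTable(tf)
#' @export
readOrthogroupTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty orthogroup table: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  species <- header[-1]
  if (length(species) == 0L) stop("orthogroup table has no species columns")
  ncol_expected <- length(header)
  lapply(seq_along(cells)[-1], function(i) {
    row <- cells[[i]]
    # trailing empty cells may be dropped by strsplit; pad them back
    if (length(row) < ncol_expected &&
        nchar(lines[i]) - nchar(gsub("\t", "", lines[i], fixed = TRUE)) ==
          ncol_expected - 1L) {
      row <- c(row, rep("", ncol_expected - length(row)))
    }
    if (length(row) != ncol_expected) {
      stop(sprintf("row %d has %d columns, expected %d (ragged table)",
                   i, length(row), ncol_expected))
    }
    memb <- lapply(row[-1], function(cell) {
      ids <- trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
      ids[nzchar(ids)]
    })
    names(memb) <- species
    Orthogroup(ogId = row[1], members = memb)
  })
}

#' Write an orthogroup table
#'
#' Inverse of [readOrthogroupTable()].
#'
#' @param ogs List of [Orthogroup-class] objects sharing a species roster.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeOrthogroupTable <- function(ogs, path) {
  species <- names(members(ogs[[1]]))
  lines <- c(paste(c("Orthogroup", species), collapse = "\t"),
             vapply(ogs, function(og) {
               cells <- vapply(members(og)[species],
                               function(ids) paste(ids, collapse = ", "), "")
               paste(c(ogId(og), cells), collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}
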