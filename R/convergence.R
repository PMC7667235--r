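#' Map alignment columns to reference residue numbers
#'
#' One-based residue numbering over the reference row's non-gap columns;
#' columns where the reference is gapped map to no position.
#'
#' @param aln An equal-width [Biostrings::XStringSet].
#' @param reference_id Name of the reference row.
#' @return Named list: `pos_to_col` (integer vector, index = residue number),
#'   `col_to_pos` (integer vector over columns, `NA` at reference gaps),
#'   `n_positions`.
#' @export
mapReferencePositions <- function(aln, reference_id) {
  assertAligned(aln)
  if (!reference_id %in% names(aln)) {
    stop("reference ", reference_id, " absent from alignment")
  }
  chars <- strsplit(as.character(aln[[reference_id]]), "")[[1]]
  nongap <- which(chars != "-")
  col_to_pos <- rep(NA_integer_, length(chars))
  col_to_pos[nongap] <- seq_along(nongap)
  list(pos_to_col = nongap, col_to_pos = col_to_pos,
       n_positions = length(nongap))
}

#' Residues observed per clade at catalogued reference positions
#'
#' @param aln Protein alignment including the reference and all clade members.
#' @param clades Named list, clade -> member sequence ids.
#' @param catalog Site catalog (`data.frame` with a `position` column of
#'   1-based reference residue numbers), e.g. [pepcSiteCatalog()].
#' @param reference_id Reference row used for the coordinate system.
#' @return A list matrix (clades x positions); each cell is the sorted set of
#'   3-letter residue codes observed across the clade's members at that site
#'   (gaps dropped). A singleton set is the clade consensus; larger sets are
#'   polymorphic.
#' @export
cladeResidues <- function(aln, clades, catalog, reference_id) {
  map <- mapReferencePositions(aln, reference_id)
  if (any(catalog$position > map$n_positions)) {
    stop("catalog position beyond reference length (",
         map$n_positions, " residues)")
  }
  missing <- setdiff(unlist(clades), names(aln))
  if (length(missing)) {
    stop("clade member(s) absent from alignment: ",
         paste(missing, collapse = ", "))
  }
  cols <- map$pos_to_col[catalog$position]
  m <- alignmentMatrix(aln)
  out <- matrix(vector("list", length(clades) * length(cols)),
                nrow = length(clades), ncol = length(cols),
                dimnames = list(names(clades), as.character(catalog$position)))
  for (cl in names(clades)) {
    sub <- m[clades[[cl]], cols, drop = FALSE]
    for (j in seq_along(cols)) {
      res <- unique(sub[, j])
      res <- res[res != "-"]
      out[[cl, j]] <- if (length(res)) sort(oneToThree(res)) else character(0)
    }
  }
  out
}

#' Score convergent substitutions against a positively-selected-site catalog
#'
#' A site is convergent for a clade when the clade consensus residue is one of
#' the residues selected in C4 grasses at that site AND differs from the C3
#' sister clade's consensus. When the C3 sister already carries a grass-C4
#' residue the site is flagged `ancestral_shared` and not counted (the
#' substitution predates the C4 transition). Polymorphic clades (no single
#' consensus) score as `partial` when any member matches; partial sites are
#' reported separately and excluded from `n_convergent` unless
#' `count_partial = TRUE`.
#'
#' @param residues A clade x site list matrix from [cladeResidues()], or a
#'   character matrix of comma-separated 3-letter codes with the same shape.
#' @param catalog Site catalog with columns `position` and
#'   `c4_grass_residues` (comma-separated 3-letter codes).
#' @param c3_sister_clade Row name of the designated C3 sister clade.
#' @param count_partial Count polymorphic any-member matches as convergent.
#' @return Named list: `sites` (`data.frame`: `position`, one row per clade x
#'   site with `clade`, `observed`, `status` in
#'   `convergent`/`partial`/`ancestral_shared`/`not_convergent`), and
#'   `clades` (`data.frame`: `clade`, `n_convergent`, `n_partial`,
#'   `n_catalog_sites`, `fraction`).
#' @export
scoreConvergence <- function(residues, catalog, c3_sister_clade,
                             count_partial = FALSE) {
  if (is.character(residues)) {
    residues <- matrix(lapply(residues, function(s) {
      r <- trimws(strsplit(s, ",")[[1]])
      r[nzchar(r)]
    }), nrow = nrow(residues), dimnames = dimnames(residues))
  }
  if (!c3_sister_clade %in% rownames(residues)) {
    stop("C3 sister clade ", c3_sister_clade, " not in residue matrix")
  }
  pos <- as.character(catalog$position)
  stopifnot(all(pos %in% colnames(residues)))
  grass <- lapply(strsplit(catalog$c4_grass_residues, ","), trimws)
  names(grass) <- pos
  test_clades <- setdiff(rownames(residues), c3_sister_clade)
  sites <- list()
  for (cl in test_clades) {
    for (p in pos) {
      obs <- residues[[cl, p]]
      sis <- residues[[c3_sister_clade, p]]
      sis_cons <- if (length(sis) == 1L) sis else NA_character_
      status <- if (length(obs) == 0L) {
        "not_convergent"
      } else if (!is.na(sis_cons) && sis_cons %in% grass[[p]]) {
        "ancestral_shared"
      } else if (length(obs) == 1L) {
        if (obs %in% grass[[p]] &&
            (is.na(sis_cons) || obs != sis_cons)) "convergent"
        else "not_convergent"
      } else {
        if (any(obs %in% grass[[p]])) "partial" else "not_convergent"
      }
      sites[[length(sites) + 1L]] <- data.frame(
        clade = cl, position = as.integer(p),
        observed = paste(obs, collapse = ", "),
        c4_grass = paste(grass[[p]], collapse = ", "),
        c3_sister = paste(sis, collapse = ", "),
        status = status, stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, sites)
  clades <- do.call(rbind, lapply(test_clades, function(cl) {
    s <- sites[sites$clade == cl, ]
    n_conv <- sum(s$status == "convergent") +
      if (count_partial) sum(s$status == "partial") else 0L
    data.frame(clade = cl, n_convergent = n_conv,
               n_partial = sum(s$status == "partial"),
               n_ancestral_shared = sum(s$status == "ancestral_shared"),
               n_catalog_sites = length(pos),
               fraction = n_conv / length(pos), stringsAsFactors = FALSE)
  }))
  list(sites = sites, clades = clades)
}

#' Packaged catalog of positively selected PEPC sites
#'
#' Reference positions (maize PEPC numbering) under positive selection in C4
#' grass PEP carboxylases, with the residue(s) selected in C4 grasses, the
#' residue of the C3 reference lineage, and the posterior-probability class
#' of the selection signal. Shipped in `extdata` together with the residues
#' observed in the two C4 clades for direct re-scoring.
#'
#' @param with_observations If `TRUE`, also return the observed clade
#'   residues as an attribute-free residue matrix (see [cladeResidues()]).
#' @return A `data.frame` with columns `position`, `confidence_class`,
#'   `c4_grass_residues`, `c3_reference_residue`; with
#'   `with_observations = TRUE`, a list of `catalog` plus `residues`.
#' @export
pepcSiteCatalog <- function(with_observations = FALSE) {
  x <- read.delim(extdataPath("pepc_selected_sites.tsv"),
                  stringsAsFactors = FALSE)
  catalog <- x[, c("position", "confidence_class", "c4_grass_residues",
                   "c3_reference_residue")]
  if (!with_observations) return(catalog)
  clade_cols <- c(Boerhavia_Okenia = "boerhavia_okenia",
                  Allionia = "allionia", C3_Nyctagineae = "c3_nyctagineae")
  residues <- t(as.matrix(x[, clade_cols]))
  rownames(residues) <- names(clade_cols)
  colnames(residues) <- as.character(x$position)
  list(catalog = catalog, residues = residues)
}
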