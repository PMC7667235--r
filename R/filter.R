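#' Aligned overlap fraction between two rows of one alignment
#'
#' Number of columns where both rows are non-gap, divided by the shorter
#' row's non-gap length. Symmetric in its arguments.
#'
#' @param frag_a,frag_b Aligned rows (equal-length character strings or
#'   [Biostrings::XString]s).
#' @return Overlap fraction in `[0, 1]`.
#' @export
alignedOverlap <- function(frag_a, frag_b) {
  a <- strsplit(as.character(frag_a), "")[[1]]
  b <- strsplit(as.character(frag_b), "")[[1]]
  if (length(a) != length(b)) stop("rows come from different alignments")
  na <- a != "-"
  nb <- b != "-"
  if (!any(na) || !any(nb)) stop("a row is entirely gaps")
  sum(na & nb) / min(sum(na), sum(nb))
}

#' Resolve multiple sequences of one species within an orthogroup
#'
#' Multiple sequences from one species are assumed to be fragments of a
#' broken assembly when no pair overlaps by more than `threshold` of the
#' shorter sequence — in which case they are concatenated into one merged row
#' — and paralogs when any pair does, in which case the species is dropped
#' from the orthogroup. Merging takes, per column, the unique non-gap residue;
#' fragments are ordered by first non-gap column and on a doubly-covered
#' column the earlier-starting fragment's residue wins.
#'
#' @param rows Named character vector (or [Biostrings::AAStringSet]) of two or
#'   more aligned rows for one species.
#' @param threshold Maximum pairwise overlap fraction for merging
#'   (default 0.10).
#' @return Named list: `action` (`"merged"` or `"dropped"`), `row` (the merged
#'   row, or `NA` when dropped), `max_overlap`.
#' @export
resolveMulticopy <- function(rows, threshold = 0.10) {
  rows <- as.character(rows)
  if (length(rows) < 2L) stop("resolveMulticopy needs at least 2 rows")
  pairs <- utils::combn(length(rows), 2)
  ov <- apply(pairs, 2, function(p) alignedOverlap(rows[p[1]], rows[p[2]]))
  if (any(ov > threshold)) {
    return(list(action = "dropped", row = NA_character_,
                max_overlap = max(ov)))
  }
  mat <- do.call(rbind, strsplit(rows, ""))
  first_col <- apply(mat, 1, function(r) which(r != "-")[1])
  ord <- order(first_col)
  merged <- rep("-", ncol(mat))
  for (i in rev(ord)) {          # earlier-starting fragment written last, wins
    nz <- mat[i, ] != "-"
    merged[nz] <- mat[i, nz]
  }
  list(action = "merged", row = paste(merged, collapse = ""),
       max_overlap = max(ov))
}

#' Low-copy orthogroup filter configuration
#'
#' Defaults encode the selection used for a 53-species roster: at least 40 of
#' 53 species present (stored as the fraction 40/53 so the criterion
#' generalizes), at most 10% of species with multiple sequences, and at least
#' 100 aligned amino acids.
#'
#' @param min_species_present Count (when `> 1`) or fraction (when `<= 1`) of
#'   roster species that must remain present after fragment/paralog
#'   resolution.
#' @param max_multi_frac Maximum fraction of species with more than one
#'   sequence before resolution.
#' @param min_aln_len_aa Minimum alignment length (columns).
#' @param overlap_threshold Passed to [resolveMulticopy()].
#' @return Config list for [filterOrthogroups()].
#' @export
filterConfig <- function(min_species_present = 40 / 53,
                         max_multi_frac = 0.10,
                         min_aln_len_aa = 100,
                         overlap_threshold = 0.10) {
  stopifnot(min_species_present > 0, max_multi_frac >= 0,
            max_multi_frac <= 1, min_aln_len_aa > 0)
  list(min_species_present = min_species_present,
       max_multi_frac = max_multi_frac,
       min_aln_len_aa = min_aln_len_aa,
       overlap_threshold = overlap_threshold)
}

#' Select single- or low-copy orthogroups
#'
#' For each orthogroup: multicopy species are first resolved (fragments
#' merged, paralogs dropped — so merged fragments still count as present),
#' then the group is kept only if (in order) enough species remain present,
#' no more than `max_multi_frac` of the roster had multiple sequences before
#' resolution, and the alignment is long enough. The reason recorded is the
#' first failing rule.
#'
#' @param ogs List of [Orthogroup-class] objects with alignments attached.
#' @param config From [filterConfig()].
#' @param roster Character vector of roster species; defaults to the union of
#'   member species across `ogs`.
#' @return Named list: `kept` (list of resolved orthogroups, each with a
#'   single aligned row per surviving species, named by species),
#'   `report` (`data.frame`: `og_id`, `decision`, `reason`, `n_present`,
#'   `n_multi`, `aln_len`), and `resolutions` (`data.frame`: `og_id`,
#'   `species`, `resolution` in `single`/`merged_fragments`/`dropped_paralogs`).
#' @export
filterOrthogroups <- function(ogs, config = filterConfig(), roster = NULL) {
  if (is.null(roster)) {
    roster <- sort(unique(unlist(lapply(ogs, function(og) names(members(og))))))
  }
  n_roster <- length(roster)
  min_present <- if (config$min_species_present <= 1) {
    # small epsilon so 40/53 of a 53-species roster is exactly 40
    as.integer(ceiling(config$min_species_present * n_roster - 1e-9))
  } else {
    as.integer(config$min_species_present)
  }
  report <- list()
  resolutions <- list()
  kept <- list()
  for (og in ogs) {
    aln <- alignment(og)
    if (!length(aln)) stop("orthogroup ", ogId(og), " has no alignment")
    memb <- members(og)
    resolved <- character(0)           # species -> single aligned row
    n_multi <- 0L
    for (sp in names(memb)) {
      ids <- memb[[sp]]
      if (length(ids) == 0L) next
      if (length(ids) == 1L) {
        resolved[sp] <- as.character(aln[[ids]])
        res <- "single"
      } else {
        n_multi <- n_multi + 1L
        r <- resolveMulticopy(as.character(aln[ids]),
                              threshold = config$overlap_threshold)
        if (r$action == "merged") {
          resolved[sp] <- r$row
          res <- "merged_fragments"
        } else {
          res <- "dropped_paralogs"
        }
      }
      resolutions[[length(resolutions) + 1L]] <- data.frame(
        og_id = ogId(og), species = sp, resolution = res,
        stringsAsFactors = FALSE)
    }
    n_present <- length(resolved)
    aln_len <- Biostrings::width(aln)[1]
    reason <- "none"
    if (n_present < min_present) {
      reason <- "too_few_species"
    } else if (n_multi > config$max_multi_frac * n_roster) {
      reason <- "too_many_multicopy"
    } else if (aln_len < config$min_aln_len_aa) {
      reason <- "too_short"
    }
    report[[length(report) + 1L]] <- data.frame(
      og_id = ogId(og), decision = if (reason == "none") "kept" else "rejected",
      reason = reason, n_present = n_present, n_multi = n_multi,
      aln_len = aln_len, stringsAsFactors = FALSE)
    if (reason == "none") {
      new_aln <- Biostrings::AAStringSet(resolved)
      kept[[length(kept) + 1L]] <- Orthogroup(
        ogId(og),
        members = lapply(stats::setNames(nm = names(resolved)), function(s) s),
        alignment = new_aln)
    }
  }
  list(kept = kept,
       report = do.call(rbind, report),
       resolutions = do.call(rbind, resolutions))
}
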