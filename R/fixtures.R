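# Loaders for the small packaged datasets that make the family's C4-origins
# scenario a one-command reproduction.

#' Packaged Nyctagineae genus-level topology
#'
#' The genus-level topology of the North American xeric clade of the
#' Nyctaginaceae, transcribed from the phylotranscriptomic species tree:
#' Allionia sister to Cyphomeris at the base of a clade whose other half
#' holds (Anulocaulis, Nyctaginia) sister to (Okenia, Boerhavia), with
#' Commicarpus branching below and Mirabilis below that (the C3 rooting).
#'
#' @return An [ape::phylo] tree with 8 genus-level tips.
#' @examples
#' tr <- nyctagineaeTree()
#' fitchMinChanges(tr, nyctagineaeTipStates())
#' @export
nyctagineaeTree <- function() {
  readNewick(extdataPath("nyctagineae_tree.nwk"))
}

#' Packaged C3/C4 tip states for the Nyctagineae topology
#'
#' Pathway calls per genus from the delta13C survey: Allionia, Okenia and
#' Boerhavia C4 (1); the rest C3 (0).
#'
#' @return Named integer vector, leaf label -> 0/1.
#' @export
nyctagineaeTipStates <- function() {
  x <- read.delim(extdataPath("nyctagineae_tip_states.tsv"),
                  stringsAsFactors = FALSE)
  stats::setNames(as.integer(x$state), x$taxon)
}

#' Packaged per-genus delta13C survey ranges
#'
#' The per-genus range of species-mean delta13C from the herbarium survey
#' (21 genera with measured values across seven tribes), for re-running the
#' genus-level pathway classification. One published range is printed without
#' minus signs in the source table (an obvious typo) and is stored negated;
#' per-genus counts are the sampled species counts.
#'
#' @return `data.frame`: `tribe`, `genus`, `n_species_sampled`, `min_mean`,
#'   `max_mean`.
#' @export
nyctagineaeIsotopeRanges <- function() {
  read.delim(extdataPath("nyctagineae_isotope_ranges.tsv"),
             stringsAsFactors = FALSE)
}

#' Count C4 genera from packaged survey ranges
#'
#' A genus counts as C4 when both ends of its species-mean range classify C4
#' (observed C4 genera contain only C4 species).
#'
#' @param ranges Output of [nyctagineaeIsotopeRanges()].
#' @param thresholds Passed to [classifyDelta13C()].
#' @return The input with `is_c4_genus` appended.
#' @export
classifyGenusRanges <- function(ranges = nyctagineaeIsotopeRanges(),
                                thresholds = isotopeThresholds()) {
  lo <- classifyDelta13C(ranges$min_mean, thresholds)$label
  hi <- classifyDelta13C(ranges$max_mean, thresholds)$label
  ranges$is_c4_genus <- lo == "C4" & hi == "C4"
  ranges
}
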