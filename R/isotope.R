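#' Classification thresholds for carbon isotope ratios
#'
#' Survey-derived delta13C windows: C4 tissue falls roughly between -10 and
#' -16 permil and C3 tissue between -23 and -32 permil, with C4-like
#' (intermediate species running a strong C4 cycle) between -16 and -22. The
#' printed windows leave gaps and are crossed by real observations (C4 species
#' means up to -9.4; a C3 call at -22.6), so the default rule uses half-open
#' boundaries at -16 and -22 with no gap: values at or above -16 are C4,
#' values in [-22, -16) are C4-like, values below -22 are C3. A C3 call above
#' the `borderline` limit (-24) is flagged `borderline_c3` — arid-zone C3
#' species with high water-use efficiency can reach such values. Values above
#' -8 or below -35 are flagged `out_of_range`.
#'
#' @param c4_min C4 lower boundary (permil), default -16.
#' @param c4like_min C4-like lower boundary, default -22.
#' @param borderline C3 calls above this are flagged, default -24.
#' @param range Plausible measurement window, default `c(-35, -8)`.
#' @return A list of thresholds consumed by [classifyDelta13C()].
#' @export
isotopeThresholds <- function(c4_min = -16, c4like_min = -22,
                              borderline = -24, range = c(-35, -8)) {
  stopifnot(c4_min > c4like_min)
  list(c4_min = c4_min, c4like_min = c4like_min,
       borderline = borderline, range = range)
}

#' Classify delta13C values into photosynthetic pathway
#'
#' @param value Numeric vector of delta13C values (permil, negative).
#' @param thresholds A list from [isotopeThresholds()].
#' @return `data.frame` with columns `delta13c`, `label` (`"C3"`, `"C4-like"`,
#'   `"C4"`), `borderline_c3`, `out_of_range`.
#' @examples
#' classifyDelta13C(c(-13.3, -26.2, -22.6, -19.0))
#' @export
classifyDelta13C <- function(value, thresholds = isotopeThresholds()) {
  if (any(!is.finite(value))) stop("delta13C values must be finite")
  th <- thresholds
  label <- ifelse(value >= th$c4_min, "C4",
                  ifelse(value >= th$c4like_min, "C4-like", "C3"))
  data.frame(
    delta13c = value,
    label = factor(label, levels = c("C3", "C4-like", "C4")),
    borderline_c3 = label == "C3" & value > th$borderline,
    out_of_range = value > th$range[2] | value < th$range[1])
}

#' Per-species mean delta13C over replicate specimens
#'
#' Species are keyed by (genus, species); replicates from different genera are
#' never pooled even if species epithets collide.
#'
#' @param records `data.frame` with columns `genus`, `species`, `delta13c`,
#'   and optionally `tribe`.
#' @return `data.frame` with one row per (genus, species): `tribe`, `genus`,
#'   `species`, `n_specimens`, `mean_delta13c`.
#' @export
speciesMeans <- function(records) {
  stopifnot(all(c("genus", "species", "delta13c") %in% names(records)))
  if (is.null(records$tribe)) records$tribe <- "Unplaced"
  key <- interaction(records$genus, records$species, drop = TRUE)
  idx <- split(seq_len(nrow(records)), key)
  out <- do.call(rbind, lapply(idx, function(i) {
    data.frame(tribe = records$tribe[i[1]],
               genus = records$genus[i[1]],
               species = records$species[i[1]],
               n_specimens = length(i),
               mean_delta13c = mean(records$delta13c[i]),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$tribe, out$genus, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-genus survey summary
#'
#' Reproduces the survey-table semantics: per genus, the number of species
#' sampled, the range (min, max) of species-mean delta13C, and the number of
#' species whose mean classifies as C4. Genera are ordered by tribe then
#' genus name. A genus is scored `is_c4_genus` when every sampled species mean
#' classifies C4 (observed C4 genera contain only C4 species).
#'
#' @param records Specimen-level `data.frame` (see [speciesMeans()]).
#' @param thresholds Passed to [classifyDelta13C()].
#' @return `data.frame`: `tribe`, `genus`, `n_species_sampled`, `min_mean`,
#'   `max_mean`, `n_c4_species`, `is_c4_genus`.
#' @export
summarizeSurvey <- function(records, thresholds = isotopeThresholds()) {
  sm <- speciesMeans(records)
  sm$label <- classifyDelta13C(sm$mean_delta13c, thresholds)$label
  idx <- split(seq_len(nrow(sm)), sm$genus)
  out <- do.call(rbind, lapply(idx, function(i) {
    data.frame(tribe = sm$tribe[i[1]],
               genus = sm$genus[i[1]],
               n_species_sampled = length(i),
               min_mean = min(sm$mean_delta13c[i]),
               max_mean = max(sm$mean_delta13c[i]),
               n_c4_species = sum(sm$label[i] == "C4"),
               is_c4_genus = all(sm$label[i] == "C4"),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$tribe, out$genus), , drop = FALSE]
  rownames(out) <- NULL
  out
}
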