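#' Chlorophyll content from 80%-acetone absorbances
#'
#' The standard two-wavelength equations for chlorophyll in 80% acetone:
#' `chl_a (mg/L) = 12.7 * A663 - 2.69 * A645` and
#' `chl_b (mg/L) = 22.9 * A645 - 4.68 * A663`. Concentrations are converted
#' to a leaf-area basis (mmol m-2) with the molar masses 893.5 g/mol (chl a)
#' and 907.5 g/mol (chl b) and the extract volume per leaf area.
#'
#' @param a645,a663 Absorbances at 645 and 663 nm (non-negative).
#' @param dilution_l_per_m2 Litres of extract per m2 of leaf sampled.
#' @return Named list: `chl_a_mg_l`, `chl_b_mg_l`, `chl_a_mmol_m2`,
#'   `chl_b_mmol_m2`, `total_mmol_m2`, `ab_ratio` (molar a/b).
#' @examples
#' chlorophyllFromAbsorbance(a645 = 0.3, a663 = 0.8, dilution_l_per_m2 = 25)
#' @export
chlorophyllFromAbsorbance <- function(a645, a663, dilution_l_per_m2 = 1) {
  stopifnot(all(a645 >= 0), all(a663 >= 0), dilution_l_per_m2 > 0)
  chl_a <- 12.7 * a663 - 2.69 * a645
  chl_b <- 22.9 * a645 - 4.68 * a663
  if (any(chl_a < 0) || any(chl_b < 0)) {
    stop("negative chlorophyll concentration; are the wavelengths swapped?")
  }
  a_mmol_m2 <- chl_a / 893.5 * dilution_l_per_m2
  b_mmol_m2 <- chl_b / 907.5 * dilution_l_per_m2
  list(chl_a_mg_l = chl_a, chl_b_mg_l = chl_b,
       chl_a_mmol_m2 = a_mmol_m2, chl_b_mmol_m2 = b_mmol_m2,
       total_mmol_m2 = a_mmol_m2 + b_mmol_m2,
       ab_ratio = ifelse(b_mmol_m2 > 0, a_mmol_m2 / b_mmol_m2, Inf))
}

#' Enzyme activity per leaf area from an A340 time course
#'
#' Converts the NAD(P)(H) absorbance slope at 340 nm into a leaf-area-basis
#' activity: the slope over the extinction coefficient and path length gives
#' mM min-1 in the cuvette; times the assay volume gives umol min-1; scaled by
#' `extract_vol / aliquot` to the whole extract; divided by leaf area (m2) and
#' 60 s gives umol m-2 s-1.
#'
#' @param slope_a340_per_min Absorbance change per minute (sign ignored).
#' @param extract_vol_ml,assay_vol_ml,aliquot_ml Volumes (mL).
#' @param leaf_area_cm2 Leaf area extracted (cm2).
#' @param epsilon Millimolar extinction coefficient of NAD(P)H at 340 nm
#'   (6.22 mM-1 cm-1).
#' @param path_cm Cuvette path length (cm).
#' @return Activity in umol m-2 s-1.
#' @examples
#' activityFromA340(0.373, extract_vol_ml = 1, assay_vol_ml = 1,
#'                  aliquot_ml = 1, leaf_area_cm2 = 1)
#' @export
activityFromA340 <- function(slope_a340_per_min, extract_vol_ml, assay_vol_ml,
                             aliquot_ml, leaf_area_cm2,
                             epsilon = 6.22, path_cm = 1) {
  stopifnot(extract_vol_ml > 0, assay_vol_ml > 0, aliquot_ml > 0)
  if (leaf_area_cm2 <= 0) stop("leaf area must be positive")
  rate_mM_min <- abs(slope_a340_per_min) / (epsilon * path_cm)
  umol_min_cuvette <- rate_mM_min * assay_vol_ml   # mM x mL = umol
  umol_min_extract <- umol_min_cuvette * extract_vol_ml / aliquot_ml
  umol_min_extract / (leaf_area_cm2 * 1e-4) / 60
}

#' Assemble an enzyme panel with per-chlorophyll activities
#'
#' @param pepc,nadp_me,nad_me Area-basis activities (umol m-2 s-1).
#' @param chlorophyll Chlorophyll content (mmol m-2).
#' @param chl_ab_ratio Chlorophyll a/b molar ratio.
#' @return List with the area-basis activities plus `per_chl` (mmol mol-1
#'   Chl s-1 = area activity / chlorophyll).
#' @export
enzymePanel <- function(pepc, nadp_me, nad_me, chlorophyll,
                        chl_ab_ratio = NA_real_) {
  stopifnot(pepc >= 0, nadp_me >= 0, nad_me >= 0, chlorophyll > 0)
  list(pepc = pepc, nadp_me = nadp_me, nad_me = nad_me,
       chlorophyll = chlorophyll, chl_ab_ratio = chl_ab_ratio,
       per_chl = c(pepc = pepc, nadp_me = nadp_me, nad_me = nad_me) / chlorophyll)
}

#' Call the C4 biochemical subtype from a decarboxylase panel
#'
#' The subtype is the decarboxylase (NADP-malic enzyme vs NAD-malic enzyme)
#' with the higher area-basis activity. The call is `robust` when that
#' activity is at least the net assimilation rate at 400 umol mol-1 CO2 (an
#' enzyme cannot carry a flux below its in-leaf rate); between 0.5x and 1x
#' `a400` the call stands with a warning flag; when both decarboxylases fall
#' below `0.2 * a400` the panel is C3-consistent and the call is `"none"`.
#' PEP carboxykinase is not assayed by this panel and has no branch here.
#'
#' @param panel A list from [enzymePanel()].
#' @param a400 Net CO2 assimilation at 400 umol mol-1 (umol m-2 s-1).
#' @return Named list: `subtype` (`"NADP-ME"`, `"NAD-ME"` or `"none"`),
#'   `robust`, `warning` (activity below `a400`), `tie`.
#' @examples
#' p <- enzymePanel(pepc = 111.8, nadp_me = 50.1, nad_me = 2.1,
#'                  chlorophyll = 0.43)
#' callSubtype(p, a400 = 23.0)
#' @export
callSubtype <- function(panel, a400) {
  acts <- c("NADP-ME" = panel$nadp_me, "NAD-ME" = panel$nad_me)
  if (all(acts < 0.2 * a400)) {
    return(list(subtype = "none", robust = FALSE, warning = FALSE,
                tie = FALSE))
  }
  top <- max(acts)
  tie <- sum(acts == top) > 1L
  list(subtype = names(acts)[which.max(acts)],
       robust = top >= a400,
       warning = top < a400,
       tie = tie)
}

#' One-tailed Welch comparison of two replicate groups
#'
#' Welch two-sample t test, one-tailed in the direction of the observed
#' difference in means, so swapping the groups leaves the p-value unchanged.
#' Two constant groups with equal means return the symmetric null value 0.5.
#'
#' @param group_a,group_b Numeric vectors (at least 2 values each).
#' @return One-tailed p-value.
#' @export
oneTailedCompare <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    return(if (mean(group_a) == mean(group_b)) 0.5 else 0)
  }
  alt <- if (mean(group_a) >= mean(group_b)) "greater" else "less"
  t.test(group_a, group_b, alternative = alt, var.equal = FALSE)$p.value
}
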