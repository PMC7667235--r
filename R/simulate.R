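# Synthetic-data generators. Each is a deterministic function of its arguments
# plus `seed`; the defaults are the study conditions the rest of the package
# is tested against (see the methods vignette for their provenance).

# Truncated-normal draws by inverse-CDF so truncation costs no rejections.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  p <- runif(n, pnorm(lower, mean, sd), pnorm(upper, mean, sd))
  qnorm(p, mean, sd)
}

#' Simulate a herbarium carbon-isotope survey
#'
#' Draws per-specimen delta13C values for a design of genera with known
#' photosynthetic pathway. Values are normal draws from the pathway's
#' distribution, truncated to the survey window, so the ground-truth label is
#' carried alongside each record. Defaults place the C3 and C4 modes at the
#' centres of the ranges observed in real surveys (C3 around -27 permil, C4
#' around -12.5 permil), well separated relative to their spreads.
#'
#' @param genera `data.frame` with columns `genus`, `n_species`, `pathway`
#'   (`"C3"` or `"C4"`), and optionally `tribe`.
#' @param c3_mean,c3_sd,c4_mean,c4_sd Pathway distribution parameters (permil).
#' @param replicates Integer range of specimens per species (sampled
#'   uniformly).
#' @param bounds Truncation window (permil), default `c(-32, -9)`.
#' @param seed Integer seed; same seed and design give an identical table.
#' @return `data.frame` with columns `specimen_id`, `tribe`, `genus`,
#'   `species`, `delta13c`, `true_pathway`.
#' @examples
#' gen <- data.frame(genus = c("GenA", "GenB"), n_species = c(3, 2),
#'                   pathway = c("C4", "C3"))
#' head(simulateIsotopeSurvey(gen, seed = 1))
#' @export
simulateIsotopeSurvey <- function(genera,
                                  c3_mean = -27.0, c3_sd = 1.5,
                                  c4_mean = -12.5, c4_sd = 1.2,
                                  replicates = 2:3,
                                  bounds = c(-32, -9),
                                  seed = NULL) {
  stopifnot(c3_sd > 0, c4_sd > 0, c4_mean > c3_mean,
            all(genera$pathway %in% c("C3", "C4")))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(genera$tribe)) genera$tribe <- "Unplaced"
  rows <- list()
  for (g in seq_len(nrow(genera))) {
    pw <- genera$pathway[g]
    mu <- if (pw == "C4") c4_mean else c3_mean
    sig <- if (pw == "C4") c4_sd else c3_sd
    for (s in seq_len(genera$n_species[g])) {
      n_rep <- if (length(replicates) > 1) sample(replicates, 1) else replicates
      vals <- rtruncnorm(n_rep, mu, sig, bounds[1], bounds[2])
      sp <- sprintf("%s_sp%02d", genera$genus[g], s)
      rows[[length(rows) + 1L]] <- data.frame(
        specimen_id = sprintf("%s_r%d", sp, seq_len(n_rep)),
        tribe = genera$tribe[g], genus = genera$genus[g], species = sp,
        delta13c = vals, true_pathway = pw, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a stepped A/Ci gas-exchange curve
#'
#' The noiseless response is a non-rectangular hyperbola between the
#' CO2-limited line `v = slope * (ci - gamma)` and the CO2-saturated ceiling
#' `a_max`, with curvature `theta`:
#' `A* = (v + a_max - sqrt((v + a_max)^2 - 4 * theta * v * a_max)) / (2 * theta)`,
#' clamped to `A* = v` when `v <= 0` so the response crosses zero exactly at
#' the compensation point. At the default `theta = 1` this reduces to
#' `A* = min(v, a_max)`, so the initial slope below the breakpoint is exactly
#' `slope`. `ci = ci_ca_ratio * ca` at every step; stomatal conductance is
#' derived from A via the 1.6 water/CO2 diffusivity ratio with a small floor —
#' a generator convenience, not a stomatal model.
#'
#' @param slope Initial slope (carboxylation efficiency), mol m-2 s-1.
#' @param gamma CO2 compensation point, umol mol-1.
#' @param a_max CO2-saturated assimilation rate, umol m-2 s-1.
#' @param theta Curvature in (0, 1]; 1 = Blackman (two-limb) response.
#' @param ci_ca_ratio Ratio of intercellular to ambient CO2; about 0.33 for C4
#'   leaves and 0.60 for C3 leaves.
#' @param ca_steps Ambient CO2 steps (umol mol-1). The default covers the
#'   measurement protocol: equilibration at 400, a saturating step at 1200,
#'   then stepwise reduction toward the compensation point (13 steps).
#' @param noise_sd Gaussian noise added to A (umol m-2 s-1).
#' @param leafT,pfd Metadata stored on the curve.
#' @param seed Integer seed.
#' @return An [AciCurve-class].
#' @examples
#' crv <- simulateAciCurve(slope = 0.25, gamma = 4.5, a_max = 31.3,
#'                         noise_sd = 0, seed = 1)
#' fitInitialSlope(crv)
#' @export
simulateAciCurve <- function(slope = 0.25, gamma = 4.5, a_max = 31.3,
                             theta = 1, ci_ca_ratio = 0.33,
                             ca_steps = c(400, 1200, 1000, 800, 600, 450, 350,
                                          250, 180, 120, 90, 60, 40, 25),
                             noise_sd = 0, leafT = 30, pfd = 1800,
                             seed = NULL) {
  stopifnot(slope > 0, gamma >= 0, a_max > 0, theta > 0, theta <= 1,
            ci_ca_ratio > 0, ci_ca_ratio < 1)
  if (!is.null(seed)) set.seed(seed)
  ci <- ci_ca_ratio * ca_steps
  if (any(ca_steps <= ci)) stop("configuration gives ci >= ca")
  v <- slope * (ci - gamma)
  a_star <- ifelse(v <= 0, v,
    (v + a_max - sqrt((v + a_max)^2 - 4 * theta * v * a_max)) / (2 * theta))
  a <- a_star + if (noise_sd > 0) rnorm(length(ci), 0, noise_sd) else 0
  gs <- 1.6 * pmax(a, 0.01) / (ca_steps - ci)
  aciCurve(ca = ca_steps, ci = ci, a = a, gs = gs, leafT = leafT, pfd = pfd)
}

# Fixed reverse codon table: one canonical codon per amino acid.
aaToCodon <- local({
  gc <- Biostrings::GENETIC_CODE
  sense <- gc[gc != "*"]
  tab <- tapply(names(sense), sense, `[`, 1L)
  tab[order(names(tab))]
})

randomProtein <- function(n) {
  paste(sample(names(aaToCodon), n, replace = TRUE), collapse = "")
}

mutateProtein <- function(aa, prob) {
  chars <- strsplit(aa, "")[[1]]
  hit <- runif(length(chars)) < prob
  chars[hit] <- sample(names(aaToCodon), sum(hit), replace = TRUE)
  paste(chars, collapse = "")
}

# Codon string for the non-gap residues of an aligned protein row, plus stop.
backtranslateRow <- function(row) {
  res <- strsplit(gsub("-", "", row), "")[[1]]
  paste(c(aaToCodon[res], "TAA"), collapse = "")
}

#' Simulate gene families with fragment and paralog structure
#'
#' Generates the inputs of the supermatrix pipeline with ground truth. Each
#' family has a master protein; each present species carries a mutated copy,
#' which with probability `fragment_prob` is split into two non-overlapping
#' aligned fragments separated by at least `fragment_gap_columns` all-gap
#' columns (emulating a fragmented transcriptome assembly), and with
#' probability `paralog_prob` is instead represented by two partial paralogous
#' copies whose aligned overlap fraction (relative to the shorter copy) is at
#' least `paralog_overlap_frac` — strictly above the 10% merge threshold, so
#' the resolution truth is unambiguous.
#'
#' @param n_species,n_families Roster and family counts.
#' @param protein_length Length range (amino acids) of family master proteins.
#' @param presence_prob Probability a species is present in a family.
#' @param fragment_prob,paralog_prob Per species-in-family probabilities of the
#'   fragment and paralog cases (mutually exclusive; fragment tried first).
#' @param fragment_gap_columns Minimum all-gap columns separating fragments.
#' @param paralog_overlap_frac Designed aligned-overlap fraction of paralog
#'   pairs; must exceed 0.10.
#' @param mut_prob Per-residue substitution probability from the master.
#' @param seed Integer seed.
#' @return List with `orthogroups` (list of [Orthogroup-class] with alignments
#'   attached), `cds` (a [Biostrings::DNAStringSet] of per-sequence coding
#'   sequences), and `truth` (`data.frame`: `og_id`, `species`, `status` in
#'   `single`/`fragments`/`paralogs`).
#' @export
simulateGeneFamilies <- function(n_species = 8, n_families = 25,
                                 protein_length = c(120, 300),
                                 presence_prob = 0.9,
                                 fragment_prob = 0.15, paralog_prob = 0.10,
                                 fragment_gap_columns = 5,
                                 paralog_overlap_frac = 0.5,
                                 mut_prob = 0.05,
                                 seed = NULL) {
  stopifnot(paralog_overlap_frac > 0.10, paralog_overlap_frac <= 1,
            fragment_gap_columns >= 1)
  if (!is.null(seed)) set.seed(seed)
  species <- sprintf("sp%02d", seq_len(n_species))
  ogs <- vector("list", n_families)
  cds <- character(0)
  truth <- list()
  for (f in seq_len(n_families)) {
    og_id <- sprintf("OG%04d", f)
    L <- sample(seq(protein_length[1], protein_length[2]), 1)
    master <- randomProtein(L)
    rows <- character(0)
    memb <- stats::setNames(vector("list", n_species), species)
    for (sp in species) {
      if (runif(1) > presence_prob) next
      copy <- mutateProtein(master, mut_prob)
      u <- runif(1)
      if (u < fragment_prob && L >= 4 * fragment_gap_columns) {
        # split into two disjoint fragments separated by >= gap all-gap cols
        gap <- fragment_gap_columns
        s <- sample(seq(floor(L * 0.25), floor(L * 0.75) - gap), 1)
        fragA <- paste0(substr(copy, 1, s), strrep("-", L - s))
        fragB <- paste0(strrep("-", s + gap), substr(copy, s + gap + 1, L))
        ids <- paste0(sp, "_", og_id, c("_f1", "_f2"))
        rows[ids] <- c(fragA, fragB)
        memb[[sp]] <- ids
        status <- "fragments"
      } else if (u < fragment_prob + paralog_prob) {
        # two partial copies overlapping by >= paralog_overlap_frac of shorter
        m <- ceiling(L / (2 - paralog_overlap_frac))
        copy2 <- mutateProtein(master, mut_prob * 3)
        pA <- paste0(substr(copy, 1, m), strrep("-", L - m))
        pB <- paste0(strrep("-", L - m), substr(copy2, L - m + 1, L))
        ids <- paste0(sp, "_", og_id, c("_p1", "_p2"))
        rows[ids] <- c(pA, pB)
        memb[[sp]] <- ids
        status <- "paralogs"
      } else {
        id <- paste0(sp, "_", og_id)
        rows[id] <- copy
        memb[[sp]] <- id
        status <- "single"
      }
      truth[[length(truth) + 1L]] <- data.frame(
        og_id = og_id, species = sp, status = status, stringsAsFactors = FALSE)
    }
    aln <- Biostrings::AAStringSet(rows)
    cds <- c(cds, vapply(rows, backtranslateRow, ""))
    ogs[[f]] <- Orthogroup(og_id, memb, alignment = aln)
  }
  list(orthogroups = ogs,
       cds = Biostrings::DNAStringSet(cds),
       truth = do.call(rbind, truth))
}

#' Simulate per-copy read counts at target RPKM levels
#'
#' Expected count inverts the RPKM formula:
#' `E(count) = rpkm_target * (length_bp / 1000) * (total_reads / 1e6)`;
#' observed counts are Poisson draws around that expectation.
#'
#' @param copies `data.frame` with columns `name`, `length_bp`, `rpkm_target`.
#' @param total_reads Total sequenced reads for the library.
#' @param seed Integer seed.
#' @return `copies` with columns `expected_count` and `count` appended.
#' @export
simulateExpressionCounts <- function(copies, total_reads, seed = NULL) {
  stopifnot(all(copies$length_bp > 0), all(copies$rpkm_target >= 0),
            total_reads > 0)
  if (!is.null(seed)) set.seed(seed)
  copies$expected_count <- copies$rpkm_target * (copies$length_bp / 1000) *
    (total_reads / 1e6)
  copies$count <- rpois(nrow(copies), copies$expected_count)
  copies$total_reads <- total_reads
  copies
}

#' Simulate a protein alignment with planted convergent residues
#'
#' Builds a reference sequence with known residue numbering (optionally behind
#' leading gap columns, to exercise coordinate mapping) and clade member
#' sequences that carry designed residues at the catalogued sites plus
#' background substitutions elsewhere. Sites not named in the design stay at
#' the catalog's ancestral (C3 reference) residue.
#'
#' @param catalog A site catalog as returned by [pepcSiteCatalog()] (columns
#'   `position`, `c4_grass_residues`, `c3_reference_residue`, ...).
#' @param clades Named list, clade -> character vector of member sequence ids.
#' @param design Named list, clade -> named character vector mapping site
#'   position (as character) to a 3-letter residue code. Naming a site absent
#'   from the catalog is an error.
#' @param ref_id Identifier of the reference row.
#' @param ref_length Reference length in residues; must cover all positions.
#' @param n_leading_gaps All-gap-in-reference columns planted before residue 1
#'   (clade members carry residues there).
#' @param noise_prob Background substitution probability at non-catalog sites.
#' @param seed Integer seed.
#' @return List with `alignment` ([Biostrings::AAStringSet], reference first),
#'   `ref_id`, `clades`, and `design` echoed as truth.
#' @export
simulateConvergenceAlignment <- function(catalog, clades, design = list(),
                                         ref_id = "reference",
                                         ref_length = max(catalog$position) + 20,
                                         n_leading_gaps = 0,
                                         noise_prob = 0.02,
                                         seed = NULL) {
  stopifnot(ref_length >= max(catalog$position))
  bad <- setdiff(unlist(lapply(design, names)), as.character(catalog$position))
  if (length(bad)) {
    stop("design names site(s) not in catalog: ", paste(bad, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  aa1 <- threeToOne(catalog$c3_reference_residue)
  ref <- strsplit(randomProtein(ref_length), "")[[1]]
  ref[catalog$position] <- aa1
  catalog_cols <- n_leading_gaps + catalog$position
  rows <- stats::setNames(
    paste0(strrep("-", n_leading_gaps), paste(ref, collapse = "")), ref_id)
  for (clade in names(clades)) {
    site_res <- design[[clade]]
    for (member in clades[[clade]]) {
      chars <- c(strsplit(randomProtein(n_leading_gaps), "")[[1]], ref)
      noise <- runif(length(chars)) < noise_prob
      noise[catalog_cols] <- FALSE
      chars[noise] <- sample(names(aaToCodon), sum(noise), replace = TRUE)
      if (length(site_res)) {
        chars[n_leading_gaps + as.integer(names(site_res))] <-
          threeToOne(site_res)
      }
      rows[member] <- paste(chars, collapse = "")
    }
  }
  list(alignment = Biostrings::AAStringSet(rows), ref_id = ref_id,
       clades = clades, design = design)
}
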