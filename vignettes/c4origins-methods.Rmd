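---
title: "Methods: desk-scale evidence for independent C4 origins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale evidence for independent C4 origins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c4origins)
```

# Scope and model

`c4origins` implements the computational chain used to argue that two closely
related plant clades acquired C4 photosynthesis independently and with
different biochemical subtypes. The chain has six stages, each exposed as a
module of exported functions: carbon-isotope pathway classification; A/Ci
gas-exchange and enzyme phenotyping with a subtype decision rule; low-copy
ortholog supermatrix construction; parsimony counting of origin scenarios;
expression-based assignment of the C4-functional gene copy; and scoring of
convergent amino acid substitutions at positively selected PEP carboxylase
sites. A synthetic-data module generates inputs with known ground truth for
every stage, so the whole pipeline is testable without any sequencing data.

# Isotope classification

C4 tissue is isotopically heavier than C3 tissue because PEP carboxylase
discriminates less against 13C than Rubisco. The survey windows usually
quoted — C4 between -10 and -16 permil, C3 between -23 and -32, C4-like
between -16 and -22 — leave gaps and are crossed by real observations (C4
species means reach -9.4; a -22.6 observation is treated as an arid-zone C3).
The default rule therefore partitions the whole line with half-open
boundaries: `value >= -16` is C4, `[-22, -16)` is C4-like, `< -22` is C3,
with no upper C4 bound below -8. Two flags qualify the call rather than
change it: `borderline_c3` on C3 calls above -24 (arid-zone C3 species with
high water-use efficiency reach such values) and `out_of_range` outside
`[-35, -8]`. All thresholds are overridable through `isotopeThresholds()`.

A genus is summarized as C4 when every sampled species mean classifies C4;
in the packaged survey ranges this yields exactly three C4 genera (Allionia,
Boerhavia, Okenia). Per-genus summaries report sampled species counts only;
accepted-species totals involve synonymy judgments that are not computable
from the data.

# Gas exchange

The A/Ci response is summarized by point statistics rather than a mechanistic
model fit (no FvCB or enzyme-limited C4 model; no mesophyll conductance):

* **Initial slope** (carboxylation efficiency, mol m^-2^ s^-1^): OLS of A on
  Ci over steps with Ci below 100 umol mol^-1^. At least two qualifying
  steps are required.
* **CO2 compensation point** (Gamma, umol mol^-1^): the x-intercept
  `-intercept/slope` of that regression, floored at zero. The estimation
  method is a design choice here — the measurement protocol steps down to
  near the compensation point, making the low-Ci limb locally linear — and a
  bracketing-interpolation alternative could be swapped in without touching
  the rest of the pipeline.
* **A400, A1200, and their ratio**: read at the ambient-CO2 400 and 1200
  steps (nearest step within 25 umol mol^-1^). Ratios are computed per
  replicate and averaged, not computed from averaged numerators and
  denominators, which is why a table can print a mean ratio of 0.74 alongside
  means whose quotient is 0.73.
* **Normalized carboxylation efficiency**: initial slope / A1200, correcting
  for photosynthetic capacity; `norm_ce * a1200 = initial_slope` holds
  exactly by construction.
* **Intrinsic WUE**: A/gs at the 400 step, reported in the conventional
  mmol mol^-1^ scale.

The one-tailed C3-vs-C4 comparison uses Welch's t (unequal variances),
one-tailed in the direction of the observed difference so that the result
does not depend on argument order. The test identity is a documented,
swappable choice; Welch is the conservative default when replication is 3-4
leaves per species.

# Enzyme and pigment arithmetic

Only the downstream arithmetic of the assays is in scope. Chlorophyll uses
the standard 80%-acetone two-wavelength equations
(`chl_a = 12.7 A663 - 2.69 A645`, `chl_b = 22.9 A645 - 4.68 A663`, mg/L),
converted to mmol m^-2^ with molar masses 893.5 and 907.5 g/mol. Activities
convert an A340 slope through the NAD(P)H millimolar extinction coefficient
6.22 mM^-1^ cm^-1^, the assay volume, the extract/aliquot ratio and the leaf
area. A negative computed chlorophyll concentration aborts with a hint that
the wavelengths are swapped — the commonest unit error in practice.

The subtype decision takes the decarboxylase with the larger area-basis
activity, and grades confidence against the leaf's own assimilation rate: a
call is *robust* when the activity is at least A400 (the enzyme can carry the
observed flux), flagged when between 0.5 and 1 times A400, and `"none"`
(C3-consistent) when both decarboxylases fall below 0.2 A400. There is no PCK
branch: PEP carboxykinase is not assayed by this panel, and transcript
evidence alone is deliberately insufficient — the packaged expression table
itself shows why, with one C4 accession expressing NADP-ME transcripts at
87% of its NAD-ME level while its leaf assays show no NADP-ME activity at
all. Transcript-based subtype typing without enzyme assays would mistype
that species; the `co_expression` flag (runner-up at >= 0.5 of the top copy)
marks exactly this situation.

Ultrastructure summaries reduce per-cell planar measurements to per-plant
means, then per-species means, with significance letters from one-way ANOVA
plus Tukey's HSD at alpha = 0.05 on the per-plant means (the letter method is
a documented choice; the per-plant-first averaging prevents
pseudoreplication across cells). Letters are withheld when any species has a
single plant.

# Supermatrix construction

The pipeline consumes an orthology table (the standard tab-separated
orthogroups dialect), protein alignments and per-sequence CDS, and emits a
partitioned codon supermatrix. The stages, in order:

1. **Longest ORF** (`longestOrf()`): all six frames are scanned; an ORF runs
   from the first in-frame start codon after a stop (or the frame edge) to
   the next stop, the longest protein wins, ties break by frame then 5'-most
   start. Whether the original selection required ATG starts is not
   recoverable, so both modes exist (`require_start = FALSE` gives
   stop-to-stop stretches); ATG-required is the default as the common
   meaning of "ORF".
2. **Fragment/paralog resolution** (`resolveMulticopy()`): multiple
   sequences of one species merge when no pair overlaps by more than 10% of
   the shorter sequence, and the species is dropped otherwise. Overlap is
   computed on aligned coordinates (shared non-gap columns over the shorter
   non-gap length), since overlap between unaligned fragments is not
   well-defined; this is flagged for users because the original tooling may
   have used unaligned lengths. Merging takes the unique non-gap residue per
   column; on the rare doubly-covered column the earlier-starting fragment
   wins (a tie-break that the 10% cap keeps nearly irrelevant).
3. **Low-copy filtering** (`filterOrthogroups()`): resolution first, then —
   in order — species presence (default 40/53, stored as a fraction so other
   rosters scale), multicopy fraction (<= 10% of species with multiple
   sequences before resolution), and alignment length (>= 100 aa). Resolving
   before counting presence is deliberate: merged fragments count as
   present, which is the point of rescuing fragmented assemblies.
4. **Codon back-translation** (`backtranslate()`): each residue column
   becomes its codon, gaps become `---`, trailing stops are stripped, and
   any translation mismatch is a hard error naming sequence and position.
5. **Gap trimming** (`trimCodonColumns()`): the 0.5 gap threshold is applied
   to whole codons, not nucleotide columns — per-nucleotide trimming at a
   column threshold can break the reading frame, so codons are evaluated and
   removed as units with the same threshold semantics. Keeping is
   boundary-inclusive (a column exactly at the threshold survives) and the
   operation is idempotent.
6. **Concatenation** (`concatenateAlignments()`): orthogroups ordered by id,
   absent species padded with gaps, one partition per gene; written as
   FASTA, relaxed PHYLIP (names to 250 characters — the strict 10-character
   dialect is not supported) and a `DATATYPE, name = start-end` partition
   file. Partition coordinates are 1-based inclusive at the file boundary
   only; internal column arithmetic is 0-based half-open.

Orthology inference, alignment inference and tree search are out of scope;
the package consumes and emits their formats.

# Parsimony origin counting

`fitchMinChanges()` computes the minimum number of C3/C4 changes on a fixed
topology (generalized Fitch via unit-cost Sankoff, so polytomies need no
arbitrary resolution), plus one optimal internal labeling decomposed into
gains and losses. The change count is rooting-invariant; the gain/loss
decomposition is not, so it is reported on the rooted tree and the witness
root prefers C3 on ties (flagged). One witness is reported rather than all
optimal labelings; the count is the authoritative statistic and alternative
equally-costly placements of the changes are not asserted to be unique.

`constrainedMinChanges()` answers the scenario question directly: the
minimum total changes among labelings with exactly `n_gains` C3-to-C4 edges,
by dynamic programming over (node, state, gains used). The root is
constrained to C3 by default — the biological question is "how many changes
if C4 arose once from C3 ancestors?", and a free root would let a zero-gain
labeling paint the whole tree C4. On the packaged eight-genus topology with
the survey's tip states, the free minimum is 2 (two independent gains) while
forcing a single gain costs 3 (one gain plus two reversions) — the
less-parsimonious single-origin scenario. `sankoffMinCost()` generalizes to
asymmetric gain/loss costs; with losses priced above gains the optimum moves
further toward independent origins, consistent with reversions being
considered unlikely.

# Expression and convergence

RPKM is `count / ((len/1000) * (total/1e6))`; the library-size denominator is
total sequenced reads (not total mapped reads), the appropriate choice when
reads were mapped only to selected gene references. The functional C4 copy
of each gene family is the copy with the highest RPKM; `dominance_ratio` and
the `co_expression` flag (threshold 0.5, chosen so an 0.87 runner-up flags
and a 2/8563 runner-up does not) qualify the assignment. The packaged
expression table is transcribed as printed; published prose refers to the
dominant Boerhavia decarboxylase copy inconsistently (NADP-ME1 vs NADP-ME2),
and the table, which is unambiguous, is treated as authoritative.

Convergence scoring anchors all site numbers to the maize PEPC coordinate
system through `mapReferencePositions()` (1-based over the reference's
non-gap columns). A catalogued site is *convergent* for a C4 clade when the
clade consensus is one of the residues positively selected in C4 grasses and
differs from the C3 sister consensus; *ancestral_shared* (not counted) when
the C3 sister already carries the grass residue — such a site cannot
evidence a C4-associated switch; *partial* when the clade is polymorphic and
only some members match (reported separately, excluded from the strict count
by default and includable via `count_partial`). The packaged catalog contains
the 19 printed positions; published fraction-of-21 phrasings ("about a
third", "a fifth") use the grass study's 21-site count as denominator, so
the report exposes exact counts and lets the caller choose the denominator.
On the packaged data the strict counts are 5 (Boerhavia/Okenia, plus one
partial) and 4 (Allionia), preserving the published ordering.

# Synthetic data: what it emulates and what it does not

Every generator is a pure function of its configuration and seed.

* **Isotope surveys**: truncated-normal draws per pathway. Defaults C3
  mean -27.0 sd 1.5, C4 mean -12.5 sd 1.2 sit at the centres of the observed
  per-genus ranges (C3 species means -29.8 to -22.6, C4 -14.9 to -9.4);
  truncation to [-32, -9] reflects the survey windows. The modes are ~14.5
  permil apart (> 4 sd), so 100% classification accuracy on synthetic
  surveys demonstrates pipeline correctness, not real-world separability of
  borderline arid-zone values.
* **A/Ci curves**: a non-rectangular hyperbola between the CO2-limited line
  `slope * (ci - gamma)` and the ceiling `a_max`, curvature `theta`
  (default 1, the two-limb limit, which makes noiseless slope/Gamma recovery
  exact and is the right regime for testing the estimators). `ci = ci_ca *
  ca` with defaults 0.33 (C4) per the observed 0.31-0.35, 0.60 for C3; the
  default 14 ambient steps mirror the measurement protocol (400,
  saturating 1200, then stepping down toward compensation). Stomatal
  conductance is back-derived from A via the 1.6 diffusivity ratio with a
  floor — a bookkeeping convenience, not a stomatal model.
* **Gene families**: a master protein per family, mutated per species;
  fragment cases split a copy into two disjoint aligned pieces separated by
  at least 5 all-gap columns; paralog cases plant two partial copies whose
  overlap fraction is at least the configured value (constructed as
  `m = ceil(L / (2 - f))`-long windows from opposite ends, so the overlap is
  unambiguous and strictly above the 10% merge threshold). No substitution
  model, indel process or assembly-error model is simulated — the generator
  exercises the resolution and filtering logic, not alignment inference.
* **Expression counts**: Poisson around the RPKM-inverted expectation.
  Poisson, not negative binomial, because only the RPKM arithmetic is
  consumed downstream; no dispersion is inferred anywhere.
* **Convergence alignments**: a reference with known numbering (optionally
  behind planted leading gap columns to exercise the coordinate map), clade
  members carrying designed residues at catalog sites and uniform background
  noise elsewhere.

Passing tests on these generators shows the pipeline computes its
definitions correctly under the stated statistical structure; it does not
validate transcriptome assembly, orthology inference or alignment quality on
real data, all of which are upstream of this package's scope.

# Numerical choices and degenerate inputs

* Isotope classification is half-open and total: every finite value gets
  exactly one label; non-finite values are errors, not NA propagation.
* `fitInitialSlope()` refuses fewer than two low-Ci points;
  `estimateGamma()` refuses non-positive slopes and floors negative
  intercept ratios at zero with a flag.
* Welch comparison of two zero-variance groups returns 0.5 on equal means
  (the symmetric null) instead of erroring.
* Fitch traceback prefers C3 on ties and flags the tie; the constrained DP
  reports explicit infeasibility rather than an infinite cost.
* FASTA reading uppercases residues and normalizes `?` and `.` to `-`;
  duplicate identifiers and empty files are errors naming the culprit.
* Trim keeps threshold-boundary columns (`>=`), so `gap_threshold = 0`
  removes nothing and `1` keeps only complete columns.

# Problem sizes

The test and acceptance workloads are sized for a desk run: 500 synthetic
gene families for resolution-truth recovery, 200 replicate noisy curves for
slope-bias estimation, 200 random trees (up to 12 leaves) against the
exhaustive parsimony oracle, and 1000 random sequences against the
exhaustive six-frame ORF scan. These sizes give stable statistics (binomial
and Monte Carlo errors well inside the asserted tolerances) while keeping
the full suite under a minute.

# Known limitations

* No mechanistic photosynthesis model; point metrics only.
* No isotope mixing models or post-photosynthetic fractionation corrections.
* The supermatrix stage trusts its input alignments; it does not re-align.
* Parsimony is unweighted/weighted counting only — no likelihood ancestral
  reconstruction, no divergence dating.
* The convergence score treats clade consensus as the unit of evidence;
  within-clade polymorphism is surfaced but not modeled.
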