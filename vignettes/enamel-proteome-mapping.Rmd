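---
title: "Methods: spatial proteome maps of forming tooth enamel"
author: "enamelmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial proteome maps of forming tooth enamel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enamelmap)
```

# The problem

Tooth enamel forms inside a transient protein matrix whose composition,
abundance, and phosphorylation state change over space and time as the
tissue mineralizes.  A diced-crown experiment cuts a developing molar crown
into a grid of small blocks (plus dentin and bone reference samples), runs
label-free LC-MS/MS on each block, and asks three questions:

1. How abundant is each protein at each grid location (a spatial abundance
   map)?
2. What fraction of a marker peptide is phosphorylated at each location
   (a phospho-occupancy map, written P:P+NP)?
3. Which proteins differ in abundance across developmental-stage groups of
   locations, and in which direction?

`enamelmap` implements this analysis as a reusable, seeded pipeline.  The
raw mass-spectrometry stage (peak picking, database search, PSM-level FDR)
is upstream commercial software and out of scope: the pipeline starts from
a peptide-level quantification report (peptide sequence, modifications,
protein accession, sample location, chromatographic peak area,
identification significance on the -10lgP scale, and a uniqueness flag).

# The quantification model

**Identification filters.**  A protein is considered identified when it has
at least two distinct unique peptide sequences dataset-wide and an
identification significance of at least 20 (-10lgP).  Uniqueness here means
the peptide is flagged unique upstream *and* maps to exactly one accession
within the dataset; razor-peptide assignment is not attempted.  The
significance threshold is applied per protein, since the report carries a
protein-level score (the per-PSM alternative cannot be evaluated without
spectra).

**Top-3 abundance.**  Protein abundance at a location is the summed peak
area of the protein's three most abundant unique peptides *at that
location*:

$$A_{p,\ell} \;=\; \sum_{i \in \mathrm{top3}_\ell(p)} \mathrm{area}_{i,\ell}.$$

With fewer than three unique peptides observed, the available ones are
summed; with none, the cell is missing.  Two deliberate conventions, both
regression-tested: records of one sequence (e.g. modified and unmodified
forms) are pooled before ranking, and rank-3 ties are broken by
lexicographic sequence so the sum has a deterministic set of summands.
Whether the study ranked peptides per location or globally is not stated in
its methods; per-location ranking was chosen because it uses all the local
evidence, and it is documented prominently here.

**Volume normalization.**  Block volumes vary (thinning cervical enamel,
crown curvature), so each location is rescaled against the reference
standard sample volume of 2.14 mm^3:

$$A'_{p,\ell} = A_{p,\ell} \cdot \frac{2.14}{V_\ell}.$$

The direction of normalization (multiplying by reference/volume) makes
equal tissue *concentrations* give equal normalized values; the source
methods state the normalization but not the formula, so the concentration-
preserving direction was chosen and is asserted by test.

**Scales.**  Maps are reported on four tagged scales: `raw_area`,
`volume_normalized`, `natural_log` (zeros become audited missing values),
and `percent` (each row scaled to its maximum = 100).  The canonical order
is fixed: top-3 &rarr; volume normalization &rarr; natural log &rarr;
percent.  Percent scaling "within the tooth crown" is ambiguous when two
teeth are analyzed at once: `percent_scale()` therefore supports both
crown-wide and per-tooth scaling.  The pipeline writes the per-tooth map
for visualization, and uses the crown-wide map for clustering and testing
so that all 21 locations live on one comparable scale.

# Phospho-occupancy maps

Four bundled marker peptides discriminate amelogenin P173/LRAP (Ser16),
the exon-4-containing P190 splice variant, the ameloblastin N-terminal
cleavage products, and the enamelin 32 kDa fragment.  At each location the
phosphorylated pool P sums matching records carrying a Phospho at the
marker position, the unphosphorylated pool NP sums matching records with no
Phospho anywhere; other modifications are ignored for matching, and a
Phospho at a different residue is audited and counted in neither pool.
Occupancy is

$$\mathrm{ratio}_\ell = \frac{P_\ell}{P_\ell + NP_\ell},$$

undefined (missing) where the marker was not observed.  The ratio is
scale-free, so volume normalization cancels; this is asserted by a test
rather than assumed.  An optional flag divides each location's ratio by the
crown-wide pooled ratio; it is off by default because the per-location
ratio is the directly interpretable quantity.  Charge states and
missed-cleavage variants are aggregated by sequence identity, and pools sum
areas rather than taking a best single form (the study's methods do not say
which; summation uses all evidence).

Marker definitions are validated, not trusted: `validate_markers()` checks
each sequence is a substring of its parent and is producible by tryptic
digestion with at most two missed cleavages and cleavage before proline
permitted — the same digestion rules as the upstream search.
`tryptic_digest()` is exhaustively checked against a brute-force
substring-and-predicate enumerator in the tests.  The packaged parent
sequences are *synthetic surrogates* (real marker peptides embedded in an
artificial backbone with correct cleavage context), bundled only so the
validation machinery is testable offline; real analyses should supply a
real proteome FASTA.

# Stage groups and differential abundance

**Group definition.**  Locations are clustered on the crown-wide percent
matrix by Euclidean distance; missing cells are imputed as 0 on that scale
(absence = not detected, which is exactly what a 0% cell asserts; row
deletion is available behind a flag).  The metric is stated by the source
analysis; the linkage is not, so average linkage is the default with
single/complete/Ward available.  Cutting the dendrogram at *k* = 5 mirrors
the five observed groupings; each cluster is then *named* by the majority
a-priori stage label of its members (Secretion, Maturation, Cuspal, DEJ,
NonEnamel), with ties resolved toward the earlier developmental stage.
PCA of the same matrix (column-centered, locations as observations, sign
fixed so the largest-magnitude loading is positive) provides the companion
ordination.

**Permutation ANOVA.**  For each protein, the one-way F statistic across
the four enamel location groups (NonEnamel is excluded from testing) is
compared against the null distribution obtained by uniformly permuting
group labels.  When the number of distinct label arrangements is at most
the permutation budget the null is enumerated exhaustively and
$p = \#\{F_{perm} \ge F_{obs}\}/N$; otherwise B Monte-Carlo draws give the
add-one estimate $p = (1 + \#\{F_{perm} \ge F_{obs}\})/(1 + B)$, which is
exactly valid and never zero.  The default budget B = 4999 resolves
p-values to 2e-4, the granularity of the smallest p-values the original
analysis reports; it is configurable.  Zero within-group variance with
non-zero between-group variance yields F = +Inf, which compares cleanly
inside the permutation scheme; all-equal values yield p = 1.

**FDR and direction.**  P-values are adjusted by the Benjamini-Hochberg
step-up procedure (via `stats::p.adjust`; the test suite checks it against
a brute-force implementation of the definition).  Each significant protein
gets a per-group direction: its group mean against the unweighted mean of
the other groups' means, with exact ties called neutral.

**Enrichment.**  Per named group, proteins observed in the group are
pre-filtered by dropping the lowest 10th percentile of group-mean
abundance, then tested for annotation-term over-representation with a
one-sided hypergeometric test against a user-supplied annotation table and
background, BH-adjusted, skipping terms with fewer than two hits.  This
replaces an online annotation service with a self-contained equivalent; it
makes no attempt to reproduce any service's curated annotation databases or
EASE-style score variant.

A note on the percentile pre-filter: with the plain nearest-rank percentile
(rank $\lceil pn/100 \rceil$) and strict-below removal, 10 distinct values
lose *zero* proteins, which contradicts the intent of dropping the bottom
10%.  The implemented rule removes values strictly below the
$(k{+}1)$-th order statistic, $k = \lceil pn/100 \rceil$: exactly the
bottom k are dropped when values are distinct, and nothing is dropped when
all values are equal.

# The synthetic diced-crown generator

The generator is first-class, tested code: it defines the study conditions
every downstream stage is validated against.

* **Grid.**  21 locations: two teeth of ten blocks each (columns surface
  &rarr; DEJ, rows cuspal &rarr; cervical) plus one bone sample — a forming
  molar carrying secretory and early-maturation enamel and an erupting
  molar carrying erupted and late-maturation enamel, with DEJ and dentin
  blocks on the inner column.  Block volumes are drawn around 2.3 mm^3
  (SD 0.25), the reported mean block volume.
* **Proteins.**  The default fixture has 100 proteins with 3-8 peptides
  each (about 550 distinct peptides, matching the scale of the real
  dataset).  Each protein belongs to one of six archetypes
  (secretory-matrix, maturation, erupted-surface, DEJ-interface,
  mineralized-tissue, ubiquitous) assigned by a deterministic interleaved
  quota (25/20/15/15/15/10%), so every prefix of proteins is class-balanced
  and adding proteins never reassigns existing ones.  A protein's mean log
  peak area is its baseline (Normal, mean 14, SD 1 on the natural-log area
  scale) plus 4 natural-log units (~55-fold) in its archetype's defining
  stages — the order of magnitude by which stage-restricted enamel matrix
  proteins differ between stages.  Random archetype assignment was
  deliberately avoided: with ~15 proteins per class, binomial fluctuation
  can under-represent a tissue class and erase the planted group structure
  the recovery tests are about.
* **Peptides.**  Peak area = exp(stage mean + peptide response offset +
  noise).  The response offset (SD 0.8) captures ionization-efficiency
  differences between peptides of one protein; the measurement noise is
  multiplicative log-normal (SD 0.3, a ~30% CV typical of label-free
  areas).  Observations strictly below the detection threshold
  (2e5 area units) are censored — left-censoring, not
  missing-at-random, which is what "no peptide data" means in a
  detection-limited map.
* **Phospho markers.**  Each marker is emitted as a P/NP record pair whose
  expected split equals the configured per-location true occupancy; the
  default profiles make the amelogenin markers highly phosphorylated in
  secretory enamel and less so later, the ameloblastin marker the
  opposite, the enamelin marker near-fully phosphorylated everywhere.
  Marker parents also get two unmodified support peptides so they pass the
  two-unique-peptide identification filter.
* **Seeding.**  One shared seed; every protein, marker, and the volume
  vector draws from its own deterministically derived sub-stream, so
  identical configurations are byte-identical and growing the fixture
  never reshuffles existing entities.

**What the generator does not emulate** — and therefore what passing tests
do *not* show about real data: chromatography and spectral artifacts,
identification error (every simulated record is a correct identification),
ionization competition and ratio compression, peptide-level correlation
beyond the shared protein profile, razor/shared peptides (every simulated
background peptide is unique by construction), and the real covariance of
biological stage profiles.  Recovery results on the fixture demonstrate
the pipeline's correctness under its own assumptions, not the
identifiability of the real study's biology.

# Numerical choices and degenerate inputs

* Permutation p-values use the add-one convention (never zero, valid at
  any B); exhaustive enumeration switches on automatically when cheaper.
* F-statistic degeneracies (zero between-group, zero within-group) are
  resolved to 0 and +Inf respectively with a relative tolerance of 1e-12
  on the sums of squares.
* Percent scaling drops rows with no positive value, with an audit entry;
  the log transform audits zero cells it sets to missing.
* Top-3 rank ties: lexicographic by sequence, asserted deterministic.
* Cluster naming ties: earlier developmental stage wins.
* All TSV artifacts serialize doubles at 17 significant digits so files
  round-trip losslessly and repeat runs are byte-identical.

# Problem sizes used by the checks

The statistical acceptance checks run at sizes chosen to give the
properties under test real power while staying quick: null calibration
uses 1000 null proteins at the 21-location, 4-group design with B = 199
(where the rejection probability at the 0.05 level is exactly 0.05 by the
add-one arithmetic); the mixed false-discovery simulation plants 10% true
effects of twice the noise SD for 200 proteins on a 4x8-location design
with B = 999 — at the 21-location design the permutation p-value floor
1/(B+1) starves the step-up procedure of rejections, making the realized
FDP vacuous, whereas FDR control itself does not depend on the design
size; occupancy recovery runs at noise SD 0.05; clustering and direction
recovery run the full default fixture across 20 seeds.

# Known limitations

* Protein significance is thresholded as provided upstream; the package
  never computes -10lgP (no spectra in scope).
* Cross-tooth percent maps depend on the chosen scaling unit; both
  variants are written, but downstream statistics use the crown-wide one.
* The direction call compares unweighted group means; a heavily unbalanced
  clustering can make "the mean of the other groups" a blunt reference.
* The over-representation test assumes an unstructured background;
  annotation correlation (e.g. nested GO terms) is not modeled.
* Zero-imputation on the percent scale treats not-detected as absent;
  for proteins near the detection limit this understates abundance and the
  row-deletion alternative may be preferable.

# Reproducing a full run

```{r, eval = FALSE}
cfg <- pipeline_config("run1", seed = 1)
run_pipeline("all", cfg)
```

writes the complete artifact set (grid, peptide report, truth tables,
abundance maps on all scales, occupancy maps, PCA scores, cluster
assignment, differential-abundance table, enrichment table) into `run1/`,
every file carrying the tool version and seed; a second run from the same
configuration is byte-identical.
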