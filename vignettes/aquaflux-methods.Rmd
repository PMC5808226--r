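---
title: "Models and methods behind aquaflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aquaflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquaflux)
```

aquaflux implements the quantitative core of a classical aquaporin
functional-characterization study: the Xenopus oocyte swelling assay with
its permeability estimators, silhouette image analysis, sequence-hallmark
annotation of a candidate water channel, and 2^-ddCt relative expression.
This vignette records the models, the assumptions behind them, and the
design choices that were genuinely open.

## The swelling assay model

A defolliculated oocyte expressing a water channel is dropped into a
hypotonic bath (here, a 3-fold dilution of Ringer's solution: internal
osmolality 202 mmol/kg against 59 mmol/kg outside). Water flows in along
the osmotic gradient and the cell swells. The osmotic water permeability
coefficient is defined from the *initial* rate of relative volume change:

$$P_f = \frac{V_0 \, \mathrm{d}(V/V_0)/\mathrm{d}t}
            {S \, V_w \, (\mathrm{Osm_{in}} - \mathrm{Osm_{out}})}$$

with $V_0 = 9\times10^{-4}$ cm³, $S = 0.045$ cm², $V_w = 18$ cm³/mol.
These constants live in `assay_constants()`. Osmolalities in mmol/kg are
bridged to mol/cm³ assuming 1 kg of water occupies 1000 cm³
(1 mmol/kg = 10⁻⁶ mol/cm³); this is the only convention under which the
printed formula is dimensionally consistent, and it is applied uniformly.

The forward model integrated by `simulate_swelling()` is

$$\frac{\mathrm{d}V}{\mathrm{d}t} = P_f \, S \, V_w \,
  \big(c_\mathrm{in}(t) - c_\mathrm{out}\big), \qquad
  c_\mathrm{in}(t) = c_\mathrm{in}(0)\,\frac{V_0}{V(t)},$$

i.e. the internal solute is conserved and dilutes as the cell swells,
while the surface area is held constant at $S$ (the assay uses a single
surface-area constant, so recomputing area from volume would be
inconsistent with the estimator). Two consequences are used as physics
checks: the volume is strictly increasing while a gradient persists, and
the equilibrium relative volume is
$\mathrm{Osm_{in}}/\mathrm{Osm_{out}} = 202/59 \approx 3.42$.

Integration is fixed-step 4th-order Runge-Kutta (via deSolve) with an
internal step of at most 1 s, resampled to the 15 s acquisition grid; the
system is smooth and non-stiff at these parameters, and the solution
matches an adaptive reference solver to better than 10⁻⁷ in relative
volume. A non-monotone noiseless solution aborts the simulation, which
would indicate a step too coarse for the requested parameters.

The measurement is the projected silhouette area. Assuming a spherical
cell, $V/V_0 = (A/A_0)^{3/2}$ (`relative_volume()`). Noise is
multiplicative Gaussian on area with the $t=0$ point pinned to exactly 1,
because real traces are normalized to their own first frame. All
estimators consume only the ratios $A/A_0$, so magnification never
enters.

For the isotonic solute-uptake assay (140 mM glycerol, trehalose or
urea), water follows the permeant solute and the apparent solute
permeability is defined by $P_{sol} = \mathrm{d}(V/V_0)/\mathrm{d}t \cdot
V_0/S$. The implied forward model is linear growth of $V/V_0$ at rate
$P_{sol} S/V_0$ (`simulate_solute_uptake()`). Study reports label these
solute-bath values "Pf" while computing them with the $V_0/S$ formula;
this package treats them as $P_{sol}$ throughout. The slight shrinkage
sometimes seen in solute baths is modeled only as noise around a zero
slope; no efflux mechanism is claimed anywhere in the source material.

## Slope fitting: the bias-variance choice

The permeability is defined from the initial gradient, but the swelling
curve decelerates as the gradient dissipates — the relative decay rate of
the slope is $\approx 1.41 \times \mathrm{slope}$ per second at the
default constants. An OLS fit over a window of length $T$ therefore
underestimates the initial slope by roughly $0.7 \cdot \mathrm{slope}
\cdot T$ (relative), while its standard error shrinks as $T^{-3/2}$.
Concretely, at 15 s sampling:

* for a strong expressor (slope $10^{-3}$ s⁻¹), a 30 s window is already
  2.1% biased and a 120 s window 7.5%;
* for a water-injected control (slope $\sim 10^{-4}$ s⁻¹) with 1% area
  noise, windows shorter than the full 5 min recording are dominated by
  noise.

`fit_initial_slope()` defaults to the first 60 s (five frames), a
reasonable fixed compromise, and always reports $R^2$ and the number of
points so poor linearity is visible. `estimate_permeability()` adds
`window_s = "auto"`: a two-pass rule that fits the full trace once and
then re-fits over $T = \delta_{max}/|s_1|$ — the time over which the
relative volume is expected to rise by $\delta_{max}$ (default 0.05),
clamped to $[2\,\mathrm{d}t,\ \mathrm{duration}]$. This keeps fast
swellers inside the near-linear regime and lets near-flat controls use
every frame. With the standard design (10 oocytes per group, 1% area
noise, an 11-fold true contrast) the adaptive rule recovers the group
fold essentially unbiased, where any single fixed window is either
biased (long) or extremely noisy in the denominator (short).

The recovery benchmarks in the test suite and acceptance script use a
fixed 120 s window for single-trace recovery over Pf in
$[10^{-3}, 10^{-2}]$ cm/s at 0.5% noise (median error ~8%), and
`window_s = "auto"` wherever expressing and control groups are compared.
Ordinary least squares is used throughout — no robust or weighted
variant — as the plainest reading of "d(V/V0)/dt".

Group contrasts (`compare_groups()`) use a two-sided Student's t-test
with pooled variance at $\alpha = 0.05$, matching the assay's standard
analysis; when both groups have zero variance the p-value is 1 for equal
means and 0 otherwise, by convention.

## Silhouette image analysis

No segmentation procedure is prescribed for oocyte silhouettes measured
by hand, so `extract_area()` implements the minimal robust reading:
global Otsu threshold, foreground taken as the minority intensity class
(silhouettes may be dark-on-light or the inverse), largest connected
component under 8-connectivity, interior holes filled, area = pixel
count. The result is invariant to increasing linear intensity rescaling
because Otsu's criterion is. Connected components are labelled with
EBImage and diagonally-touching labels merged by union-find, since the
library's labelling is 4-connected. The synthetic frame renderer draws a
centered disc (pixel centers within the radius) plus additive Gaussian
noise; render→extract round-trips are accurate to ~2% for radii of
20-200 px provided the silhouette stays the minority class of the frame.
Drifting oocytes, non-spherical shapes and illumination artifacts are out
of scope.

## Sequence hallmark annotation

A water-selective insect aquaporin carries a recognizable syntax:
two NPA boxes on the pore-lining hemi-helices, an aromatic/arginine
(ar/R) constriction that sets water selectivity, six membrane-spanning
hydrophobic stretches, and — in Lepidoptera — a C-terminal "SYDF"
peptide. The annotator (`annotate_aquaporin()`) assembles:

* **ORF**: longest forward-strand ATG→stop span over the three reading
  frames (ties to the smaller start), standard genetic code; appropriate
  for oriented mRNA/RACE products. Coordinates are 1-based inclusive and
  include the stop; the translation excludes it.
* **MW / pI**: average residue masses plus one water, and
  Henderson-Hasselbalch net charge over D/E/C/Y/H/K/R and both termini
  with the Bjellqvist pKa set, solved by bisection to |charge| < 10⁻⁴ —
  the ExPASy Compute pI/MW conventions. Both depend only on composition.
* **Motifs**: exact overlapping scan for NPA; terminal 4-mer.
* **Hydropathy**: Kyte-Doolittle means over a centered window (default
  19, the span of a membrane-crossing helix), defined only where the full
  window fits; hydrophobic segments are maximal runs of centers above 1.6,
  merged across gaps of at most 3 centers. This is presented as a
  hydropathy heuristic, *not* a topology predictor: it makes hydrophobic
  cores visible but is not claimed to reproduce a dedicated
  transmembrane-topology tool's 6-segment call, which is why the segment
  count is reported but never asserted.
* **ar/R mapping** (`map_selectivity_filter()`): Needleman-Wunsch global
  alignment (BLOSUM62, gap open 10, extend 0.5) of the query against a
  reference channel of known structure; each stated reference position is
  reported with the aligned query residue and position, or an explicit
  gap. Percent identity uses alignment columns as the denominator; the
  published "79% identity" figure for related sequences has no stated
  algorithm and is therefore never used as a hard expectation.
* **Degenerate in-silico PCR** (`in_silico_pcr()`): the forward primer is
  matched on the forward strand and the reverse primer as its reverse
  complement, IUPAC degeneracy honored on the primer side only (an
  ambiguous template base such as N matches nothing), perfect matches
  required — no mismatch tolerance is defensible when an exact product
  length is the observable. Products include both primer footprints.

## Relative expression (2^-ddCt)

`relative_quantity()` implements the Livak method: technical replicates
are averaged per biological replicate (cells with technical SD > 0.5
cycles are flagged — a conventional plate-QC threshold, not a literature
value), $\Delta C_t = C_t^{target} - C_t^{ref}$ per replicate,
$\Delta\Delta C_t$ centers on the **mean** $\Delta C_t$ of the calibrator
condition (stable under unbalanced replication; the per-replicate
alternative is not), and $rq = 2^{-\Delta\Delta C_t}$. Equal
amplification efficiencies are assumed, as the assay design asserts;
efficiency (Pfaffl) correction is deliberately omitted but the interface
leaves room for it. The calibrator defaults to the lowest-expressing
condition when unspecified, since published figures typically express
folds against the weakest tissue or stage. rq is invariant to adding any
constant to every Ct.

`group_stats()` reproduces the screening-then-testing pipeline common in
expression papers: Shapiro-Wilk per group and Levene across groups on
log-folds (the log transform symmetrizes fold ratios), then Student's t
for two conditions; for more, one-way ANOVA with Tukey HSD under variance
homogeneity, otherwise Dunnett's T3 — pairwise Welch statistics referred
to the studentized maximum modulus, computed here with the
identity-correlation approximation $p = 1-(2\Phi_t(t;\nu)-1)^{k}$ over
the $k$ comparisons, which is the standard conservative bound and the
only option without a dedicated T3 implementation on hand. Compact
letter displays are built by the insert-and-absorb rule over conditions
ordered by mean.

## Synthetic data: what it does and does not emulate

Every generator is seeded, regenerates byte-identically from (parameters,
seed), and returns its ground truth alongside the data, so each pipeline
stage has blind round-trip tests. Defaults mirror the characteristic
magnitudes of the assay being emulated:

* `gen_swelling_experiment()`: 10 expressing + 10 control oocytes,
  group-mean Pf 7.7×10⁻³ vs 7.0×10⁻⁴ cm/s (an 11-fold contrast), 10%
  between-oocyte lognormal variation (permeability is positive and
  right-skewed), 1% multiplicative area noise, 15 s / 5 min sampling.
* `gen_solute_experiment()`: 9 oocytes per group at the ~5×10⁻⁶ cm/s
  apparent-permeability scale of a water-selective channel in a 140 mM
  solute bath, with *no* true group difference by default.
* `gen_aqp_transcript()`: a 258-codon ORF flanked by UTRs, NPA boxes
  planted at residues 89 and 206, C-terminal SYDF, and a degenerate
  primer pair spanning a 431 bp product; a verifier re-scans the product
  to guarantee the planted ORF is the longest (bounded regeneration).
  Spurious NPA occurrences are scrubbed so planted positions are
  exhaustive. The 5' UTR excludes G, which prevents chance upstream
  starts/stops from competing with the planted frame.
* `gen_ct_table()`: 4 biological × 3 technical replicates, Gaussian Ct
  noise (default 0.2 cycles), folds planted on the target gene against a
  stable reference.

What passing these tests shows is that the *estimators* are correct and
well-calibrated under the stated noise families. What they cannot show is
robustness to everything real data adds: oocyte rupture and drift,
reference-gene instability, amplification-efficiency differences,
non-Gaussian plate effects, and the idiosyncrasies of real cDNA (repeats,
composition bias). Real deposited records (the GenBank transcripts and a
structure-solved reference channel) can be run through the same
annotator; the packaged tests use constructed stand-ins — always labelled
synthetic — so that the suite runs without downloads.

## Numerical details and edge cases

* An exactly constant series has zero total variance; its fit reports
  slope 0 and `NA` for $R^2$ rather than 0/0.
* `compare_groups()` and `group_stats()` fall back to p = 1 (flagged
  degenerate) when every observation is identical.
* Bisection for pI runs on [0, 14] to a net-charge tolerance of 10⁻⁴,
  ~200 iterations maximum; composition permutations cannot change the
  result, except through the N-terminal residue's own pKa.
* Alignment tie-breaking follows the alignment engine's deterministic
  traceback; identity among co-optimal alignments can differ in
  principle, so the brute-force oracle in the tests accepts any optimal
  alignment's identity.
* Problem sizes in the benchmarks (200 seeded repetitions for recovery
  and power studies; 500 random sequences for the ORF property; 128-300
  px frames) were chosen as the smallest sizes at which the Monte-Carlo
  estimates are stable to well within the asserted margins.

## A worked example

```{r example, eval = FALSE}
ex <- gen_swelling_experiment(seed = 1)
est <- estimate_permeability(ex$traces, kind = "pf", window_s = "auto")
compare_groups(est[est$group == "expressing", ],
               est[est$group == "control", ])
plot_traces(ex$traces)

tx <- gen_aqp_transcript(seed = 1)
annotate_aquaporin(tx$sequence)

tab <- gen_ct_table(conditions = c("foregut", "hindgut"),
                    true_folds = c(foregut = 1, hindgut = 19.23), seed = 1)
rq <- relative_quantity(tab, calibrator = "foregut")
group_stats(rq)
```

## Known limitations

* The swelling model holds surface area constant and the cell spherical;
  both break down for large volume excursions (membrane unfolding lets
  real oocytes exceed nominal surface limits before lysis).
* Only the initial slope is estimated; the full nonlinear curve is never
  fitted, so information in the late trace is unused by design.
* The hydropathy segment caller is not a topology predictor and makes no
  inside/outside claims.
* The Dunnett T3 p-values use the independence bound rather than the
  exact studentized-maximum-modulus distribution; they are conservative.
* No efficiency correction, melt-curve QC, or reference-gene stability
  ranking in the expression module.
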