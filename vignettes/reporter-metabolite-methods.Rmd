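---
title: "Methods: reporter-metabolite analysis, isotopomer correction and rate estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reporter-metabolite analysis, isotopomer correction and rate estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reportermet)
```

# The reporter-metabolite model

A genome-scale metabolic network links every metabolite to the reactions it
participates in, and every enzymatic reaction to the genes encoding its
enzymes. Projecting a differential-expression contrast onto this structure
asks a different question than per-gene testing: *around which metabolites
is transcription coordinately changing?* For each metabolite we form a gene
set — the union of genes associated with any reaction the metabolite takes
part in, in any role — and score that set for coordinated regulation. A
significant metabolite set is a *reporter metabolite*, a hotspot of
transcriptional regulation in the network. Pathway gene sets (all genes of
the reactions annotated to one pathway) and ordinary annotation sets (GO
terms, read from GMT files) are scored the same way.

## Gene-level statistic

Genes with FPKM below a floor (default 5) in any sample are discarded:
log-ratios of near-zero FPKM values are dominated by sampling noise. The
gene-level statistic is then the log2 FPKM ratio between the two conditions,
with replicate samples summarised by the arithmetic mean before the ratio.
The engine accepts any number of replicates, but the design it is built for
is a single profile per condition, where the statistic is simply the log2
ratio of the two profiles. Whether the expression floor should require all
samples or any sample to pass is exposed as `mode` in
`filter_expression()`; all-samples is the default because it is the
conservative choice for ratio statistics (both the numerator and the
denominator are then bounded away from zero).

## Set statistic and permutation null

The set statistic is the **median** of the member genes' statistics (mean
of the two central values for even sizes). The median is robust to a few
extreme members, which matters for metabolite sets that mix a coordinately
regulated pathway with unrelated housekeeping reactions.

Significance comes from **gene permutation**: the null for a set of
effective size $k$ (members intersected with the filtered universe) is the
distribution of medians of $k$ genes drawn without replacement from the
universe, redrawn independently each permutation. Five directionality
classes are reported:

* **distinct-directional up / down** — observed median of *signed*
  statistics against the right / left tail of null medians of signed
  statistics. Detects sets shifted coherently as a whole; this is the class
  that defines reporter metabolites here.
* **mixed-directional up / down** — median of the positive (negative)
  member statistics only, against medians of equal-count draws from the
  positive (negative) sub-universe. Detects significant partial regulation
  in sets whose remainder moves the other way or not at all.
* **non-directional** — median of absolute statistics against null medians
  of absolute statistics, right tail: regulation regardless of direction.

p-values use the estimator $p = (b+1)/(n_{perm}+1)$, where $b$ counts null
values *at least as extreme* as the observed one. This keeps $p > 0$ (a
permutation test cannot certify $p = 0$), and because ties count as
extreme, completely degenerate inputs (all statistics equal) give $p = 1$
rather than spurious significance. Benjamini–Hochberg adjustment is
computed within each class across sets and reported alongside; the default
report ordering uses raw p for the distinct-directional-up class, with
significance conventions of 0.005 for metabolite sets and 0.05 for GO sets.

Two implementation details are deliberate. First, permutation draws select
gene *positions* independently of the statistic values stored at them, so
two runs under the same seed visit the same gene labels even when the
statistics differ. This makes two properties exact rather than asymptotic:
negating every statistic exchanges the up and down p-values exactly, and
raising every member's statistic can never increase the up p-value. Second,
null distributions are computed once per distinct draw size per call (they
do not depend on which set is being scored), which is what makes 10,000
permutations across hundreds of sets cheap; the RNG is consumed in a fixed
phase order (signed/absolute nulls for all sizes, then positive-subset,
then negative-subset nulls) so results are reproducible bit-for-bit from
the seed.

For small universes `exhaustive = TRUE` enumerates all
$\binom{n}{k}$ subsets and reports the exact tail proportion. The
enumeration is the independent oracle against which the sampling path is
validated in the test suite; it refuses to run past a configurable subset
cap.

## Set-construction choices

* Compartmentalised networks default to one candidate set per (metabolite,
  compartment) — the network's native granularity; `collapse_compartments`
  merges by metabolite name for analyses that want one set per compound.
* Currency metabolites (water, protons, cofactor pools) touch hundreds of
  reactions and produce large, uninformative sets. Rather than hard-coding
  chemistry, the constructor exposes `max_size` (default 500) and a
  `blacklist` (default empty), both visible in the run manifest.
* `min_size` defaults to 5: the permutation null of a median over very few
  genes is coarse and unstable, and singleton "sets" are just gene tests.
* Gene–protein–reaction boolean rules are flattened to the set of genes
  they mention. Set membership is all the statistic needs; complex/isozyme
  logic would matter for flux analysis, which is out of scope.
* Ortholog translation (e.g. human network to mouse expression) replaces
  each member by all of its mapped targets: one-to-many expands, many-to-one
  merges, unmapped members are dropped by default.

# Natural-abundance correction of mass-isotopomer distributions

A measured mass-isotopomer distribution (MID) of a fragment with $n$
tracer-eligible carbons mixes true tracer labeling with naturally occurring
heavy isotopes of every atom. The forward model is linear: column $j$ of
the correction matrix is the expected measured mass-shift distribution of a
molecule with exactly $j$ tracer-derived labels, built by convolving
per-element mass-shift distributions — the $j$ labeled positions are heavy
with probability `purity` (default 1), and the remaining tracer carbons,
the non-tracer carbons and all other atoms (H, N, O, P, S) contribute at
natural abundance. The matrix is truncated to the observed window
M+0…M+$n$; column sums below 1 account exactly for mass beyond the window.

The correction solves `measured ≈ A %*% corrected` by **non-negative least
squares** (an active-set solve) and renormalises to sum 1. Plain inversion
of `A` can return negative fractions on noisy data; the constrained solve
cannot, by construction. The fit's residual norm is reported, and a
residual above `warn_tol` (default 0.01) flags the row rather than erroring
— a flagged fit usually means the measured vector is inconsistent with any
physical labeling pattern. Isotope abundance constants live in one editable
place (`natural_abundance()`); correction can be restricted to a subset of
elements (e.g. carbon only) via the `elements` argument, with full-formula
correction as the default. Unit-mass-resolution MS is assumed; resolved
fine structure is out of scope.

# Exchange rates, SDH activity, respiratory parameters

**Exchange rate.** The consumption/excretion rate $\alpha$ normalises the
change in a metabolite's amount in the medium by the cell-time that
produced it: $\alpha = 10^6 \, \Delta M / \int_0^t X(\tau)\,d\tau$, in nmol
per $10^6$ cells per hour. Cell numbers are modeled as exponential growth
between consecutive observed counts, so each interval contributes
$X_i(e^{k\Delta t}-1)/k$ with $k = \ln(X_{i+1}/X_i)/\Delta t$; the
$k \to 0$ limit $X_i \Delta t$ is substituted when $|k\Delta t| < 10^{-9}$
to avoid cancellation. This integral form is the only reading of a
per-cell-per-hour normalisation consistent with growth between two
timepoints. Excretion is positive, consumption negative; fold-changes
between conditions are ratios of $|\alpha|$. Optional blank correction
subtracts the cell-free well's change first (off by default).

**SDH activity** is the direct assay formula $B/(\Delta T \times V) \times
D$ (nmol DCIP · min⁻¹ · µl⁻¹).

**Respiratory parameters** summarise a four-phase mitochondrial stress
test. Measurements are averaged within phase (all cycles, not only the
final one — the simpler and lower-variance choice, since the protocol does
not specify). Non-mitochondrial respiration (post-rotenone) is subtracted
from basal and maximal (post-FCCP) rates; ATP-linked respiration is the
oligomycin drop; spare (reserve) respiratory capacity is maximal − basal,
also as a percentage of basal. When FCCP fails to raise OCR above basal the
reserve is *nonexistent*: reported as 0 with an explicit flag, not as a
negative capacity.

# What the synthetic data emulates — and what it does not

The generators in `sim_config()` / `simulate_fixtures()` produce every
input the pipeline consumes, with one RNG stream per generator derived from
the master seed by fixed offsets (adding a generator call never perturbs
the others).

* `sim_network()` builds a random bipartite reaction–metabolite structure
  with genes drawn per reaction. Planted metabolites get dedicated
  reactions whose gene lists partition an exact-size set, so recovery runs
  know the truth; planted sets may still overlap random sets through shared
  genes, exercising the non-partition structure of real metabolite sets.
* `sim_expression()` draws log-normal baseline FPKM (meanlog log 50, sdlog
  1 — a realistic bulk RNA-seq spread in which roughly 1% of genes fall
  below an FPKM of 5) and sets condition B to
  $\mathrm{baseline} \cdot 2^{\delta_g + \varepsilon}$ with planted effect
  $\delta_g$ and noise $\varepsilon \sim N(0, 0.5)$. Planted genes are
  floored at the expression threshold in both conditions so filtering
  cannot silently delete the signal.
* `sim_mids()` runs the *forward* natural-abundance convolution of known
  truths (plus optional multiplicative noise); `sim_growth_course()` uses
  the exact exponential model with a planted $\alpha$; `sim_ocr()` draws
  phase measurements around configured means, whose default FCCP/basal
  ratio of 1.59 represents a healthy 59% spare capacity.

The defaults are the validation conditions: universe of 2,000 genes, one
planted 20-gene metabolite set at +1.0 log2 units against noise sd 0.5,
10,000 permutations, significance 0.005; 500 null sets at 2,000
permutations for calibration; 1,000 random MIDs over 1–6 tracer carbons;
growth rates spanning 0 to ln(8)/72 h⁻¹ (an 8-fold expansion in 72 h).
These sizes were chosen as the smallest at which the planted effect is
decisively separated from the null and the calibration test has power.

What passing these tests does **not** show about real data: the generator
plants clean multiplicative effects on exact member sets with i.i.d.
Gaussian log-ratio noise. Real RNA-seq has mean–variance dependence,
correlated genes, batch structure, and metabolite sets whose members
overlap heavily (every gene of a hub metabolite's set belongs to many
other sets); permutation nulls over genes ignore inter-gene correlation
entirely, which can be anticonservative on real contrasts. The isotope
generators assume the forward model is exactly the correction model —
real spectra add baseline drift, detector nonlinearity and unresolved
interferences that no linear correction removes.

# Numerical and degenerate-input choices

* Medians of even-sized vectors are the mean of the two central values,
  consistently in R and in the compiled permutation kernel.
* Permutation draws use R's RNG (partial Fisher–Yates in compiled code),
  so `seed` fully determines results; identical seed, inputs and `n_perm`
  reproduce a result bit-for-bit.
* Sets with no member in the universe are skipped and listed with a
  reason, not scored at p = 1.
* A mixed-directional p-value is `NA` when the set has no member of that
  sign; `NA`s are excluded from BH adjustment.
* Result tables are sorted by distinct-up p with `set_id` as the
  deterministic tie-break, so reruns are byte-identical.
* The NNLS solve cannot return negative fractions; an all-zero solution
  (only possible for pathological inputs) is an error, not a silent 0/0.
* `exchange_rate()` requires $t_0 = 0$, strictly increasing times and
  positive counts, and treats $|k\Delta t| < 10^{-9}$ by the continuous
  limit.

# Known limitations

* Only the median set statistic and gene-permutation nulls are
  implemented; sample permutation is meaningless for the one-profile-per-
  condition design this targets, and other set statistics (mean, Stouffer,
  running-sum) are out of scope.
* SBML support covers the Level 3 core subset plus `fbc` gene products and
  `groups` pathways — enough for modern genome-scale reconstructions, not
  a general SBML toolkit; no flux modeling of any kind.
* The correction matrix supports C, H, N, O, P, S with a ¹³C tracer;
  other tracers (¹⁵N, ²H) would need the labeled-element generalisation.
* GO annotation sets are taken as given in GMT form; no ontology-aware
  propagation is performed.

# A worked end-to-end example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 42)
fix <- simulate_fixtures(cfg, tempfile("fixtures"))
res <- run_reporter_pipeline(list(
  expression = fix$expression, design = fix$design,
  network = fix$network, gmt = list(go = fix$go_gmt),
  n_perm = 10000, seed = 42, out_dir = tempfile("out")))
dplyr::arrange(tidy(res$results$metabolite), p_distinct_up) |> head()
autoplot(res$results$metabolite)
```
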