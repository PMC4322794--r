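# reportermet

Reporter-metabolite analysis of transcriptional regulation over
genome-scale metabolic networks, with companion tools for ¹³C
mass-isotopomer correction, growth-normalized metabolite exchange rates,
SDH enzymatic activity and mitochondrial respiratory parameters.

## Who this is for

Systems-biology and cancer-metabolism groups who have a two-condition
differential-expression contrast (e.g. a gene knockdown vs control) and
want to know *where in metabolism* transcription is being rewired — not
gene by gene, but metabolite by metabolite — and who run the standard
companion measurements of such studies: isotope tracing, spent-media
uptake/excretion assays, colorimetric enzyme assays and extracellular-flux
(Seahorse-style) oxygen traces.

## The method

For each metabolite *m* of a metabolic network, the genes of all reactions
in which *m* takes part form a gene set *G(m)*. With per-gene statistics
*s(g)* = log₂(FPKM_B / FPKM_A) over the filtered universe (FPKM ≥ 5 in
all samples), each set is scored by

  S(m) = median { s(g) : g ∈ G(m) }

and assigned permutation p-values against the null of medians of |G(m)|
genes drawn without replacement from the universe (gene-label
permutation, default 10,000 draws, p = (b+1)/(n_perm+1)). Five
directionality classes are reported — distinct-directional up/down
(signed medians), mixed-directional up/down (sign-restricted member
subsets vs sign-restricted sub-universes) and non-directional (absolute
statistics) — with BH adjustment within each class. Metabolites
significant in the distinct-directional class are **reporter
metabolites**: hotspots of coordinated transcriptional change in the
network. Pathway sets and GO-term sets (GMT) are scored identically, and
collections can be translated through an ortholog map (e.g. human network
→ mouse expression) first.

The same package implements the measurement-side calculations:

* `correct_mid()` — natural-abundance correction of mass-isotopomer
  distributions by non-negative least squares against the convolution
  matrix of the fragment's elemental formula;
* `exchange_rate()` — consumption/excretion rate α = 10⁶ · ΔM / ∫X(τ)dτ
  (nmol per 10⁶ cells per hour) under piecewise-exponential growth;
* `sdh_activity()` — B/(ΔT × V) × D;
* `respiratory_params()` — basal, ATP-linked, maximal and spare
  respiratory capacity from a four-phase stress-test OCR trace.

A seeded synthetic-data module (`sim_config()`, `simulate_fixtures()`)
generates toy networks, expression tables with planted reporter
metabolites, convolved MIDs, growth courses and OCR traces for end-to-end
validation.

## Worked example

```r
library(reportermet)

cfg <- sim_config(seed = 42)                  # 2,000 genes, planted 20-gene set at +1 log2
fix <- simulate_fixtures(cfg, "fixtures")
res <- run_reporter_pipeline(list(
  expression = fix$expression, design = fix$design, network = fix$network,
  gmt = list(go = fix$go_gmt), n_perm = 10000, seed = 42, out_dir = "out"))
#> filter: 1967 of 2000 genes retained (FPKM >= 5).
#> build-sets: 31 metabolite set(s).
#> ...
dplyr::arrange(tidy(res$results$metabolite), p_distinct_up, set_id) |> head(3)
#>   set_id    n_universe stat_median p_distinct_up padj_distinct_up
#> 1 M_planted         20      0.950      0.0001000          0.00310
#> 2 M024              10      0.316      0.0577             0.730
#> 3 M023              11      0.279      0.0876             0.730
```

The planted metabolite is recovered as the top reporter metabolite at
p = 1e-04 (the smallest value 10,000 permutations can certify), far below
the 0.005 reporting level; the runner-up null sets sit two orders of
magnitude higher. `res$tables` holds one sorted TSV per collection
(metabolite, pathway, go) and `manifest.json` records the config, input
digests and per-stage counts.

The measurement-side functions are one-liners:

```r
fit <- correct_mid(mid_vector(c(0.30, 0.02, 0.01, 0.67), "C3H5O3", "lactate"))
fit$corrected$fractions          # 0.311 0.010 0.008 0.671  (residual 2.5e-16)
fractional_labeling(fit$corrected)   # 0.68

sdh_activity(B = 10, delta_t_min = 30, volume_ul = 5)   # 0.0667 nmol/min/ul

respiratory_params(tibble::tibble(
  phase = c("basal", "oligomycin", "fccp", "rotenone"),
  ocr   = c(100, 40, 159, 0)))$reserve_capacity_pct      # 59
```

A thin CLI over the same functions lives at `inst/cli/reportermet.R`
(subcommands `gsa`, `correct-mid`, `rates`, `simulate`).

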