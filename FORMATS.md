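# File formats

All inputs and outputs are plain text. Paths below are the defaults used by
the `zinbiome` command-line wrapper; every function accepts/returns the
corresponding in-memory objects.

## Inputs

### ASV/OTU count table (TSV) — `readAsvTable()` / `writeAsvTable()`
First column `taxon` (unique ids), remaining columns one per sample
(header = sample ids), cells non-negative integers. No empty cells.

### Sample metadata (CSV) — `readMetadata()`
Required columns: `sample_id`, `age_years`, `sex` (`F`/`M`), `ethnic`
(e.g. `U`/`K`), `geography` (e.g. `S`/`W`/`H`/`N`), `height_m`,
`weight_kg`. Optional: `bmiaz` (BMI-for-age z-score; required by the `da`
and `fit` subcommands — produce it with `zscore`).

### Taxonomy table (TSV) — `readTaxonomyTable()`
Columns `taxon`, `lineage`; lineage is SINTAX-style,
`d:...,p:...,c:...,o:...,f:...,g:...` (missing ranks allowed; they pool
into `unclassified` on aggregation).

### LMS growth reference (CSV) — `readLmsReference()`
Columns `measure` (`bmi`/`height`/`weight`), `sex` (`F`/`M`),
`age_months` (strictly increasing per measure and sex), `L`, `M`, `S`
(`M`, `S` positive). A synthetic example ships in
`inst/extdata/lms_reference_synthetic.csv`; real WHO tables are supplied by
the user in this layout.

## Outputs

### Posterior fit (CSV) — `fit` subcommand
`parameter`, `mean`, `sd`, `q2.5`, `q97.5`, `ess`, `rhat`, `failed`.
Parameter names follow `beta[<design column>]`, `gamma[<zero column>]`,
`theta`, `tau`, `theta0`. Failed fits have `NA` numeric fields.

### Differential-abundance results (CSV) — `da` subcommand
Per taxon x covariate (`age_c`, `bmiaz`): `taxon`, `covariate`, `effect`
(posterior mean, log-mean scale), `sd`, `q2.5`, `q97.5`, `discriminatory`
(95% CI excludes 0), `highlight` (|effect| > threshold, default 0.35),
`failed`, plus per-taxon columns `phiHat`, `invThetaHat`, `relAbundance`
(taxon total / cohort total on the filtered table).

### Interaction report (CSV) — `da --interactions-out`
`taxon`, `ethnic`, `geography`, `effect`, `q2.5`, `q97.5` for each observed
non-reference (ethnic, geography) cell, relative to the reference cell,
plus `nonOverlap` (TRUE when at least one pair of cells for the taxon has
non-overlapping intervals).

### Benchmark results (CSV) — `benchmark`
`n`, `effect`, `phi`, `invTheta`, `model`, `replicate`, `arb`,
`invThetaEst`, `failed`. Failed fits have `arb = NA`. The optional summary
CSV carries per-cell `meanArb`, `sdArb`, `meanInvThetaEst`, `naCount`.

### Per-taxon characterization (CSV) — `characterize`
`taxon`, `mean`, `sd`, `zeroFraction`, `phiHat`, `invThetaHat`,
`invThetaNbHat` (NB part after removing estimated extra zeros),
`zeroInflated`.

### Cohort summary (JSON) — `characterize --summary-out`
Keys `zeroInflatedFraction`, `meanPhiFlagged`, `overdispersedFraction`,
`nTaxa`, `nSkipped`.

### GVIF screen (CSV) — `gvif`
`candidate`, `maxGvifScaled` (max GVIF^(1/(2 df)) over term groups),
`acceptable` (strictly below 3), `rankDeficient`.

### Metadata with z-scores (CSV) — `zscore`
The input metadata plus `bmiaz` and `zbmi_class`
(underweight/normal/overweight/obese).
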