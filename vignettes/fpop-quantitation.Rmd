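---
title: "Quantifying the extent of modification in FPOP footprinting data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the extent of modification in FPOP footprinting data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpopquant)
```

## The measurement

In hydroxyl radical protein footprinting (HRPF), and in particular fast
photochemical oxidation of proteins (FPOP), hydroxyl radicals generated by
laser photolysis of hydrogen peroxide covalently oxidize solvent-exposed
side chains. After proteolysis and LC-MS/MS, a database search assigns each
spectrum to a peptide, possibly carrying localized oxidation products
(+15.9949, +31.9898, +47.9847 Da and a range of side-chain-specific
masses). The structural readout is the *extent of modification* (EOM): the
fraction of a peptide's total extracted-ion-chromatogram (XIC) area that is
carried by its modified forms,

$$
\mathrm{EOM} \;=\; \frac{\sum_{\text{modified forms}} A_f}
                        {A_{\text{unmod}} + \sum_{\text{all forms}} A_f}.
$$

At residue level the numerator is restricted to forms modified at that
residue. Because oxidation also occurs in solution without irradiation,
no-laser control samples (peroxide-exposed, not irradiated) are quantified
identically and their mean EOM is subtracted as background:
$\mathrm{EOM}_{\text{net}} = \overline{\mathrm{EOM}}_{\text{laser}} -
\overline{\mathrm{EOM}}_{\text{control}}$.

A companion statistic, the *average peptide oxidation events* (APO),
weights each form by its number of oxidation events $k_f$:

$$
\mathrm{APO} \;=\; \frac{\sum_f k_f\,A_f}
                        {A_{\text{unmod}} + \sum_f A_f},
$$

so a peptide whose modified signal sits in a single triply-oxidized form
has APO three times its EOM. APO and peptide EOM bracket the information a
residue-level analysis resolves; `fpopquant` reports both.

## Pipeline

`fpop_quantify()` takes a canonical five-column PSM table (protein
accession, peptide sequence, modification annotation, precursor abundance,
spectrum file — the minimal schema every supported search-engine export
can be mapped onto with `apply_column_mapping()`), plus a sample map
assigning each spectrum file to condition × replicate × {laser, control}.
The stages are:

1. **Modification parsing and classification** (`parse_modifications()`,
   `classify_events()`). Three annotation grammars are supported (Proteome
   Discoverer bracket tokens, FragPipe assigned-modification tokens, and a
   positional generic grammar). Events are classified `fpop` / `fixed` /
   `other` against an extensible catalog; a row whose annotation
   contradicts its sequence is quarantined to the filter audit rather than
   aborting the run.
2. **Search-node deduplication** (`deduplicate_nodes()`). Multilevel
   search workflows report the same identification — most often the
   unmodified peptide — once per search node. Left in place, those
   duplicates inflate the EOM denominator and bias the EOM low. Within
   each (file, sequence, form, charge) group one record survives.
3. **Charge-state summation** (`summarize_areas()`). Form areas are summed
   over charge states within each spectrum file, never across files.
4. **Missing-unmodified filter** (`filter_missing_unmodified()`). A
   modified form without an observed unmodified peptide in the same file
   yields no defensible ratio and is excluded for that file only.
5. **Per-replicate EOM/APO**, then the **replicate-support filter**
   (`filter_replicate_support()`): a target is reported only when its
   modified area is seen in at least `min_mod_replicates` laser
   replicates.
6. **Replicate averaging and control subtraction**. Arithmetic mean and
   sample SD across laser replicates; controls are pooled into one
   background mean per condition and subtracted.
7. **Condition comparison** for multi-condition runs: Welch's t-test on
   per-replicate control-subtracted EOMs, restricted to proteins
   quantifiable in every condition, with optional Benjamini-Hochberg
   adjustment.

```{r example}
cfg <- synth_config(n_proteins = 5, peptides_per_protein = 3,
                    replicates_per_condition = 4, control_replicates = 3,
                    sigma = 0.15, seed = 42)
experiment <- generate_experiment(cfg)
fit <- fpop_quantify(experiment$psm, experiment$sample_map)
fit
head(fit$peptide[, c("condition", "protein", "sequence", "n",
                     "mean_eom", "control_mean", "net_eom", "apo")])
```

## Parameters that matter

* `min_mod_replicates` (default **3**, dimensionless count). The rule it
  implements is that an EOM is only trustworthy when the oxidized species
  is observed in more than two replicate samples; the literal reading is
  ≥ 3, which is the default. The phrasing is ambiguous between strictly
  more-than-two and at-least-two, and designs with n = 3 replicates are
  common, so the threshold is exposed rather than hard-coded; the audit
  records the value used. The filter counts *laser* replicates only —
  controls estimate a background mean with however many replicates observe
  it.
* `mass_tol` (default **0.01 Da**). Catalog matching tolerance; search
  engines report deltas to four decimals, so 0.01 Da separates every
  default catalog entry while absorbing rounding.
* `dedup_policy` (default **max**). Which duplicate survives is not
  observable in the EOM when duplicates are true copies; `max` (highest
  abundance, ties to first) is deterministic when they are not. `first`
  is available for strict input-order semantics.
* `denominator_mode` (default **literal**). The residue-level denominator
  is stated in the field as "the modified residue and all unmodified
  residues in the peptide", which reads as numerator + unmodified area;
  that is the `literal` mode. The grammatically alternative reading —
  the full peptide denominator — is `all_forms`, and carries an exact
  identity: summed over residues, `all_forms` residue EOMs equal the APO.
  Both are implemented because the sentence genuinely underdetermines the
  intent; tests pin each mode to its own closed form.
* `mean_mode` (default **arithmetic**). FPOP replicate EOMs are not
  heavy-tailed enough to warrant a geometric mean, and the arithmetic mean
  supports ordinary SDs and t-tests. The geometric mode
  (`exp(mean(log v))`, zeros mapped to 0 with a flag) is provided for
  compatibility with legacy spreadsheet pipelines.
* `clip_negative` (default **FALSE**). Background subtraction can produce
  a negative net EOM; silently clipping hides control anomalies, so
  negatives are reported with a `negative_net` flag, and clipping (with
  the original value preserved in the flags) is opt-in.

N-terminal annotations take position 0 and never classify as FPOP unless a
catalog entry explicitly permits the N-terminus: N-terminal acetylation is
a search-artifact class, not a footprint.

## The synthetic-data generator

`generate_experiment()` emulates the *structure* of a searched FPOP
experiment: multi-condition, multi-replicate PSM tables containing
unmodified and modified peptide forms, multiple charge states, no-laser
controls with background oxidation, and the two corruption modes the
filters target (node duplicates, replicate dropout). Defaults describe the
reference design used throughout the tests: 100 peptides over 20 proteins,
2 conditions × 4 laser replicates + 4 controls, true per-peptide modified
fraction uniform in [0.05, 0.5], 2% control background, oxidation confined
to the commonly searched M/F/H/I/L/V/W/Y residues, 20% of modified area in
a 2-3-site form, two charge states.

Abundance is lognormal: the per-file total peptide area is drawn with
log-scale SD `sigma`, and every XIC component (form × charge) receives
independent mean-preserving lognormal noise with the same `sigma`,
reflecting independently integrated chromatographic peaks. `sigma = 0`
therefore yields exact, noise-free fractions — the property the noise-free
recovery test exploits — and `sigma = 0.2` is a realistic label-free
replicate scatter. Duplicates and dropout are applied as post-processing
passes seeded separately (`seed + 1`, `seed + 2`), so changing their rates
never perturbs the core draw; that is what makes the duplicate-invariance
test an exact byte-level comparison.

What the generator does **not** emulate: retention-time structure, isotope
envelopes, interference/chimeric spectra, missing peptides, search-engine
FDR behavior, or intensity-dependent missingness. Passing tests therefore
demonstrate the *arithmetic and filtering logic* on structurally faithful
tables, not robustness to every pathology of real LC-MS data.

## Numerical choices

* Welch's t-statistic is computed in closed form with a 1e-12 variance
  floor per group, so zero-variance replicate lists (common on clean
  synthetic data) give a defined, conservative p-value instead of an
  error; away from that corner it agrees with `stats::t.test()` to
  1e-10, which the tests check.
* Result TSVs serialize doubles with 17 significant digits, making
  write/read a bit-exact round trip; the determinism and
  duplicate-invariance checks compare output files byte for byte.
* Aggregation uses the n−1 sample SD, with `sd = 0` and a `low_n` flag for
  singletons. The recovery check treats `sd/sqrt(n)` as the standard error
  of a target's net EOM; with 4 replicates that interval behaves like a
  t(3) interval, whose 3-SE coverage is ~94% nominally, so coverage
  observed near 95% on the reference design is the expected behavior, not
  slack.
* Deduplication, filtering and aggregation iterate over groups in first-
  appearance order and break ties by input order, so every output is a
  pure function of the input table and configuration.

## Problem sizes

Unit and property tests run on 200-summary random batteries and 5-15
protein synthetic experiments; the recovery check uses the full reference
design (100 peptides, 16 spectrum files, ~16,000 PSM rows), which
quantifies in a few seconds. These sizes give stable statistics while
keeping the default suite quick.

## Known limitations

* Protein-level coordinates for residue reporting require a mapped
  `protein_start` column; otherwise residues are reported
  peptide-relative (`M5@PEPTIDE`).
* Control and laser replicates are never paired; controls are pooled into
  a per-condition background mean. FPOP designs do not pair them, but a
  paired design would need a different estimator.
* TMT channels are treated as independent pseudo-files after expansion;
  no reporter-ion normalization is applied.
* The comparison stage assumes per-replicate EOMs are approximately
  normal; with 3-4 replicates the Welch test is indicative, not exact.
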