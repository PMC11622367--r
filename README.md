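# fpopquant

Quantitation of covalent-labeling / hydroxyl-radical protein footprinting
(FPOP/HRPF) mass spectrometry experiments, from search-engine PSM tables to
filtered, control-subtracted, replicate-averaged **extent of modification
(EOM)** at peptide and residue level.

In FPOP, hydroxyl radicals oxidize solvent-exposed side chains; the
structural signal is the fraction of each peptide's XIC area carried by its
oxidized forms,

```
EOM = Σ (modified form areas) / (unmodified area + Σ all form areas)
```

with the background EOM of no-laser control samples subtracted, and the
companion statistic APO (average peptide oxidation events) weighting each
form by its number of oxidation events:

```
APO = Σ (k_f × A_f) / (unmodified area + Σ all form areas)
```

The package is aimed at structural-proteomics labs doing peptide- or
proteome-wide footprinting who have searched their data with Proteome
Discoverer, FragPipe, or anything that can export the five minimal
columns (protein accession, peptide sequence, modification annotation,
precursor abundance, spectrum file). It implements the fidelity rules that
make EOM trustworthy at scale:

* **search-node deduplication** — multilevel searches report the same
  (usually unmodified) identification once per node, silently deflating the
  EOM; one record survives per (file, peptide, form, charge);
* **missing-unmodified exclusion** — no ratio is reported for a file in
  which the unmodified peptide was not observed;
* **replicate support** — a target needs modified-area evidence in at
  least `min_mod_replicates` (default 3) laser replicates;
* **both-conditions restriction** — differential comparisons cover only
  proteins quantifiable in every condition;

plus charge-state summation, an extensible modification catalog
(+16/+32/+48 series and common side-chain products by default), arithmetic
replicate averaging with a geometric-mean compatibility mode, Welch
condition comparisons, bar / grouped-bar / Venn / volcano graphics, and a
synthetic-data generator with known ground truth.

## Worked example

```r
library(fpopquant)

cfg <- synth_config(n_proteins = 5, peptides_per_protein = 3,
                    replicates_per_condition = 4, control_replicates = 3,
                    sigma = 0.15, seed = 42)
experiment <- generate_experiment(cfg)
fit <- fpop_quantify(experiment$psm, experiment$sample_map)
fit
#> FPOP extent-of-modification results
#>   conditions: A, B
#>   peptide targets: 30   residue targets: 102
#>   rows: 2100 in -> 2100 after parsing -> 2100 after deduplication
#>   filter audit entries: 0 (none)
#>   condition comparisons: 66 (Welch)

head(fit$peptide[, c("condition", "protein", "sequence", "n",
                     "mean_eom", "control_mean", "net_eom", "apo")], 4)
#>   condition protein       sequence n mean_eom control_mean net_eom   apo
#> 1         A PROT001 ECWFFVPAGTCNNR 4    0.403       0.0188   0.384 0.560
#> 2         A PROT001   EGGLCVDFATIR 4    0.126       0.0213   0.105 0.176
#> 3         A PROT001     FASFWHTAMK 4    0.487       0.0207   0.467 0.675
#> 4         A PROT002 ESEPTCGNYLYSSK 4    0.312       0.0195   0.293 0.441
```

Each row is one peptide in one condition: `mean_eom` is the arithmetic
mean over the `n` laser replicates, `control_mean` the pooled background
EOM of the no-laser controls (here the generator's true 2% background),
`net_eom` their difference — the quantity plotted and compared between
conditions — and `apo` the event-weighted oxidation measure (`apo >
mean_eom` whenever multi-site forms are present). Against the generator's
ground truth this run recovers net EOM with a mean absolute error of
0.0087 over 30 targets.

Results are written with `write_results(fit, "out/")` (peptide, residue,
comparison, filter-audit and Venn-membership TSVs plus a config echo);
figures with `plot(fit, kind = "bar" | "grouped_bar" | "venn" |
"volcano")`.

Real exports enter through the same path:

```r
rows <- read_psm_table("psm.tsv")                 # or .csv / .xlsx
psm  <- apply_column_mapping(rows, default_column_mapping("fragpipe"))
fit  <- fpop_quantify(psm, read_sample_map("sample_map.tsv"),
                      dialect = "fragpipe")
```

A thin command-line wrapper with `simulate` / `quantify` / `plot`
subcommands is installed at `system.file("cli", "fpopquant", package =
"fpopquant")`.

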