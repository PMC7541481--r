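# cyrho

Screening, clade assignment and photocycle kinetics of microbial rhodopsins.

Cyanobacteria were long assumed to capture light only through chlorophyll
photosynthesis, yet many freshwater strains also carry genes for microbial
rhodopsins — seven-transmembrane photoreceptors that bind retinal through a
Schiff-base lysine and can pump ions across the membrane. A recently
characterised clade of such proteins (cyanorhodopsins, CyR) consists of
light-driven outward proton pumps found exclusively in non-marine
cyanobacteria, absorbing green light at 550 nm with an unusually long-lived
M intermediate and an extremely acidic proton-acceptor pKa.

`cyrho` packages the computational side of that kind of study as reusable,
tested components:

- **Genome screening** — detect rhodopsin homologs in proteomes by pairwise
  alignment (BLOSUM62, affine gaps) against a labelled reference panel;
  read off the helix-C ion-transport motif (DTD/DTE, NDQ, NTQ/TSD, ...),
  the Schiff-base lysine, counterion and proton-release residues at
  reference-numbered positions; predict transport function from an ordered
  rule table.
- **Clade assignment** — neighbor-joining trees on p-distances with
  column-bootstrap support (100 replicates), bipartition-based clade
  placement with a ≥50% support rule, and the habitat-by-clade survey table.
- **Photocycle kinetics** — forward-simulate the sequential proton-pump
  photocycle K → M → O → ground (closed-form Bateman populations, Gaussian
  spectral bands) on the instrument grids (370–700 nm at 5 nm, 0.01–977 ms);
  fit the M-decay rate constant by single-exponential least squares and all
  time constants with decay-associated spectra by variable projection;
  model pyranine proton-release/uptake traces.
- **pKa titration** — simulate two-species pH titration series and estimate
  pKa by Henderson–Hasselbalch fitting,
  `A(pH) = A_prot + (A_deprot − A_prot) / (1 + 10^(pKa − pH))`,
  with censored reporting ("pKa < 2.0") when the midpoint is not bracketed
  by the sampled pH range.
- **Synthetic data with ground truth** — every input above can be generated
  with planted truth (clade-labelled homologs with planted motifs plus
  decoys; noisy flash-photolysis matrices; titration series), so every
  stage has end-to-end recovery tests.

## Worked example

```r
library(cyrho)

# --- photochemistry: simulate the pH 7 photocycle and fit it back
model <- photocycle_model()                     # 550-nm ground state, k2 = 0.016 ms^-1
flash <- gen_flash_dataset(model, noise_sigma = 0.001, seed = 42)
fit   <- fit_m_decay(flash)
sprintf("M-decay rate: %.4f ms^-1 (se %.2g)", fit$rate, fit$stderr)
#> [1] "M-decay rate: 0.0160 ms^-1 (se 7.9e-05)"

gfit <- global_fit(flash, 3, seed = 42)
signif(gfit$tau, 4); gfit$assignment
#> [1]  0.4994 19.7700 62.6100
#> [1] "K" "O" "M"

# --- titration: alkaline side (Schiff-base lysine), then acid side
fit_pka(gen_titration_dataset(10.7, acid_side = FALSE, noise_sigma = 0.002, seed = 42))
#> Henderson-Hasselbalch fit at 550 nm: pKa = 10.706 (se 0.00317)
fit_pka(gen_titration_dataset(acid_side = TRUE, noise_sigma = 0))
#> Henderson-Hasselbalch fit at 605 nm: pKa < 2.00 (estimate 1.500 near acid boundary)

# --- survey tabulation on the packaged synthetic 154-genome reconstruction
tab <- tabulate_habitat(cyanobacteria_survey_fixture())
tab[tab$subclade == "Total", c("possessing_genomes", "all_genomes", "gene_total",
                               "CyR", "Freshwater")]
#> Rhodopsin distribution and habitats
#>  possessing_genomes all_genomes gene_total CyR Freshwater
#>                  42         154         56  13         29
```

The fitted M-decay rate (0.016 ms⁻¹) is the observable that makes this pump
stand out — its M state lives ~15–250× longer than in the classic proton
pumps — and the two pKa results reproduce the reporting of the titration
analysis: a normal Schiff-base midpoint near 10.7 and an acid-side midpoint
too low to bracket, reported as a "< 2.0" bound.

The whole synthetic survey (generate genomes → screen → motifs → tree →
clade assignment → habitat table → one kinetics and one titration recovery)
runs from a single seeded configuration:

```r
res <- run_pipeline(run_config(master_seed = 3, n_genomes = 6, out_dir = "demo_run"))
res$habitat_table
```

A thin shell wrapper lives at `inst/scripts/cyrho-pipeline.R`
(`Rscript cyrho-pipeline.R --config cfg.yaml --seed 3 --out run_dir`).

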