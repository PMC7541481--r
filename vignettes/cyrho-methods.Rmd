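---
title: "Models and methods in cyrho"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in cyrho}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyrho)
```

`cyrho` re-implements, as reusable and fully tested components, the two
computational stages behind the characterisation of cyanobacteria-specific
light-driven proton pumps (the cyanorhodopsin, or CyR, clade): a genome
screening / clade-assignment stage over protein sequences, and a
spectroscopy stage that models and fits the pump's photocycle and the pH
titration of its key side chains. Every input the pipeline consumes can be
generated synthetically with known ground truth, which is what makes the
recovery properties of each stage testable. This vignette explains the
models, the defaults and why they were chosen, the numerical choices, and
what the synthetic tests do and do not demonstrate.

## 1. Sequence screening

### Homology detection

Candidate rhodopsins are detected by pairwise alignment of every query
protein against a labelled reference panel (BLOSUM62, affine gaps with
opening 11 / extension 1, global alignment with free end gaps). A query is a
hit when its best reference alignment reaches 25% identity over aligned
columns and covers 60% of the reference. We deliberately use pairwise
alignment against a panel rather than a profile HMM: the panel is an
explicit, user-replaceable configuration item, the method is self-contained,
and on the synthetic benchmark (substitution-only divergence up to 0.3 per
site) it separates homologs from unrelated decoys with a wide margin —
screening precision and recall are both 1.0 across seeds in the test suite.
On real, indel-rich and deeply diverged data a profile method would be more
sensitive; the thresholds are therefore exposed as arguments, and the
reference panel, not the algorithm, is the main determinant of sensitivity.

### Functional positions and the helix-C motif

Ion-pumping function in microbial rhodopsins is carried by a handful of
positions: the helix-C triplet (proton acceptor, its hydrogen-bond partner,
the proton donor — D85/T89/D96 in bacteriorhodopsin numbering, hence "DTD"),
the Schiff-base lysine in helix G, the counterion aspartate, and the
extracellular proton-release glutamate pair. `reference_map()` records where
these sit on a reference sequence; `extract_motif()` aligns a query to that
reference and reads off the query residues in those columns, reporting
1-based positions in the query's own coordinates and flagging roles that
align to gaps (a warning, never an error: a truncated query is still
reportable).

`predict_function()` applies an ordered first-match rule table: no Schiff
lysine → non-functional opsin; DTD or DTE triplet with an acidic acceptor →
outward proton pump; NDQ → sodium pump; NTQ/TSD-type → chloride pump; acidic
acceptor without an acidic donor → inward-pump/sensor class; otherwise
unknown. The lysine rule comes first because without the retinal linkage no
transport is possible; the DTD/DTE rule precedes the chloride/sodium rules
because the proton-pump motifs are the decision of interest here. The table
is a data object, so rule order is visible configuration, and the prediction
is total: every conceivable motif call maps to exactly one label. One known
caveat is encoded deliberately: a DTD-bearing protein with weak measured
activity might transport another ion, but the rule table still labels DTD as
an outward proton pump — resolving that requires wet-lab evidence, not
sequence analysis.

### Trees, bootstrap and clade assignment

Distances are p-distances over gap-free aligned columns (optionally
Poisson-corrected, $d = -\ln(1-p)$), trees are neighbor joining, and supports
come from the classical Felsenstein column bootstrap with 100 replicates.
This replaces maximum-likelihood inference on purpose: clade *assignment*
depends on separation between clades, not on branch-length optimality, NJ on
additive distances provably recovers the generating topology (a property the
suite tests against random additive trees via the four-point condition), and
the whole analysis stays desk-scale. An externally computed newick tree can
be supplied instead wherever a tree is consumed. Negative NJ branch lengths,
a known artefact on non-additive input, are clamped to zero with a warning.

The multiple alignment behind the bootstrap is reference-anchored: every
sequence is aligned to one anchor and the columns stacked, with insertions
relative to the anchor dropped. This is exact for the substitution-only
synthetic data and adequate for indel-light real data; for indel-rich data a
progressive MSA should be substituted upstream. Leaf rows are canonically
sorted before resampling so bootstrap supports are invariant to input order;
column resampling occasionally removes the entire overlap of a very distant
pair, in which case that replicate pair receives 1.5 times the largest
finite distance rather than aborting the replicate.

A query is assigned to the clade of its nearest reference only if three
checks pass: the nearest-clade distance is not tied with another clade; the
tree contains a bipartition side holding the clade's references and the
query, free of foreign references, whose subtending edge has bootstrap
support of at least 50% (the display convention of published rhodopsin
trees); and the query's distance to the clade is at most 2.5 times the
clade's own reference diameter (plus an absolute floor of 0.05). The third
check exists because an unrelated sequence often attaches to the tree as a
long-branch *sister* of some clade — topologically inside a supported side,
but at a distance incompatible with membership. The stretch factor is
deliberately generous: clade members generated at the default divergence sit
near 1 times the diameter, unrelated decoys near 20 times, so the rule is
insensitive to its exact value.

### The habitat table

`tabulate_habitat()` reduces genome records to the survey summary: per
genomic subclade (A–G, NA), the number of rhodopsin-possessing genomes, gene
counts per rhodopsin clade, and possessing-genome counts per habitat
(marine / freshwater / saline / unknown; "high salinity" in survey prose maps
to the Saline column). Internal consistency (row and column sums) is
asserted on every output. `cyanobacteria_survey_fixture()` ships a
deterministic, explicitly synthetic 154-genome reconstruction whose
*marginals* match the published survey (56 genes in 42 of 154 genomes; 3/1/
15/24/13 genes across the XLR/NaR/XeR/CyHR/CyR clades; 2/29/9/2 possessing
genomes across habitats; diox1 in 152 genomes). The per-subclade cells of
the printed table are typographically ambiguous in our source text, so only
the prose-stated marginals are anchored; the row-level allocation is an
invented but consistent stand-in, and is documented as such.

## 2. Synthetic sequence generation

The generator builds a 250-residue scaffold (uniform over the 20 amino
acids) with seven mapped functional sites, using the numbering of the
N2098R-type pump by default (acceptor 74, hydrogen-bond partner 78, donor
85, release pair 182/192, counterion 200, Schiff lysine 204). Each clade has
a founder drawn from the scaffold at the template's divergence (expected
substitutions per site, default 0.25) and members drawn from the founder at
one third of that divergence, so within-clade identity dominates
between-clade identity by construction; founders are a pure function of the
scaffold specification and the clade label, so references and planted
genome genes generated in separate calls belong to the same clades.
Mutations are substitutions only, keeping site coordinates exact; an
optional indel-stress flag inserts one short loop away from the mapped
sites. Two negative classes exist: unrelated decoys (fresh random sequences)
and, implicitly, homologs whose Schiff-lysine site is ablated — decoys carry
both properties at once. CyR-like templates put zero habitat weight on
marine environments, mirroring the non-marine composition of the real clade;
this is a generator default, not a claim about genomes. All generators are
pure functions of their arguments and a seed; one master seed spawns
per-component substreams (`substream_seed()`), so no stage reads system
entropy and adding a stage never perturbs another stage's stream.

What the synthetic data does *not* emulate: realistic proteome composition
(everything that is not a planted gene is a uniform-random decoy), gene
synteny, nucleotide-level evolution, rate heterogeneity across sites, and
(by default) indels. Passing recovery tests therefore demonstrate
correctness of the machinery under the stated generative model, not
real-data sensitivity.

## 3. The photocycle model

After flash excitation, the pump traverses a sequence of spectrally
distinct intermediates before recovering: a red-shifted K state, the
blue-shifted M state (deprotonated Schiff base), and a red-shifted O state.
`photocycle_model()` implements the minimal irreversible first-order chain

$$K \xrightarrow{k_1} M \xrightarrow{k_2} O \xrightarrow{k_3} \text{ground},$$

with a flash exciting a fraction $f$ of the ground state into K. Exactly
these three intermediates are resolved for the N2098R pump, and no
back-reactions are reported, so none are modelled; the L and N states known
from bacteriorhodopsin are likewise omitted. Light/dark adaptation is
ignored (one all-trans ground state), consistent with the observation that
both adapted forms of N2098R have the same absorption maximum and
predominantly all-trans retinal.

Populations follow the closed-form Bateman solution. Near-degenerate rate
pairs (relative gap below $10^{-9}$) switch to the analytic
$t\,e^{-kt}$-type limits instead of evaluating cancellation-prone generic
formulas; the suite verifies both regimes against an independent
Runge–Kutta integration to $10^{-8}$ and mass conservation to $10^{-9}$.

Defaults describe the N2098R photocycle at pH 7: ground band at 550 nm, K,
M and O bands at 620, 405 and 645 nm, and $k_2 = 0.016$ ms$^{-1}$ (the
published M-decay rate). The K-formation-side rate $k_1 = 2$ ms$^{-1}$ and
O-decay rate $k_3 = 0.05$ ms$^{-1}$ are not printed anywhere; they are
modelling choices set once so that M rises within about 2 ms and the cycle
completes by roughly 300 ms, matching the reported timing bounds, and they
are never used as recovery truth. Spectral bands are Gaussians in
wavelength — transparent against wavelength-domain difference spectra,
slightly unphysical versus wavenumber-domain bands — with default widths of
40 nm (ground, K, O) and 30 nm (M) and amplitudes 1.0/0.9/0.8/0.35, giving
the two large positive features (K, M) and one small one (O) seen in the
published difference spectra. The excited fraction defaults to $f = 0.3$;
all difference amplitudes scale linearly in $f$, so every recovery quantity
used in testing is a rate, time or peak position, never an absolute
amplitude.

The simulated difference matrix is
$\Delta A(\lambda, t) = K b_K + M b_M + O b_O - (K{+}M{+}O)\, b_G$
on the published grids (370–700 nm in 5-nm steps; 100 log-spaced times
spanning 0.01–977 ms), plus i.i.d. Gaussian noise. The pyranine proton
trace is $-c \cdot M(t)$: under 1:1 stoichiometry with release on
M-formation and uptake on M-decay, the bulk acid excess at any instant
equals the current M population, which reproduces the observed
dip-then-recover shape with the dip between 0.1 and 100 ms.

### Fitting

`fit_m_decay()` restricts the 405-nm trace to times at and after its
extremum and fits $A e^{-kt} + c$ by Levenberg–Marquardt least squares,
multi-started from 8 log-spaced initial rates spanning the observation
window; the best sum of squares wins. The small early-time contamination
from the fast K→M phase decays orders of magnitude faster than M itself at
the default rate separation and biases the fit by well under 1%.

`global_fit()` fits $\Delta A(\lambda,t) = \sum_i \mathrm{DAS}_i(\lambda)\,
e^{-t/\tau_i}$ by variable projection: for any candidate $\tau$ set the
decay-associated spectra are the linear least-squares solution per
wavelength (via QR), and only the $\log\tau$ vector is optimised
(Nelder–Mead, multi-start with seeded jitter, SSE tolerance $10^{-12}$ with
a polish pass at $10^{-14}$; Brent's method for the one-component case).
Candidate sets with two time constants closer than $10^{-6}$ relative, or a
rank-deficient design, score infinite and are thereby rejected — fresh
starts take over. Components are assigned to intermediates by the
wavelength of their positive DAS peak, matched greedily (best match first)
to the configured band centers (K 620, M 405, O 645 nm); an all-negative
DAS is matched by its bleach-side extremum. On noiseless self-generated
data the three time constants are recovered to $10^{-3}$ relative error.

`mdecay_vs_ph()` tabulates the M-decay rate across per-pH datasets. The
acid-side acceleration seen in proton pumps is *reported* (a monotonicity
attribute), never enforced, because the functional form of the pH dependence
is not established.

## 4. Titration and pKa estimation

A titration series is a two-species mixture: protonated and deprotonated
forms contribute fixed spectral bands weighted by the Henderson–Hasselbalch
occupancy $\theta(\mathrm{pH}) = 1/(1 + 10^{\,\mathrm{p}K_a - \mathrm{pH}})$
with Hill slope fixed at 1, per the single-pKa assumption; multi-site
fitting is out of scope. On the acid side (counterion protonation) the
visible band red-shifts; on the alkaline side (Schiff-base deprotonation)
it collapses toward a 410-nm band. Wavelength coverage is 250–750 nm in
5-nm steps.

`fit_pka()` tracks absorbance at the wavelength of maximal change across
the series (auto mode — the acid and alkaline transitions shift different
bands, so no single fixed wavelength serves both) and fits the occupancy
model, profiling the two asymptote absorbances out linearly so only the pKa
is optimised (coarse grid scan, then Brent to $10^{-8}$). The standard
error comes from the curvature of the profiled objective.

A midpoint within half a pH unit of the sampled boundary is not reliably
bracketed: the fit then reports a censored result with the bound one unit
inside the range, read as "pKa < bound" (acid side) or "> bound" (alkaline
side). This reproduces the reporting style of the source analysis, where
the proton acceptor's midpoint lies below the lowest measurable pH and is
given as "< 2.0". The boundary comparison is inclusive with a $10^{-6}$
tolerance so that a noiseless midpoint sitting exactly on the threshold
censors deterministically. The generator's default acid-side truth (1.5 on
a grid starting at pH 1.00) sits exactly at that threshold by design — it
exercises the censoring path, and under noise the reported
estimate-or-bound never exceeds 2.0 either way.

## 5. Interfaces, sizes and limitations

The package's interface is its exported functions; `run_pipeline()` ties
all stages together on one `run_config()` (master seed, generator sizes,
thresholds, bootstrap count), writes FASTA/TSV/CSV/newick/JSON artifacts
plus a manifest (config hash, seed, versions) into a run directory, and a
thin script at `inst/scripts/cyrho-pipeline.R` exposes it to the shell.
Residue positions are 1-based everywhere; CSV matrices carry the wavelength
in the first column and time (ms) or pH as column headers.

Test-suite problem sizes are deliberately desk-scale: panels of 5 clades
with 1–3 references each, 4–10 genomes per screening experiment, 100
bootstrap replicates, 10–50 noise seeds per recovery estimate, 200 seeds
for peak-finder robustness. These sizes make every stochastic claim cheap
to re-verify while keeping Monte-Carlo error well inside the asserted
tolerances.

Known limitations, restated: no profile/HMM search and no
transmembrane-topology checks; reference-anchored (not progressive)
alignment; NJ instead of likelihood trees; irreversible three-state
photocycle without branching, photo-selection or temperature dependence;
Gaussian-in-wavelength bands; single-pKa titration; and synthetic data that
is substitution-only by default. Each is a deliberate scope decision, and
each is the first thing to revisit when moving from synthetic to real data.
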