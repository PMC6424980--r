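---
title: "Decoding phosphorylation barcodes: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding phosphorylation barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphobarcode)
```

This vignette documents the scientific models behind each analysis stage,
the tunable parameters and their defaults, what the synthetic-data
generators do and do not emulate, and the design decisions taken where the
problem left the design open. It states no empirical result that the test
suite or the acceptance script does not itself compute.

## The system

Arrestins terminate G-protein signaling by binding activated,
phosphorylated G-protein-coupled receptors. The rhodopsin C-terminal tail
carries seven phosphorylatable Ser/Thr residues — S334, T335, T336, S338,
T340, T342, S343, always in this sequence order in this package — and the
combination of phosphates present (the phosphorylation barcode) determines
arrestin-1 affinity, C-tail release (the activation hallmark detected by
limited proteolysis) and the ability to form a ternary complex with the
activated receptor core. A `phospho_pattern` is the unit of identity: a
7-bit occupancy vector, serialized everywhere as a 7-character bitstring
such as `"0000111"`.

## Array importance: additive model + exhaustive AIC selection

Mean spot intensity for a peptide with occupancy bits $P_i$ is modeled as
$y = c + \sum_i \theta_i P_i$, with $c$ the non-specific binding
component. Replicates (default 4: duplicate spots on two independently
synthesized arrays) are averaged before fitting; responses are analyzed on
the raw intensity scale because the model is additive in intensities, not
log intensities.

All $2^7 = 128$ site subsets are fitted by OLS (intercept always
included) and scored with the Gaussian profile-likelihood AIC,
$n\ln(\mathrm{RSS}/n) + 2(|S|+1)$. Two numerical choices matter:

* **AIC variant.** The profiled-out variance parameter contributes a
  constant $+2$ across all models and is omitted; constant offsets cannot
  change rankings. Lower is better; ties are broken by smaller support,
  then lexicographic bitstring, so results are bit-for-bit deterministic.
* **Zero residuals.** Noise-free data interpolate exactly; RSS is floored
  at $\varepsilon \cdot \max(\mathrm{TSS}, 1)$ before the log so the
  criterion stays finite without perturbing any realistic comparison.

Exhaustive enumeration subsumes bidirectional stepwise selection (any
stepwise path visits a subset of the 128 models), so only the exhaustive
search is implemented; the test suite cross-checks every subset's fit
against an independent normal-equations solve.

For threshold-robustness reports a scalar per-site statistic is needed
where the primary display is a matrix; we use the standard model-averaging
choice, the Akaike-weighted mean coefficient over all 128 models
(weights $\propto e^{-\Delta\mathrm{AIC}/2}$, coefficient 0 where a site
is excluded). Thresholds that leave fewer than 9 distinct patterns (the
minimum for the 8-parameter model to be overdetermined) are reported
infeasible rather than failing the scan.

## Binding: hyperbolic titration fit vs exact occupancy

Two deliberately different equilibrium treatments are used, matching how
each assay operates:

* **Anisotropy titrations** use $r = R_0 + \Delta R\, P/(K_d + P)$ with
  total protein $P$ in place of free protein. The tracer is at 20 nM,
  three to four orders of magnitude below every $K_d$ of interest, so
  ligand depletion is negligible and the hyperbola is exact for practical
  purposes. Fitting is unweighted nonlinear least squares (no weighting
  scheme is implied by the data model); starting values come from the
  curve geometry, with a bounded (`port`) retry. The default simulated
  design is an 11-step 2-fold dilution from 500 µM plus a buffer-only
  control — the dilution factor is a convention, as only the step count
  is fixed by the assay description.
* **NMR samples** hold protein at 100 µM, comparable to both peptide and
  $K_d$, so depletion matters. Occupancy comes from the physical root of
  the 1:1 quadratic,
  $PL = \tfrac12[(P_t+L_t+K_d) - \sqrt{(P_t+L_t+K_d)^2 - 4P_tL_t}]$,
  with limits ($L_t = 0$, $K_d = 0$, $P_t \to 0$) handled analytically.
  "Saturation" is read as the fraction of *protein* bound: arrestin is
  the NMR-observed species, and under this reading a peptide at the
  250 µM detection bound gives 78.7% occupancy at the 10:1 endpoint —
  the ≈79% regime — while tighter binders sit in the high-80s to 90s.

**Censoring.** The assay cannot resolve affinities at or beyond 250 µM;
fits with $K_d \ge 250$ µM (boundary excluded from the binder class, since
binders are defined by $K_d < 250$ µM), undefined $K_d$, or a standard
error overlapping the bound without half-saturation inside the tested
range, are reported as ">250". A flat curve (no amplitude) is censored
rather than treated as an error, because $\Delta R \approx 0$ makes $K_d$
structurally unidentifiable.

## CSP analysis

The combined amide shift is
$\Delta\delta = \sqrt{(0.2\,\Delta\delta_N)^2 + (\Delta\delta_H)^2}$ —
the 0.2 weight compensates the wider ¹⁵N dispersion. Trajectories are
tracked against the ratio-0 reference by residue identifier (assigned peak
lists make positional nearest-neighbor matching unnecessary and
error-prone); unassigned peaks (`unass…`) are tracked but excluded from
classification summaries.

Design choices where the source material gives only qualitative guidance:

* **Class edges.** The magnitude scale (nonsignificant → very large) is a
  rainbow without numeric cut-offs; by default the four edges are the
  20/40/60/80th percentiles of the nonzero final shifts of non-broadened,
  assigned residues, overridable by fixed ppm values in `csp_config()`.
  A consequence: classes are relative to the dataset under analysis, so
  cross-dataset comparisons should fix the edges explicitly.
* **Broadening.** "Strong line broadening" has no stated threshold; a
  residue is flagged when its endpoint intensity falls below 0.3 of its
  reference intensity after median-normalizing each spectrum (a stand-in
  for dilution/receiver-gain correction, which the inputs do not carry).
  A peak absent from the endpoint spectrum is broadened by definition.
  The broadened flag overrides the magnitude class.

## Synthetic data: the stated world

The generators emulate the statistical structure each analysis assumes,
with explicit seeds and no hidden RNG state (the caller's stream is
restored). Where the assay description fixes a value, the default is that
value: 4 array replicates; an 11-step dilution with 20 nM tracer; NMR
ratios 0/1/4/10 at 100 µM protein. Free parameters the description does
not fix were chosen once as realistic for the field and are not tuned:

| parameter | default | rationale |
|---|---|---|
| array θ (key sites) | 900, 800 a.u. | dominant contributions, well above noise |
| array θ (secondary) | 400, 400 a.u. | intermediate tier seen in the importance display |
| array θ (others) | 50–60 a.u. | near the noise floor |
| array intercept | 500 a.u. | visible non-specific component |
| array noise SD | 100 a.u. | ~11% of a strong spot; effective SE 50 after 4 replicates |
| titration R₀ / ΔR | 0.05 / 0.10 | typical fluorescein anisotropy span |
| titration noise SD | 0.002 | plate-reader scale read noise |
| CSP residues | 160 | ≈40% backbone assignment completeness of a 404-aa protein |
| CSP dmax (¹H/¹⁵N) | 0.12 / 0.6 ppm | sub-ppm fast-exchange perturbations |
| CSP perturbed / broadened fraction | 0.30 / 0.08 | N-domain-weighted response with a minor broadened subset |

The array noise model is additive Gaussian clipped at zero — the simplest
recoverable choice. The NMR generator works in the fast-exchange limit:
observed position = free position + occupancy × bound-state change, with
occupancy from the exact quadratic; slow/intermediate exchange is
represented only by the intensity-loss flag, not by peak doubling, because
the analysis quantifies positions and flags broadening but does not model
exchange timescales. Shift noise defaults to 0 ppm so trajectories are
exactly monotone in ratio; set `shift_noise_sd` to probe robustness.

What a green test therefore establishes: that the estimators invert their
own forward models at realistic noise (support recovery, Kd within 10%
median error, occupancy/broadening recovery). What it does not establish:
robustness to features real data have and the generators lack — spatial
array artifacts, peptide synthesis yield differences, anisotropy drift,
cooperative or multi-site binding, exchange-regime crossovers, peak
overlap and assignment errors.

## The motif rules

The classifier is a pure function of the pattern. Key sites T340 and S343
are both required for tight arrestin-1 binding; the inhibitory site T342
abrogates binding only at low total phosphorylation, implemented as the
gate `phospho_count ≤ 3` — the smallest count gate consistent with the
tri-phosphorylated non-binder that carries both keys plus T342 and with
the unaffected 4P/6P/7P binders. C-tail release is predicted by the same
predicate as tight binding (the assays agree on every peptide). Ternary
complex formation is `robust` for tight binders, `moderate` when exactly
one key site is present but both secondary sites T335 and S338 are, and
`low` otherwise.

Two taxonomy ambiguities were closed as follows. T335/S338 are labeled
both "secondary" and part of the modulator region in the source material;
each site gets one primary role (`secondary`) to keep the classifier
total, with the dual membership recorded in a `modulator_region` flag.
The penta-phosphorylated peptide lacking S343 reduces but does not
abolish ternary complex formation; since it carries one key site plus both
secondary sites, the rule yields `moderate`, and the concordance
regression freezes that reading.

The packaged named-peptide panel (`inst/extdata/panel_synthetic.csv`) is a
*synthetic reconstruction*: compositions of 0P, 7P and the tri-phospho
non-binder with T342 are fixed by the assay narrative, and all other rows
satisfy the narrative's constraints (key-site membership, secondary-site
pairs, phosphate counts) but resolve the remaining freedom by choice,
recorded per row in the `source` column. Analyses that depend on exact
compositions of the reconstructed rows should treat them accordingly.

Arrestin-2 predictions are deliberately narrow: tight if both key sites
are present, plus the two documented isoform-specific exceptions (the
5P-like pattern and the T342-containing tri-phospho pattern). No general
arrestin-2 code is claimed — the data underdetermine one.

`motif_scan()` accepts declarative boolean expressions over site states
(`AND`/`OR`/`NOT`, parentheses), so externally proposed motifs can be
evaluated against any panel without code changes; spacing-style motifs
are expressed by expanding admissible placements into an `OR` of
conjunctions.

## Known limitations

* The panel reconstruction above: row-level compositions marked
  `synthetic` are constrained, not known.
* Class edges are dataset-relative by default (see above).
* The titration fitter assumes a single 1:1 site and no tracer depletion;
  both break for stoichiometric regimes, where `occupancy_exact()` is the
  right tool.
* The motif rules are trained on rhodopsin-derived peptides; transferring
  them to other receptor C-termini assumes the key/inhibitory/secondary
  spacing generalizes, which the package does not itself test.
* The AIC search is exact but the importance display inherits OLS
  collinearity behavior if a panel confounds sites (the fitter rejects
  rank-deficient designs naming the collinear columns rather than
  silently dropping them).
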