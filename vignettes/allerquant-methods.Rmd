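---
title: "Methods: quantifying ligand effects on allergen stability and processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying ligand effects on allergen stability and processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allerquant)
```

`allerquant` implements four quantitative procedures used to characterize
how hydrophobic cargo binding changes an allergen's fold stability and its
processing by endosomal proteases, plus the synthetic-data generators that
make every stage testable with known ground truth. This vignette records
the models, the parameters that matter, the numerical choices, and the
limits of what the validation suite demonstrates.

## Isotope-pair digestion quantification

### Model

Two digestion reactions are run in parallel: apo protein at natural
isotopic abundance (NA) and cargo-loaded protein uniformly labeled with
¹⁵N. Equal volumes are pooled per timepoint and measured in one MALDI
spectrum, so the two channels share all downstream sample handling and
their peak intensities are directly comparable. A peptide containing $N$
nitrogen atoms appears twice, split by

$$\Delta m = \varepsilon \, N \times 0.9970349\ \mathrm{Da},$$

where $\varepsilon \in (0, 1]$ is the isotopic enrichment (default 1) and
0.9970349 Da is the ¹⁵N–¹⁴N mass difference. The package models peak
centroids only: uniform enrichment shifts the envelope centroid by
$\varepsilon N \Delta m$, and since the instrument data are centroided
single m/z values per species, simulating full isotopologue envelopes
would add parameters without changing any reported quantity. Deisotoping,
multiple charging and PTM search are out of scope.

Masses are monoisotopic by default (average masses are available), built
as residue-mass sums plus one water plus a 1.007276 Da proton for
\[M+H\]⁺ — MALDI peptide ions are treated as singly charged. Cysteine is
treated as a free thiol (digestions are run under DTT); fixed
modifications are not applied by default.

### Candidate enumeration

Cathepsin S cleavage is broad and the experimental identification strategy
is mass matching, not cut-site prediction. Enumeration is therefore
**unspecific** by default: every contiguous substring with length in
5–40 residues and NA mass inside the m/z 800–4000 acquisition window is a
candidate. A `user_rules` hook restricts fragments to those flanked by
allowed P1 residues (termini always qualify) when a protease with known
specificity is wanted. Enumeration uses prefix sums over residue masses,
which makes peptide-concatenation additivity exact by construction; the
test suite checks it against a brute-force substring oracle on constructs
up to 30 residues.

### Pair matching

A candidate is a pair when both of its label masses match distinct peaks
within tolerance. The default tolerance is ±0.3 Da, a conservative figure
for reflector MALDI on 1–4 kDa peptides; it is configurable in Da or ppm.
Two ambiguity policies exist:

- `report_all` (default): every candidate–peak match is emitted, flagged
  `ambiguous` when a peak supports more than one candidate. This mirrors
  manual assignment practice, where the analyst resolves ambiguity.
- `nearest`: peaks are consumed greedily by the closest-mass candidate,
  so every peak supports at most one pair.

Candidates matching only one channel are reported as `na_only` or
`n15_only` rather than dropped: fragments present in the apo digestion but
absent from the loaded one are themselves a readout (cryptic cut sites).
Missing partners in a ratio time-course are explicit censored entries,
never zero-imputed — a zero denominator would fabricate infinite ratios.
Ratios are intra-spectrum intensity quotients; no cross-timepoint
normalization is applied because each pooled spectrum is internally
comparable and the ratio cancels shared factors. Whether the intensity
column is peak height or area is left to the caller; the package ratios
whatever quantity it is given.

### Coordinates

Fragment intervals are 1-based inclusive and construct-relative
everywhere; the construct's `numbering_offset` (34 for a 34–216
construct) converts to full-protein numbering on output. The literature
position "residues 23–31" for the 981.6/991.6 epitope fragment is read as
construct-relative: with offset 34 it maps to full-protein 56–64, which is
the only reading that places it inside the expressed region. Residual
expression-tag residues are assumed absent after tag cleavage.

### The synthetic stand-in construct

The construct sequence itself is external reference data that the package
cannot ship: the repository therefore carries a clearly labelled
*synthetic* 183-residue stand-in whose positions 23–31 were designed (by
searching amino-acid compositions against an independent mass calculator)
to carry 10 nitrogens and a monoisotopic \[M+H\]⁺ of 981.61 Da, so the
documented 981.6/991.6 isotope pair is reproduced to one decimal. All
sequence-independent behaviour (matching, kinetics, censoring, mapping) is
unaffected by the stand-in; mass values for other fragments are not
meaningful for the real protein, and users analysing real data should
supply the real FASTA.

## Epitope overlap

T-cell epitope intervals are user-supplied in full-protein numbering (the
published epitope coordinates are not reproduced here; the shipped TSV is
a synthetic fixture documenting the schema). Overlap is computed with
`IRanges` after offset conversion; one row per (fragment, epitope) pair
with at least one shared residue, reporting the intersection size and the
fraction of the fragment covered. Adjacent intervals do not overlap under
inclusive coordinates.

## Thermal melt analysis

### Model and the 25% melting temperature

Melt curves are fit by least squares to a two-state Boltzmann:

$$s(T) = b_f(T) + \left[b_u(T) - b_f(T)\right] f(T), \qquad
f(T) = \frac{1}{1 + e^{(T_{1/2} - T)/w}},$$

with $f$ the fraction denatured, $T_{1/2}$ the midpoint (°C) and $w > 0$
the width (°C). Baselines are fitted, not taken from endpoint averages;
they are constant by default with a linear option for sloped baselines.
The reported melting temperature is the temperature of **25%**
denaturation,

$$T_{M25} = T_{1/2} - w \ln 3,$$

used instead of the conventional 50% midpoint because strongly stabilized
samples may not reach 50% denaturation within the measurable range at all.
Because $T_{M25}$ is defined on the fitted fraction denatured, it is
invariant to affine rescaling of the signal axis.

### Numerical choices

Fits use Levenberg–Marquardt (`minpack.lm::nlsLM`) from a deterministic
multi-start grid: eight $T_{1/2}$ starting values spanning the observed
temperature range crossed with three width scales (range/20, range/10,
range/5), keeping the lowest-RSS converged fit — so results are exactly
reproducible. The width is bounded below at 10⁻³ °C. A fit needs more
points than parameters and at least 8 points with strictly increasing
temperatures.

Censoring uses the fitted model, not the noisy last datum: when
$f(T_{\max}) < 0.25$, $T_{M25}$ is reported as "> $T_{\max}$". Censoring
propagates through $\Delta T_M$: a censored sample gives a lower bound on
the stabilization, a censored reference an upper bound, and two censored
fits an undefined, flagged result. Thermodynamic quantities (ΔH, ΔG) and
reversibility analysis are out of scope.

## Proteolysis kinetics

Substrate band fractions from SDS-PAGE densitometry (normalized to the
t = 0 band, so raw gel units cancel) are converted to initial rates
$(1 - \text{fraction})/t$ averaged over the sampled timepoints — an
initial-rate approximation matching short (≤ 60 min) linear-range
sampling; no exponential is fitted. Rates are regressed on substrate
concentration **through the origin** (a true proteolysis rate is zero at
zero substrate), giving a slope in min⁻¹·µM⁻¹. The uncentered r² of that
fit diagnoses the linear range (default threshold 0.9): saturating,
concentration-independent rates fit an origin line poorly and fail the
check, flagging that rate differences may no longer reflect catalytic
turnover. Relative proteolysis is the sample slope divided by the apo
slope; apo vs itself is 1 by construction and zero slope (no detectable
cleavage, the long-chain cargo limit) gives 0. The input contract is
substrate-loss fractions; product-appearance densitometry would need
conversion upstream.

## Binding stoichiometry

A linear standard curve (ordinary least squares, intercept fitted by
default since baseline signal is plausible; a through-origin option
exists) converts replicate sample intensities to lipid concentrations,
$(I - b)/a$, which divided by the protein concentration give lipids per
protein. Replicates are aggregated at the ratio level (mean, n−1 sd),
matching a three-independent-trials design. Intensities below the fitted
intercept imply negative concentrations and are excluded with a warning.
The estimate is invariant to any common rescaling of curve and sample
intensities.

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of its configuration and seed.

**Digestion experiments.** Each true fragment appears with first-order
kinetics: NA intensity $A(1 - e^{-kt})$, ¹⁵N intensity
$A(1 - e^{-\rho k t})$, so the noiseless pair ratio is
$R(t) = (1 - e^{-\rho k t})/(1 - e^{-kt})$ — near $\rho$ early,
approaching 1 from below, and non-decreasing. First-order appearance is
the minimal model consistent with the observed time-course shape (early
suppression of the loaded channel, late convergence); it is a modeling
choice, not a measured mechanism. Defaults encode the study design:
20 paired plus 6 NA-only fragments drawn from the candidate space with
label masses ≥ 2.5 Da apart (so noiseless matching is unambiguous),
$\rho = 0.7$ (loaded digestion 30% slower, giving a 20–40% ¹⁵N abundance
deficit mid-course), $k = 0.002$ min⁻¹ (placing the 4 h pooled spectrum
mid-course and leaving a small residual difference at 24 h), six
timepoints from 30 min to 24 h, 0.05 Da m/z jitter, 5% lognormal
intensity noise (lognormal for positivity, parameterized by CV) and 10
uniform decoy peaks per spectrum. What is *not* emulated: isotopologue
envelopes, detector saturation, baseline/chemical noise structure,
correlated intensity drift between channels, and real cathepsin S
site preferences — so passing tests demonstrate correctness of the
quantification given centroided, internally comparable peak lists, not
robustness to every instrumental artifact.

**Melt curves** are Boltzmann signals on a 25–95 °C grid (the standard
acquisition range) with multiplicative Gaussian noise; default baselines
mimic negative 222 nm ellipticity shrinking in magnitude on unfolding.

**Densitometry** applies multiplicative noise to the loss term and clamps
band fractions to \[0, 1\]. The default true slope, 10⁻⁴ min⁻¹·µM⁻¹,
keeps all points of the 5–75 µM × 30/60 min design inside the linear
range (maximum loss 0.45); a much larger slope would saturate the highest
concentration within the first timepoint and no slope could be recovered —
the generator emulates an assay operated, as designed, in its linear
range.

**Standard series** produce noisy linear standards spanning 2–12 mM plus
replicate sample intensities implied by a true stoichiometry (default 4.7
lipids per protein at 2 mM protein, three replicates).

## Validation problem sizes

The test suite validates each stage by closed loop (noiseless input →
exact ground-truth recovery, e.g. pair precision = recall = 1 and ratios
matching the closed form to 10⁻⁹) and by parameter recovery under noise:
200 digestion replicates at 5% intensity noise and 0.05 Da jitter (median
ratio error), 100 melt curves at 1% CV (mean $T_{M25}$ recovery within
0.5 °C), 200 kinetics replicates at 5% noise (mean relative rate within
10% of $\rho$), and 500 stoichiometry replicates at 5% noise (mean within
3% of truth). An independent ODE integration (`deSolve`) cross-checks the
kinetic ratio law. These sizes give stable Monte-Carlo summaries while
keeping the default suite fast.

## Known limitations

- Peak picking, recalibration and profile-spectrum processing are
  upstream; inputs must be centroided.
- Matching assumes the candidate space contains the true fragments; a
  fragment with an unanticipated modification will surface only as an
  unassigned peak.
- The statistical layer is deliberately descriptive (means, censor
  counts); no inferential testing of ratio differences is provided.
- The shipped construct and epitope files are synthetic stand-ins for
  reference data that cannot be redistributed here; quantitative mass
  values on the stand-in sequence apply to that sequence only.
- The orchestration layer is the exported function
  `run_quantified_digest()` plus the per-stage functions; there is no
  shell executable, as the intended interface is the R session.
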