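---
title: "Semi-orthogonal scoring of noncanonical DNA motifs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-orthogonal scoring of noncanonical DNA motifs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadscan)
```

## The projection model and the Qs score

quadscan represents a DNA strand as a sequence of signed heights on a
single projection axis.  The four bases are pictured as vectors of equal
magnitude $A_0$ standing on a base line: the complementary pair G/C spans
one plane ($\sigma$), the pair A/T a second plane ($\rho$) inclined
towards the first.  With $\psi$ the inclination from orthogonality (so
the planes subtend $\alpha = 90^\circ - \psi$), the projections onto the
$\sigma$ axis are

$$h_G = +A_0, \quad h_C = -A_0, \quad h_T = +A_0\sin\psi, \quad
  h_A = -A_0\sin\psi,$$

with $A_0 = 3$ by default.  Two structural facts are encoded here.
First, the height of every base is the exact negative of the height of
its complement; consequently the score defined below flips sign under
reverse complementation, which is what lets one scan detect G-rich
(quadruplex-forming) candidates on either strand and C-rich (i-motif)
candidates as their mirror image.  Second, at $\psi = 0$ the planes are
orthogonal and A/T project to zero: sequences differing only in their
A/T content become indistinguishable.  That degeneracy is exactly the
blind spot of run-length scoring schemes for G-rich sequences, and a
non-zero $\psi$ is what removes it: at the default $\psi = 30^\circ$
($\alpha = 60^\circ$, the setting at which the prediction thresholds are
defined) G$_3$T$_3$-type and G$_3$A$_3$-type repeats separate cleanly,
as `qs_score()` shows.

Joining the vector endpoints $(i, h_i)$ by a polyline, the **Qs score**
of a sequence of length $n$ is the signed trapezoid area under that
polyline divided by the number of nucleotides:

$$Q_s = \frac{1}{n}\sum_{i=1}^{n-1}\frac{h_i + h_{i+1}}{2}.$$

The polyline spans positions $1..n$ only — it is not closed to zero
height at either end — so a G homopolymer attains the supremum
$A_0(n-1)/n$, and the score of a fixed repeat grows slowly towards its
asymptote with repeat count.  Sequences of length 0 or 1 subtend no area
and score 0.  Three exact identities follow from the definition and are
enforced as property tests: reversal invariance, complement antisymmetry
($Q_s(\mathrm{revcomp}) = -Q_s$), and the linear decomposition
$Q_s(\psi) = Q_{s,GC} + \sin\psi\, Q_{s,AT}$, which separates the fixed
G/C contribution from the $\psi$-scaled A/T contribution.  An
independent shoelace polygon-area computation serves as the oracle for
the trapezoid sum.

### Calibration of the height model

The magnitudes and signs above are a calibration, fixed once before any
other code was written.  Three features are forced by the reference
panel of scored oligonucleotides that the package reproduces (nine
sequences — four (GT)$_n$ and four (GA)$_n$ repeat lengths plus a
31-nt GGGAGCGA-repeat reference — each scored at $\psi = 15^\circ$ and
$30^\circ$):

* **T positive, A negative.** (GT)$_n$ scores rise with $\psi$ while
  (GA)$_n$ scores fall; with the opposite signs both would move together.
* **Signed, not absolute, area.** The GGGAGCGA-repeat sequence contains
  four C residues; only if C contributes negatively do its scores
  (1.28 and 1.11) come out right.  The same sequence rules out any
  G-run-length weighting.
* **Open endpoints.** The $(n-1)/n$ length trend across the repeat
  series matches the printed values only if the polyline is not closed
  to the axis.

With $A_0 = 3$ all eighteen panel values reproduce within $\pm 0.015$ of
their 2-decimal print; the two largest deviations (2.1875 vs 2.18 and
2.2083 vs 2.20 for the two longest (GT)$_n$ rows at $30^\circ$) are one
final-digit unit and consistent with truncation rather than rounding of
the reference values, so the test tolerance $\pm 0.015$ covers either
convention.

### Score bands

`classify_qs()` maps a score at $\psi = 30^\circ$ to a structural
prediction:

| band | label |
|---|---|
| $Q_s > 2$ | `ZG4_prone` |
| $1.2 < Q_s \le 2$ | `G4_candidate` |
| $0.7 \le Q_s \le 1.2$ | `tetrahelix_band` |
| $Q_s < -1.2$ | `imotif_candidate` |
| otherwise | `none` |

1.2 is the quadruplex-formation threshold; scores above 2 are
characteristic of dinucleotide repeats that adopt left-handed (Z-form)
quadruplexes under molecular crowding.  The tetrahelical band collects
sequences just below the quadruplex threshold — the (GA)$_n$ repeats
proposed to stack AGAG-quartets, and the GGGAGCGA-repeat reference
structure.  Two design choices deserve a note.  The band's upper edge is
set at the quadruplex threshold itself rather than at 1.1: the band is
nominally described as 0.7–1.1 because its known members print as
0.71–1.11 at two decimals, but its reference sequence scores 1.113
unrounded, so a literal 1.1 edge would exclude the very sequence that
defines the band.  Every score at or above 0.7 that does not clear 1.2
is therefore banded, which leaves no unclassified gap below the
threshold.  The i-motif rule is the package's mirror construction: no
negative threshold is separately established, and complement
antisymmetry makes $-1.2$ the only non-arbitrary choice.  The lower
band edge matters in practice: a (GA)$_6$ oligo scores 0.6875 and is
deliberately left out of the band (it is observed to stay unfolded),
while (GA)$_9$ at 0.7083 is in.

## Scanner semantics

`scan_sequence()` applies the score over sliding windows (default 25 nt,
step 1) at 0-based half-open coordinates, scoring a shorter-than-window
sequence as one whole-sequence window.  Trailing partial windows are
skipped by default because the $(n-1)/n$ factor biases short windows
low; `include_partial = TRUE` restores them.  The implementation
accumulates the trapezoid half-sums once, so a scan is linear in
sequence length regardless of step.

`call_intervals()` emits plus-strand calls at $Q_s \ge$ threshold and
minus-strand calls at $Q_s \le -$threshold, merging overlapping
same-strand windows into maximal intervals that retain the extremal
window score.  Scanning a reverse complement yields the same call set
with strands swapped and coordinates remapped — a property test, since
it follows from the height antisymmetry.

One quantitative limit is worth stating because it governs what a scan
can find: a window of size $w$ containing a repeat tract of length
$\ell < w$ dilutes the tract's trapezoid sum over $w$ positions.  A
(GT)$_8$ tract (16 nt) inside a 25-nt window contributes at most
$2.25 \times 15 = 33.75$ to the window sum, while `ZG4_prone` requires
a sum above $2w = 50$; over a random background such a tract can
therefore never reach the Z-G4 band at the default window.  Only tracts
spanning a full window (13 or more GT repeats at $w = 25$) are
guaranteed Z-G4-level calls; shorter qualifying tracts (8–12 repeats)
are still recovered, but as `G4_candidate`-level intervals at the 1.2
threshold.  The spike-recovery tests use tract lengths of 13, 18 and 27
repeats for the Z-G4 recall claim for exactly this reason.  Choose the
window to match the shortest tract you need at full scoring strength.

## Repeat-tract finding

`find_dinucleotide_repeats()` reports maximal tracts of a two-base unit
(defaults GT and GA).  A tract is found as a maximal alternating run of
the two bases; within a run the phase (GT vs TG) with more complete
units wins, ties preferring the unit as given, so the reported `count`
is the full-unit count, coordinates span complete units only, and a
dangling half unit is flagged rather than counted.
Reverse-complement tracts (an AC-repeat is a GT-repeat on the other
strand) are reported with `strand = "-"` in plus-strand coordinates.
The default `min_repeats = 6` with a `confident` tier at 8 encodes the
empirical six-to-eight-repeat critical range for these repeats to adopt
noncanonical motifs: six repeats are reliably below the folding limit,
eight or more reliably above, so tracts of 6–7 are reported but not
flagged confident.  A regex enumeration is the independent oracle in the
tests.

## Two-state melting analysis

`fit_two_state()` implements the standard van't Hoff two-state reading
of a melting curve.  With $T$ in Kelvin, molecularity 1, and the
mid-point convention $\Delta S = \Delta H / T_m$,

$$K(T) = \exp\!\left[-\frac{\Delta H}{R}\left(\frac{1}{T} -
 \frac{1}{T_m}\right)\right], \qquad \theta(T) = \frac{K}{1+K},$$

so the fraction folded $\theta$ is exactly $1/2$ at $T_m$ for any
$\Delta H$.  The observed signal is modelled with linear folded and
unfolded baselines,

$$S(T) = (b_f + m_f T)\,\theta(T) + (b_u + m_u T)\,(1 - \theta(T)),$$

and all six parameters ($T_m$, $\Delta H$, four baseline coefficients)
are fit by Levenberg–Marquardt least squares.  $\Delta H$ is the
apparent (van't Hoff) enthalpy, in kJ/mol, negative for a structure
written folded $\to$ unfolded; the free energy at a reference
temperature (default 0 °C, a conventional comparison point for these
motifs) follows as $\Delta G(T_{ref}) = \Delta H (1 - T_{ref}/T_m)$ and
is negative when folding is favored there.  Temperatures are Celsius at
every interface and Kelvin internally.  Heating-rate effects and
hysteresis are outside the model; the heating rate is carried as
metadata only.

Choices made where the analysis was genuinely open:

* **Molecularity.** Intramolecular (1) is the default.  Because some of
  the motifs motivating this module are plausibly multimeric, a
  `molecularity` argument generalizes the equilibrium to
  $K \cdot m (1-\theta)^m = \theta$ in reduced-concentration units,
  referenced so that $\theta(T_m) = 1/2$; strand-concentration
  dependence is deliberately not modelled, since reported mid-points
  rarely come with the concentrations needed to resolve it.
* **Baselines float.** All four baseline coefficients are free
  parameters, initialized from straight-line fits to the outer 15% of
  points on each side.  A common linear drift added to a whole curve
  consequently shifts the fitted $T_m$ by less than 0.2 °C (tested).
* **Initialization.** $T_m$ starts at the derivative estimate below,
  falling back to the steepest-difference temperature; $\Delta H$ starts
  at $-200$ kJ/mol, a mid-range value for these transitions.  Bounds
  keep $T_m$ in 200–500 K and $\Delta H$ negative.  Non-convergence is
  an explicit error carrying the starting values; a fitted $T_m$
  outside the measured range sets `in_range = FALSE` with a warning.

`tm_from_derivative()` provides the independent, model-free estimate:
the temperature of the extremal first derivative after Savitzky–Golay
smoothing (default cubic, 21-point window, shrunk for short curves),
with the grid argmax refined by the vertex of a quadratic fitted over
the peak's half-height region.  Non-uniform grids are linearly resampled
first.  A curve with no transition must fail rather than return a
number: the peak must exceed `prominence` (default 5) times the
derivative-level noise, where the noise is estimated from high-frequency
successive differences of the raw signal propagated through the central
derivative kernel — a flat or purely drifting curve has a constant
derivative and is rejected, with the peak search confined to the grid
interior because the filter's asymmetric edge kernels inflate variance
there.  One systematic limit, verified numerically in development: the
derivative extremum of a van't Hoff sigmoid sits slightly *below*
$T_m$ (the $1/T^2$ factor skews $d\theta/dT$), by under 0.2 °C for
$\Delta H = -350$ kJ/mol but by $\approx 0.8$ °C for a broad
$-100$ kJ/mol transition even without noise.  The derivative estimate
and the fit therefore agree within 1 °C only for sharp transitions;
for broad ones the fit is the better estimator and the derivative value
should be treated as an initializer.

## Synthetic data: what it emulates and what it does not

The generators in this package are first-class, tested code, and every
claim the test suite makes is made against them.

* `make_repeat_oligo()` reconstructs the repeat oligonucleotides of the
  reference panel exactly.
* `make_random_genome()` draws i.i.d. bases at a configurable GC
  fraction (default 0.5; G and C equiprobable, likewise A and T).  GC
  content is exposed because the null distribution of window scores
  depends on it.
* `make_spiked_genome()` plants known tracts at stated offsets in such a
  background and emits a BED-like truth table, giving scanner recall and
  false-positive tests a ground truth that is forced by construction.
* `simulate_melt()` generates the exact two-state signal plus seeded
  Gaussian noise whose standard deviation is a stated fraction of the
  folded–unfolded amplitude at $T_m$.

All generators run under a fixed Mersenne–Twister seed, restore the
caller's RNG state, and are byte-identical across runs.  What the
synthetic background does **not** emulate: real genomic base
composition (isochores, CpG suppression), the heavy-tailed length
distribution of real microsatellites, or correlated instrument noise
and hysteresis in melting curves.  A perfect recall number on spiked
genomes therefore demonstrates the scanner's correctness, not its
genomic precision–recall tradeoff; and parameter-recovery statistics on
simulated curves bound estimator error under the stated noise model
only.

## Problem sizes and numerical tolerances

The test suite exercises: the full 18-value reference panel; 1,000
random sequences (2–60 nt) for the property and oracle suites; five
spiked and twenty null 10-kb genomes at window 25, step 1, for recall
and false-positive checks; and a 3 × 3 grid of simulated melting curves
($T_m \in \{40, 55, 70\}$ °C, $\Delta H \in \{-100, -200, -350\}$
kJ/mol, 201 points, 1% noise) for parameter recovery — sizes chosen so
the whole suite completes in well under a minute while every claim
remains statistically meaningful.  Exact identities are asserted to
1e-10–1e-12; panel reproduction to $\pm 0.015$ as derived above;
recovery medians to 0.5 °C in $T_m$ and 5% in $\Delta H$ at 1% noise.

## Known limitations

* The score is the 1-D projection onto the G/C axis; the A/T-axis
  profile is not used independently, so motifs defined by A/T-rich
  patterns (e.g. cruciform-extruding palindromes) are out of scope.
* Band classification is defined at $\psi = 30^\circ$ only; scores at
  other angles are reported but not banded.
* The classifier predicts propensity, not folding: band membership says
  a sequence scores like known formers, and the melting module exists
  precisely because that prediction needs experimental confirmation.
* RNA input is scored as its DNA analog (U mapped to T); structural
  differences between r(UG) and d(TG) repeats are not modelled.
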