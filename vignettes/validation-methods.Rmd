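---
title: "How ciflint validates a crystal-structure archive"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How ciflint validates a crystal-structure archive}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciflint)
```

## What the toolkit checks, and why

A small-molecule crystal-structure archive couples three layers of
information: the crystal data and refined model (CIF), the final observed
and calculated intensities (FCF), and, increasingly, the raw unmerged
reflection file and refinement instructions embedded inside the CIF with
checksums. Each layer over-determines the others, and that redundancy is
what makes automated validation possible: the density implied by the model
can be compared with the density implied by the data, reported agreement
statistics can be recomputed from the archived reflections, and the
reported symmetry can be tested both against the atomic coordinates and
against the intensity pattern.

`ciflint` re-derives everything it can and reports discrepancies as
levelled alerts — A (serious), B, C (check), G (informative). Alerts are
pointers, not verdicts: a short contact may be a genuine structural
feature, and a proposed higher symmetry may be deliberate pseudo-symmetry.
The toolkit therefore never auto-fixes anything; it reports the evidence
(fit fractions, tolerances, suggested translations or twin laws) so a
human can decide.

## The symmetry engine

All symmetry work rests on exact integer arithmetic: an operator is a
3x3 integer rotation part and a translation stored in twelfths of a cell
edge, so group closure, systematic-absence conditions and site-symmetry
counts involve no floating-point tolerance at all. Hall symbols are
decoded to generators (lattice letter, optional inversion, rotation fields
with the implied-axis rules, origin shift) and closed under composition; a
bundled table of the 230 standard settings plus common alternate settings
(cell and origin choices, rhombohedral/hexagonal axes) links Hall and
Hermann-Mauguin symbols.

The crystal system is always derived from the operator set — by counting
rotation orders of the proper point group — and never inferred from the
metric; the metric is only *checked* against the system, with tolerance
`max(3*su, 0.002 A / 0.02 deg)`. This ordering matters: a monoclinic cell
with beta accidentally near 90 degrees must not be promoted to
orthorhombic by a metric argument alone.

Site symmetry is counted geometrically: `sso` is the number of operators
mapping a site onto itself within 0.01 Angstrom (Cartesian, modulo
lattice translations), the multiplicity is `nsym/sso`, and the
refinement-style site occupancy factor is `occupancy/sso` — hence the
textbook value of 0.5 for a fully occupied atom on an inversion centre of
a four-operator group.

## Reflection statistics

Equivalents are merged under the Laue group by inverse-variance weighting;
`Rint = sum|Fo2 - <Fo2>| / sum Fo2` over multiply measured groups. The
weighted residuals use the established two-parameter scheme
`w = 1/[sigma^2 + (aP)^2 + bP]`, `P = (max(Fo2,0) + 2 Fc2)/3`; the
clamping of negative observed intensities inside `P` (and `|Fo| = 0` in
R1) is deliberate and tested. R1 uses the `I > 2 sigma(I)` observed
criterion by default; the criterion is configurable because upstream
conventions differ, and the report always states which was used.

Three R-value sets are compared: one from the embedded unmerged data
(merged by `ciflint`, with calculated intensities from the archived
model), one from the FCF as given, and the reported values. On an
internally consistent archive all three agree to the printed precision.

The analysis of variance uses ten equal-population resolution bins and
fixed `Fc/Fc(max)` bin edges (0, 0.1, 0.2, 0.4, 0.6, 0.8, 1); the axes
are conventional, the edges are this package's choice. Bins with scale
factor `K = <Fo2>/<Fc2>` outside [0.8, 1.2] or a bin goodness of fit
above 2 are flagged. The normal-probability statistic fits a line through
the central 80% of the ordered weighted residuals; the reported S-shape
metric is the maximum central deviation from that line.

The absolute-structure estimate is a Parsons-style quotient fit:
observed Bijvoet quotients `q_o = (I+ - I-)/(I+ + I-)` are regressed on
the calculated quotients of the untwinned model via `q_o = (1 - 2x) q_c`,
weighted by first-order-propagated variances; pairs with `|q_c| < 1e-4`
carry no signal and are dropped. The Bayesian (Hooft-style) treatment is
intentionally not implemented, and the report labels the estimate
accordingly to avoid conflation. An estimate above 0.5 means the model
should be inverted; an estimate within two standard uncertainties of 0.5
is reported as indeterminate.

The fabrication screen exploits a simple observation: genuinely estimated
uncertainties scatter about any smooth function of intensity, while
invented ones are often an exact function of it. A quadratic fit of
`sigma^2` against `I` with `R^2 > 0.9999` and relative residuals below
0.1% is reported as suspicious — a screening signal for a human, never
proof.

## Difference maps and voids

The difference map is the Fc-phased `|Fo| - |Fc|` synthesis, evaluated by
FFT after expanding the unique reflections over the space group and
completing Friedel mates; the F(000) term is excluded, so the mean is
exactly zero, and the FFT agrees with direct Fourier summation to 1e-8 on
small coefficient sets (a standing test). A well-behaved refinement gives
excursions within about +/-0.5 e/A^3; grading into C/B/A at 0.5/1.0/1.5
is this package's rule, with excursions within 1 Angstrom of an atom of
Z >= 20 reported separately as probable absorption artefacts. On-atom
density above 0.5 e/A^3 flags a possible atom-type error (a one-electron
mistake produces roughly 0.9 at copper-sphere resolution on the synthetic
fixtures). Hydrogen sites are tested directly: below -0.2 e/A^3 in the
as-is map a hydrogen is sitting where density had to be removed.

Void detection marks every voxel within `r_vdw + probe` of any
symmetry-expanded atom (probe 1.2 Angstrom, grid 0.2 Angstrom, both
configurable and echoed in the report) and clusters the free voxels under
periodic 6-connectivity; regions below 20 A^3 are suppressed but counted.
Only detection and electron-count integration are implemented — the full
solvent-contribution iteration, and its resonant-scattering refinement,
are out of scope by design. Integrated electron counts are
truncation-limited: at a 0.65 1/A cutoff an omitted oxygen integrates to
its 8 electrons only within about 15%.

## Missed symmetry and twinning

The coordinate search enumerates all metric-compatible integer
involutions (translations, inversion, two-folds and mirrors along axes
and diagonals), harvests candidate translations from atom-pair difference
vectors, and accepts an operation when at least 85% of the eligible atoms
map onto an atom within 0.45 Angstrom (both thresholds configurable and
echoed). Hydrogens and disordered atoms are excluded, and element
identity is ignored by default so C/N-type mis-assignments are still
caught. When the found operation closes to a tabulated group, the report
names it and counts extinction violations of the archived data under the
proposed group as corroboration. Full Niggli-reduction-based lattice
hunting (sub/supercells) is deliberately out of scope and the report does
not claim it.

Twin detection follows the rotation-overlap principle: outliers with
`Fo2 >> Fc2` are tested against two-fold rotations about low-index direct
and reciprocal rows (indices up to 2, lattice-integrality within 0.05);
a law explaining at least 60% of outliers is scored by golden-section
refinement of the twin fraction minimizing R1 of the two-component
intensity model on [0, 0.5], and the R1 drop is reported. The estimated
drop is this package's approximation, not a reproduction of any upstream
convention. Detection is defeated by data from which the deviating
reflections were already removed — the report says so when the outlier
count is too small to assess.

## The synthetic-data generator

The generator is first-class code, not a test hack: it builds a random
connected molecule (jittered tetrahedral walk), packs it into the
requested space group by trying orientations and shrinking the cell axis
by axis until symmetry images sit just inside van der Waals contact
(margin -0.1 Angstrom, above the -0.2 contact-alert threshold, as real
crystals do), and fills residual solvent-accessible pockets with
solvent-like oxygen atoms — mimicking a solvate — so the reference
structure is genuinely alert-free. Exact spherical-atom structure factors
use the bundled four-Gaussian coefficients with f'/f'' at Cu and Mo
K-alpha.

The noise model is declared because detection thresholds reference it:
`sigma^2 = sigma0^2 + k I` with `sigma0 = 1`, `k = 0.02`, Gaussian
perturbation of intensities, and lognormal estimation scatter (15%) on
the *reported* sigmas — without that scatter, honest data would be
indistinguishable from fabricated data under the smoothness screen.
Corruptions (edited payloads, wrong atom type, misplaced hydrogen,
stripped inversion, twinning, inversion twinning, fabricated sigmas,
inflated low-order data) each trigger exactly their intended check in a
standing corruption-by-rule test matrix.

What passing these tests shows — and what it does not: the fixtures
contain no bonding density (spherical atoms), no absorption surface, no
thermal diffuse scattering, no realistic disorder. They validate the
machinery (algebra, statistics, map synthesis, search logic), not the
empirical thresholds' behaviour on real diffraction data, whose noise is
richer than the declared model.

## Numerical choices and problem sizes

Translations are exact twelfths; operator closure is integer arithmetic
capped at order 192. Degenerate inputs are handled explicitly: empty
reflection sets, missing columns and unparsable values raise typed errors
at module boundaries but become missing-data alerts inside the
orchestrator, which never lets one failed stage abort the rest. Bit-equal
rendering of the text report for identical inputs is a standing test.

The test suite runs structures of 6-12 atoms in cells of 700-1300 A^3 at
a 0.65 1/A resolution cutoff (roughly 2,000-5,000 unique reflections,
20,000 unmerged measurements), chosen so each simulation carries enough
signal for parameter-recovery checks (twin fractions to within 0.05,
absolute-structure fractions to within three standard uncertainties)
while the whole suite stays comfortably within a routine CI budget.

## Known limitations

CIF 1.1 only (CIF2/DDLm syntax is rejected with a clear error); no
dictionary-level vocabulary validation. The embedded-payload checksum
convention of the original ecosystem is undocumented, so `ciflint` ships
its own documented reference algorithm, applies it end-to-end to its own
archives, and caps checksum-mismatch alerts at C level for foreign files.
No magnetic or superspace groups; no powder, electron-diffraction or
non-spherical-atom (Hirshfeld-atom) refinement models; no refinement at
all — `ciflint` evaluates models, it never adjusts them.
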