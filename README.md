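# ciflint

Validation of small-molecule crystal-structure archives, in R.

A published crystal structure is archived as a CIF (cell, symmetry,
refined model, agreement statistics), usually together with the final
reflection data (FCF) and, in modern archives, the raw unmerged
reflection file and refinement instructions embedded in the CIF with
checksums. These layers over-determine each other, and `ciflint` exploits
that redundancy: it re-derives everything it can from the archive and
reports discrepancies as levelled alerts (A = serious, B, C = check,
G = informative), in the tradition of automated structure validation.

What it recomputes and checks:

- **Symmetry** — Hall symbols are expanded to full operator groups by
  exact integer arithmetic (translations in twelfths); Hermann–Mauguin
  symbol, Hall symbol, operator loop, crystal system and cell metric are
  cross-checked; site-symmetry order, multiplicity (`sso·ssm = nsym`) and
  occupancy/SOF bookkeeping (`SOF = occupancy/sso`) are verified; ORTEP
  style `s_uvw` symmetry codes are encoded/decoded (digit = translation
  + 5, range −5..4).
- **Reflection statistics** — merging and R<sub>int</sub>, completeness
  per resolution shell (data are expected complete to s = sin θ/λ =
  0.6 Å⁻¹; the copper-sphere limit is 1/1.5418 = 0.65 Å⁻¹, i.e. θ =
  27.5° for Mo Kα, d = 0.77 Å), the two-parameter weighting scheme
  w = 1/[σ²(F<sub>o</sub>²) + (aP)² + bP], R1/wR2/goodness-of-fit
  recomputed three ways (from embedded data, from the FCF, as reported),
  analysis of variance (bin scale K and bin GooF), normal-probability
  statistics, a Parsons-style Bijvoet-quotient estimate of the absolute
  structure fraction x (invert when x > 0.5), and a fabricated-data
  screen (σ(I) an implausibly exact function of I).
- **Model** — formula/Z/M<sub>r</sub>/density arithmetic (with the
  `[+solvent]` bracket rule), Hirshfeld rigid-bond test on the ADPs,
  covalent connectivity, short intermolecular contacts classified
  (H⋯H, O⋯O/O⋯N missing-hydrogen, halogen⋯halogen informational),
  centre-of-gravity rule with the small-species exemption, transmission
  range vs crystal size, data-to-parameter ratio, resonant scattering
  factors against bundled tables.
- **Density** — F<sub>c</sub>-phased |F<sub>o</sub>|−F<sub>c</sub>
  difference maps by FFT (featureless bound ±0.5 e Å⁻³), density on atom
  sites (wrong atom type), hydrogen-site support, solvent-accessible
  voids with integrated electron counts.
- **Missed symmetry and twinning** — an ADDSYM-style coordinate search
  over metric-compatible involutions (default 0.45 Å, 15% non-fit
  allowed) with reflection corroboration, and a TwinRotMat-style search
  for two-fold twin laws explaining I<sub>obs</sub> ≫ I<sub>calc</sub>
  outliers, with twin-fraction and R1-drop estimates and HKLF5 export.

Everything is exercised by a synthetic-structure generator that produces
internally consistent archives — and deliberately corrupted variants —
so no external data are needed.

## Worked example

```r
library(ciflint)
m      <- generate_structure(n_atoms = 8, n_h = 2, seed = 7)  # P2_1/c fixture
ds     <- make_dataset(m, seed = 7)                            # noisy data to 0.65 1/A
report <- run_validation(model_to_cif(m, ds))
print(report)
```

```
ciflint validation report
tolerances: addsym 0.45 A / 15% non-fit, probe 1.20 A, grid 0.20 A, contact slack 0.20 A

== data_I ==
cell: a=9.9800 b=11.7112 c=9.1653 alpha=90.000 beta=103.000 gamma=90.000 V=1043.76
symmetry: HM: P 1 21/c 1  Hall: -P 2ybc  nsym: 4
                 R1     wR2      S
from embedded  0.0143  0.0108  1.078
from fcf       0.0143  0.0108  1.078
reported       0.0143  0.0108  1.078
Rint (refold of archived data): 0.0153
difference map range: -0.054 to 0.051 e/A^3
alerts: 2 (A:0 B:0 C:0 G:2)
ALERT 0007 G 2 hydrogen atom(s) on calculated (riding) positions
ALERT 0978 G mean difference density at bond midpoints -0.000 e/A^3
```

The three R-value rows agree because the archive is self-consistent: the
first is recomputed from the embedded unmerged reflection payload (merged
by `ciflint`, calculated intensities from the archived model), the second
from the reflection loop as given, the third as reported in the CIF.
R<sub>int</sub> = 0.015 reflects the generator's declared noise model,
the difference map is featureless (|ρ| < 0.06 e Å⁻³ against the ±0.5
bound), and only informative G-level notes remain — riding hydrogens, and
the bond-midpoint density measure, which is zero here because the
synthetic data contain spherical atoms only.

Corrupt the archive and the corresponding check fires; for example, a
structure whose inversion centre was deliberately dropped:

```r
ms <- ciflint:::corrupt_model(m, "strip_inversion")
run_validation(model_to_cif(ms, make_dataset(ms, seed = 7)))
#> ALERT 9048 A inversion centre at (0.000, 0.000, 0.000) fits 100% of atoms
#>              (tol 0.45 A); implied group: -P 2ybc
```

A shell entry point with the same behaviour (exit 0 = clean, 1 = A-level
alerts, 2 = cannot validate) is installed at `exec/ciflint`:

```sh
ciflint check structure.cif --fcf structure.fcf --format chk
```

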