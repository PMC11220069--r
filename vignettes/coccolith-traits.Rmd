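---
title: "Estimating coccolithophore cell size and cellular calcite from coccosphere morphometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating coccolithophore cell size and cellular calcite from coccosphere morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coccotraits)
```

## The problem

A scanning electron micrograph of an intact coccosphere yields a handful of
lengths: the long and short coccosphere axes, the length (and sometimes
width or process height) of one flat-lying coccolith, and a count of the
coccoliths on the visible hemisphere. Everything a trait ecologist or
biogeochemist actually wants — cell volume, equivalent spherical diameter,
per-cell calcite — must be modelled from those lengths, and the modelling
rules differ sharply between taxa. This vignette describes the models this
package implements, the assumptions behind them, the tunable parameters,
and what the accompanying synthetic-data tests do and do not demonstrate.

## Geometry

Coccosphere volume is computed from the two measurable axes with one of
three idealised shape classes assigned per taxon in the registry:

| shape class | volume | used for |
|---|---|---|
| `PROLATE_SPHERE` | $\frac{\pi}{6} d^2 h$ | spherical, sub-spherical, prolate and elongated-ellipsoid coccospheres |
| `CONE_HALF_SPHERE` | $\frac{\pi}{4} h d^2$ | cone-plus-hemisphere forms |
| `DOUBLE_CONE` | $\frac{\pi}{12} h d^2$ | strongly tapering forms (*Calciosolenia*) |

A true triaxial ellipsoid cannot be recovered from a 2-D image (the third
axis is unmeasurable), so elongated species are treated as prolate
spheroids. Size is reported as the equivalent spherical diameter
$\varnothing = (6V/\pi)^{1/3}$, which makes sizes comparable across shape
classes. Axes are defensively sorted so $d \le h$, with a warning, because
field tables carry them in either order.

The organic cell inside the coccosphere is estimated through the
taxon-specific fraction $y$ of coccosphere volume occupied by cell volume
(calibrated externally by light microscopy and consumed here as a registry
parameter): cell diameter $= \varnothing\, y^{1/3}$. For multilayer
coccospheres (chiefly *Emiliania huxleyi*, with a mean coccolith thickness
of 0.13 µm) the measured diameter is first reduced by twice the coccolith
thickness per extra layer, otherwise the single-layer $y$ would
overestimate the cell. The reported coccosphere ESD stays as measured;
only the cell-size conversion uses the corrected diameter.

## Calcite

The core mass model is
$$\text{coccolith PIC (pg)} = C_L^3 \times K_s \times 2.7,\qquad
  \text{cellular calcite} = \text{coccolith PIC} \times C_N,$$
with $K_s$ a dimensionless shape factor spanning roughly 0.01–0.2 across
extant species and 2.7 pg µm$^{-3}$ the density of calcite. Because $C_L$
enters cubed, coccolith size dominates every uncertainty budget (see the
sensitivity section).

`total_cell_calcite()` orchestrates the taxon-specific corrections:

* **Effective length.** The measured length wins when present (a
  provenance flag notes when a configured fixed length was overridden);
  *Alisphaera* polycrater falls back to a fixed 0.8 µm; *Umbellosphaera*
  uses $0.7 \times C_{L,\max}$ because its coccolith sizes vary so widely
  on a single coccosphere that the largest measurable coccolith is not
  representative (the 0.7 ratio is the calibrated average of the cubic-mean
  to maximum length on fully measured collapsed coccospheres;
  `umbellosphaera_average_cl()` reproduces that derivation). The raw
  maximum stays in the input record, so both values are available.
  *Discosphaera* records carry trumpet width in the length column by
  data-entry convention — the registry's `size_metric` documents this.
* **Effective count.** The measured total (visible count × 2, or × 3 for
  the pseudo-multilayered *Umbellosphaera*) plus any loose adjacent
  coccoliths; otherwise fixed fallbacks (*Florisphaera* 145, *Alisphaera*
  400); otherwise, for holococcolithophores, a surface-area
  back-calculation $C_N = \mathrm{round}(4\varnothing^2/(C_L C_W))$, which
  models the coccolith footprint as an ellipse on a spherical coccosphere
  with full single-layer coverage and no overlap. Coverage is exposed as a
  `packing` parameter (default 1.0) since the archival method states only
  that surface areas were used. A missing width falls back to
  $C_W = C_L$ (circular footprint) with a flag.
* **Additive components.** Exothecal coccoliths are counted and added at a
  common $K_s = 0.02$ across their diverse morphologies; the input schema
  has no XC-length column in the published descriptor, so an optional
  `exothecal_length_um` column is accepted, falling back to body $C_L$
  with a flag. Circum-flagellar coccoliths share the body shape factor and
  are simply carried inside $C_N$. Appendage calcite uses fixed masses:
  12.5 pg per appendage for *Michaelsarsia* (equivalently four 5.5 µm
  segments at $K_s = 0.007$; 8 appendages, i.e. 100 pg, assumed when
  uncountable) and a flat 33 pg for *Ophiaster* when arms are present.
* **Dimorphic coccospheres.** *Rhabdosphaera* assumes half the coccoliths
  are spinose (calcite from spine length, fixed 5 µm when unmeasurable)
  and half are not; fractional coccolith counts from the split are kept as
  real numbers because mass, not plate count, is the quantity of interest.

Every breakdown component is non-negative and the components sum to the
cellular total exactly; a brute-force test enumerates all component
coccoliths of randomized records and checks the sum against the orchestrated
result.

## The taxon registry

All constants live in one delimited-text table
(`inst/extdata/taxon_registry.csv`), one row per taxon key, resolved in the
order species → morpho-group → genus → life-cycle-phase default. Genus and
species match case-insensitively; morpho-groups match exactly after
whitespace normalisation; the key's life-cycle phase must equal the row's
phase at every level, which is how the holococcolith default
($K_s = 0.036$, $y = 0.80$) and the *Alisphaera* polycrater row are kept
separate from heterococcolith entries. An unidentified *Syracosphaera*
resolves at genus level to $K_s = 0.02$; the paper trail gives no $y$ for
that fallback, so the package uses 0.75, matching the *molischii*/*nodosa*
group values. Registry rows whose `source_note` says `placeholder` encode
literature-derived shape factors that this package cannot derive from its
own constants (e.g. *Gephyrocapsa*, *Calcidiscus*, *Helicosphaera*,
*Umbellosphaera*); no test or shipped result depends on them, and users
should confirm them before quantitative use. *Acanthoica* polar-spine
calcite is deliberately left unmodelled: no single shape factor reproduces
the plausible spine-mass range, so spinose *Acanthoica* coccospheres are
knowingly underestimated, as in the source methodology.

In strict mode an unresolvable taxon is an error; in lenient mode the
record is skipped with a machine-readable warning and listed in the
result's `skipped` attribute — no data is silently dropped.

## Sensitivity analysis

`run_sensitivity()` recomputes cellular calcite with one parameter
perturbed at a time: $K_s$ and $C_L$ by ±5–30 % (relative), $C_N$ by ±2
and ±5 coccoliths (absolute, floored at 1). Perturbations apply to the
*effective* parameters after all fallbacks — a length perturbation scales
fixed fallback lengths, spine lengths and exothecal lengths alike — while
fixed appendage masses stay constant, so arm-bearing taxa attenuate the
closed-form response. For records whose calcite is pure mass model the
responses obey exact laws, which serve as the module's oracle
(`closed_form_change()`, agreement to 1e-9 relative):

$$\Delta_{C_L} = 100\,[(1+\delta)^3 - 1]\,\%,\qquad
  \Delta_{K_s} = 100\,\delta\,\%,\qquad
  \Delta_{C_N} = 100\,\Delta/C_N\,\%.$$

The cubic law makes coccolith size by far the dominant error source: +30 %
in $C_L$ inflates cellular calcite by 119.7 % while −30 % removes 65.7 %.
No combination rule across parameters is implemented — the one-at-a-time
design is the point of the analysis.

## The synthetic-data generator

`generate_coccospheres()` emulates the structure of the archived
measurement tables so the whole pipeline is testable without the archived
data: one row per intact coccosphere with the descriptor's columns, a
notes column carrying machine-readable flag tokens, per-taxon size and
count distributions, and the documented noise modes. Choices the source
data cannot fix were made once, on standard grounds:

* coccolith length is lognormal between coccospheres (positive,
  right-skewed size data) with a within-coccosphere lognormal spread
  (default relative SD 0.10, within the ±10–15 % "reasonable" range for
  coccoliths on one coccosphere; sizes can spread up to ca. 30 %);
* the visible count is $4 + \text{NegBin}$ (overdispersed counts with a
  floor of 4 visible coccoliths);
* coccosphere surface area is made consistent with the placed coccoliths:
  $\varnothing^2 = (C_N/\text{layers}) \cdot \bar{C_L} C_W / 4$, after
  which an aspect ratio (1–1.3 for prolate forms, 3–5 for double cones) is
  drawn preserving that ESD;
* noise modes follow the stated magnitudes: the partial-length doubling
  error is normal with mean −0.6 % truncated at ±8 %, miscounts are ±1–5
  coccoliths, and spines/appendage counts are unobservable with
  configurable probability (falling back to the fixed rules).

Two design points keep the noiseless round trip *exact* for every taxon in
the default mix (a property the test suite asserts to 1e-10): generated
*Umbellosphaera* coccolith lists are rescaled so their cubic-mean length is
exactly $0.7 \times C_{L,\max}$ — i.e. the generator emulates coccospheres
for which the 0.7 calibration is exact, whereas the real calibration set
spans 0.55–0.81 — and holococcolith counts are drawn so the surface-area
back-calculation recovers them identically. Generated tables use the
reader-normalised convention (full coccolith lengths; the partial flag is
provenance), whereas input files record half lengths under the partial
flag; `read_measurements(partial_is_half = )` switches between the two.

What passing these tests shows is internal consistency: the pipeline
inverts the generator's forward model exactly when noise is off, and under
the documented noise the cellular-calcite errors stay inside the ca.
5–40 % envelope expected from the cubic law and miscount arithmetic. What
they cannot show is fidelity to real assemblages: the generator makes no
attempt at ecological composition, depth structure, covariation of size
with environment, morphotype mixtures, or the taxon-specific ways real
coccospheres deviate from the idealised shape classes and coverage
assumptions.

## Numerical conventions

* Closed-form arithmetic only; equality assertions use a relative
  tolerance of 1e-9 (1e-12 for single-formula identities).
* Degenerate inputs are errors, not NAs: non-positive lengths and volumes,
  $y \notin (0,1]$, counts below 1, multilayer corrections that exceed the
  diameter, holococcolith footprints larger than the coccosphere.
* Output files round lengths/diameters/volumes to 4 significant figures
  and masses to 2 decimals (the dataset convention); internal computation
  is full precision, and the formatting is a projection so writing is
  idempotent.
* Reported sensitivity percentages are rounded to whole percent in
  summaries only.
* Input is delimited text (configurable delimiter, alias headers, user
  column maps); the descriptor's native spreadsheet format is out of scope
  for this text-only toolchain — export to CSV first.

## Problem sizes

The shipped tests run the generator at 15–700 records per property
(distributional checks use 700; exact-closure and oracle checks use
25–250), and the Monte-Carlo volume check uses $10^6$ points; the full
suite completes in well under a minute. The acceptance script reproduces
the sensitivity extremes on 135 synthetic coccospheres of four
demonstration species (20 + 55 + 30 + 30), mirroring the published
demonstration set; the length and shape-factor responses are
record-independent, so this size is a convention, not a constraint.

## Known limitations

* Shape factors for several genera are placeholders pending user
  confirmation (see the registry's `source_note`).
* Coccolith thickness variability, morphotype-specific shape factors
  (a single $K_s$ is used for *E. huxleyi* across morphotypes, with a
  quoted ±19 % coccolith-calcite spread), and correlated multi-parameter
  error propagation are out of scope.
* Cell volume → organic carbon conversion is left to downstream
  relationships; this package stops at cell size and calcite.
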