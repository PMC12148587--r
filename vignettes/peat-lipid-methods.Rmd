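---
title: "Methods: peat lipid biomarker indices, classification and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peat lipid biomarker indices, classification and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peatlipid)
```

## Scope and data model

`peatlipid` analyses depth-resolved lipid biomarker concentrations from
peat cores. The pipeline starts at a quantified concentration table —
GC-MS peak picking, compound identification and quantification are
upstream and out of scope — and ends at per-sample molecular indices,
threshold-based source classifications, auxiliary marker summaries and a
contrast of each site against a reference condition.

The canonical container is a *long* table (`conc_table`): one row per
(sample, compound), where a sample is a `site` × `status` × `depth_cm` ×
`replicate` subsample and a compound is a compound class plus either a
carbon chain length (`"C23"`) or an analyte name (`"sitosterol"`).
Concentrations are µg/g dry weight. Two depth conventions coexist in this
field and are deliberately kept distinct: sample depths are positive cm
below the surface, while water-table levels (WTL) are signed cm relative
to the surface (negative = below). They are reconciled in exactly one
place, the archaeol/WTL consistency check.

Non-detects are first-class: they are stored as flags, not as zeros or
missing rows. When a numeric profile is extracted they are substituted
with a configurable value (default 0) and the substitution is logged.
Zero is the default because the molecular indices are concentration
ratios, and a compound that was not detected contributes no mass to
either side of a ratio; how the original study treated non-detects in its
own index arithmetic is not stated, so this is a package convention, made
explicit rather than buried.

## The n-alkane indices

For a profile of chain-length concentrations \(C_n\) (alkanes, C14–C35):

* **Carbon preference index**
  \[
  \mathrm{CPI} = \frac{2\,(C_{23}+C_{25}+C_{27}+C_{29}+C_{31})}
  {(C_{22}+C_{24}+C_{26}+C_{28}+C_{30}) + (C_{24}+C_{26}+C_{28}+C_{30}+C_{32})}
  \]
  High odd-over-even predominance (CPI well above 1) marks fresh plant
  wax; values approaching 1 mark degradation and/or microbial input. The
  window is exactly as written: C33 is not in the numerator and C34 not
  in the denominator, and no "extended" variant is silently substituted.
* **Average chain length**
  \[
  \mathrm{ACL} = \frac{\sum n\,C_n}{\sum C_n},\quad
  n \in \{23,25,27,29,31,33\}
  \]
  the abundance-weighted mean carbon number of the long odd homologues.
  One published rendering of this formula begins with a first
  coefficient equal to the concentration itself rather than the chain
  number; the stated definition ("average number of carbon atoms per
  molecule") and the divisor structure force the weighted-mean reading,
  which is what the package implements. ACL shifts are read only as
  vegetation/moisture shifts; no temperature or precipitation
  reconstruction is attempted.
* **Aquatic macrophyte proxy**
  \[
  P_{aq} = \frac{C_{23}+C_{25}}{C_{23}+C_{25}+C_{29}+C_{31}} \in [0,1]
  \]
* **Pairwise ratios** C23/C29, C25/C29 (Sphagnum vs. vascular input) and
  C23/C25 (wet- vs. dry-favouring Sphagnum).
* **Chain-class sums** over short (C15–C20, algal/bacterial), mid
  (C23–C25, Sphagnum/aquatic) and long (C27–C35, vascular) windows.
  These defaults follow the usage under which depth-resolved results are
  typically reported; introductory texts sometimes quote C15–C21 /
  C27–C33 instead, so the boundaries are configurable and chains covered
  by no class (C14, C21, C22, C26) are returned as a remainder
  diagnostic rather than silently dropped. Whether a "mid-chain mean"
  averages the two odd chains or also C24 differs between authors;
  `mid_chain_stats()` exposes both.
* **Cmax**, the modal chain, with ties broken toward the lower chain (a
  documented, deterministic rule).
* For n-alkanols (C12–C36, even-dominated), `alkanol_eop()` is the
  even/odd mirror of the CPI. No standard formula exists for this
  quantity; the mirror construction is a derived convenience metric and
  is labelled as such.

Every index is scale-free (except the sums, which scale linearly), so
results are invariant to unit changes. Degenerate inputs never raise:
an index whose denominator is zero is returned as `NA` and the reason is
collected in a `flags` field, so batch runs over whole tables always
complete and report their coverage.

## Threshold classification

P\(_{aq}\) bands: below 0.1 → terrestrial; 0.1–0.4 → emergent
macrophytes; above 0.4 → Sphagnum/submerged vegetation. The quoted band
wording ("below", "between", "exceeding") leaves the boundary points
ambiguous; both 0.1 and 0.4 are assigned to the emergent class (closed
interval), the most literal reading, and this choice is unit-tested so
it cannot drift. The C23/C25 moisture classification uses a balanced
band of 1 ± 0.1 by default; no numeric dominance cut-off is standard in
the field, so the tolerance is an explicit artifact parameter.
Vegetation hints map a modal chain to taxa known to peak there (C31 →
*Rhynchospora alba*, *Calluna vulgaris* leaf; C29 → *Molinia caerulea*,
*Calluna* stem; C27 → *Drosera* sp.; C23/C25 → hollow/hummock Sphagnum;
C17 → algae and photosynthetic bacteria). Hints are qualitative tags
with rule provenance, never exclusive identifications, and no
chemotaxonomic library beyond these documented taxa is attempted.

## Auxiliary markers

* **Stanol/sterol ratio** — microbial hydrogenation converts sterols to
  stanols, so stigmastanol/sitosterol (default pair; campestanol/
  campesterol and cholestanol/cholesterol are configurable alternates)
  indexes degradation of the sterol pool.
* **Ergosterol flag** — fungal biomass marker, `TRUE` iff detected above
  zero.
* **αβ-hopane fraction** — Σαβ/(Σαβ+Σββ) over hopanes and hopanols
  (hopenes/diploptene excluded). The field describes αβ "dominance"
  qualitatively; the fraction makes it testable with 0.5 as the
  neutrality point. Stereochemistry is parsed from compound names and
  accepts both Greek letters and ASCII fallbacks.
* **Archaeol/WTL consistency** — archaeol (methanogen marker) is
  expected at and below the water table. A detection at or below the
  deepest WTL excursion is `consistent`; a detection strictly above the
  shallowest excursion is `inconsistent`; a detection inside the
  fluctuation band is `indeterminate`, because temporarily saturated
  microsites can host methanogens there; and a non-detect is never
  treated as evidence against anoxia (it is `consistent` only above the
  band, where absence is the expected oxic outcome). The band-based
  rule was chosen over a simpler two-way split precisely to encode the
  microsite allowance.

## Condition contrasts

The restored-approaches-natural versus degraded-falls-below contrast is
qualitative in the source literature; `condition_contrast()`
operationalises it as `log2(site / reference)` per depth and per
quantity (total alkanes, mid- and long-chain sums, total sterols, total
hopanoids, CPI, P\(_{aq}\)), with the reference value the mean (median
optional) of the reference-status sites at the matched depth. A contrast
is "within band" when |log2 ratio| ≤ 1, i.e. within 2-fold — a default,
fully configurable, and echoed into every report. `restoration_report()`
aggregates to per-site verdicts: `near_natural` when ≥ 0.75 of defined
contrasts are within band, `partial` at ≥ 0.4, `degraded_signal` below.
With one core per site the study design supports no hypothesis testing,
and none is performed.

## The mixing simulator

`generate_dataset()` emulates the statistical structure the analysis
assumes, not any particular measured core:

* **End-members** are triangular chain-length distributions centred on
  the field-anchored modal chains — algal/bacterial C17, hollow Sphagnum
  C23, hummock Sphagnum C25, vascular C31 (shoulder at C29) — with even
  chains suppressed 10:1. That contrast puts the CPI of fresh mixed
  material in the mid-teens, matching little-decomposed bog peat; the
  exact template numbers are simulator constants.
* **Decomposition** is modelled as odd→even mass transfer: each odd
  chain loses `extent · Cn`, half to each adjacent even chain, with the
  edge chain's outward half redirected inward so total mass is conserved
  exactly. CPI — the degradation proxy — responds to the odd/even
  contrast, not to bulk mass loss, which is why the operator conserves
  mass. CPI decreases strictly in the extent; note it continues below 1
  at high extents (the transfer overshoots parity) rather than
  converging to 1.
* **Noise** is multiplicative lognormal per concentration (default
  σ = 0.2, unit mean), reflecting the strictly positive,
  heteroscedastic character of GC-MS quantification. No within-sample
  replicate variance is published for this kind of survey, so the level
  is a stated convention, not an estimate.
* **Status effects**: degraded sites carry 0.3× the biomarker mass of
  natural sites, are vascular-dominated and more decomposed; restored
  sites share the natural parameters. The default design is six sites
  (two degraded, two natural, two restored) × three depths (10, 30,
  80 cm — acrotelm, transition zone, catotelm), one replicate each.
  Depths are independent draws; no depth-coupled diagenesis model is
  attempted.

What the simulator does *not* emulate: inter-site template variation,
compound co-detection limits, chromatographic interferences, or real
depth autocorrelation. Passing parameter-recovery tests therefore shows
the pipeline is consistent with its own generating model, not that any
particular field inference is correct.

## Numerical choices and problem sizes

Ties in `cmax` break low; zero denominators flag rather than raise;
profile round-tripping through CSV uses 17 significant digits so
read∘write is the identity; decimal commas are schema errors, never
silent misparses; weights must sum to 1 within 1e-8. The test suite
exercises the formula oracles on 1,000 random profiles at 1e-12 relative
tolerance, mass conservation on 1,000 profiles, a 21-step Sphagnum
weight sweep, a 19-step decomposition sweep, and 100 seeded noisy
datasets for label recovery — sizes chosen to make the checks sharp
while keeping a full run in well under a minute.

## Known limitations

Indices are relative measures and none is standardised across studies;
the classification bands are literature conventions, not fitted
thresholds. The contrast module compares levels, not dynamics: a single
time point cannot distinguish recovery trajectories. The archaeol rule
depends on a WTL envelope that many site tables report only as a mean;
with an incomplete envelope the check returns `indeterminate` rather
than guessing.
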