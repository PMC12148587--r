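# peatlipid

Lipid biomarkers — n-alkanes, n-alkanols, sterols, pentacyclic
triterpenoids, hopanoids and archaeol — record what grew on a peatland,
how wet it was, and how far its organic matter has decomposed. This
package is for peatland ecologists and organic geochemists who have a
quantified GC-MS concentration table (µg/g dry weight, by site, depth
and compound) and want the standard depth-resolved diagnostics from it:
molecular indices, source classifications, marker summaries, and a
quantitative comparison of degraded and restored sites against
near-natural reference conditions.

## What it computes

For each sample's n-alkane profile C<sub>n</sub> (C14–C35):

* **CPI** (carbon preference index), the odd-over-even predominance of
  the long chains —
  `CPI = 2(C23+C25+C27+C29+C31) / [(C22+C24+C26+C28+C30) + (C24+C26+C28+C30+C32)]`
  — high in fresh plant wax, near 1 in degraded or microbially reworked
  peat;
* **ACL** (average chain length) — `ACL = Σ n·Cn / Σ Cn` over odd
  n ∈ {23,…,33} — tracking vegetation and moisture shifts;
* **P<sub>aq</sub>** — `(C23+C25) / (C23+C25+C29+C31)` — the aquatic
  macrophyte / Sphagnum proxy, with interpretation bands &lt;0.1
  terrestrial, 0.1–0.4 emergent macrophytes, &gt;0.4 Sphagnum/submerged;
* the C23/C29, C25/C29 and C23/C25 ratios, chain-class sums
  (short C15–C20, mid C23–C25, long C27–C35), the modal chain
  C<sub>max</sub>, and an even-over-odd index for n-alkanols.

Beyond the indices: threshold-based source and moisture classification
with rule provenance, stanol/sterol degradation ratios, the ergosterol
fungal flag, αβ- vs ββ-hopane dominance, archaeol vs. water-table
consistency, per-depth log2 contrasts of every site against the
reference condition, and a seeded end-member mixing simulator
(algal C17, hollow Sphagnum C23, hummock Sphagnum C25, vascular C29/C31
end-members; mass-conserving odd→even decomposition; lognormal noise)
for testing and parameter-recovery studies. See the methods vignette
(`vignettes/peat-lipid-methods.Rmd`) for the model details and design
choices.

## Worked example

```r
library(peatlipid)

# a six-site, three-depth synthetic survey (two degraded, two natural,
# two restored sites); for real data use read_conc_table("table.csv")
tab <- generate_dataset(seed = 42)
idx <- alkane_indices(tab)
idx10 <- idx[idx$depth_cm == 10, ]
cbind(idx10["site"], round(idx10[c("cpi", "acl", "paq")], 2),
      paq_class = classify_paq(idx10$paq))
#>     site  cpi   acl  paq           paq_class
#> 1   AV-D 2.31 29.48 0.29 emergent_macrophyte
#> 4  AV-ED 2.36 29.65 0.21 emergent_macrophyte
#> 7  BK-ER 6.28 26.35 0.70  sphagnum_submerged
#> 10  BK-N 7.45 26.32 0.72  sphagnum_submerged
#> 13 PI-ER 7.37 26.71 0.65  sphagnum_submerged
#> 16  PU-N 7.48 26.84 0.71  sphagnum_submerged
```

The two degraded sites (AV-D, AV-ED) show the vascular-dominated,
decomposed signature: low CPI (≈2.3, strong odd/even erosion), long ACL
(≈29.5) and low P<sub>aq</sub>; the natural and restored sites keep the
fresh Sphagnum signature (CPI 6–7.5, ACL ≈26.5, P<sub>aq</sub> &gt; 0.4).
Contrasting every site against the natural reference:

```r
restoration_report(condition_contrast(tab, idx))
#> Restoration report (band: |log2 ratio| <= 1; verdict cuts: near >= 0.75, partial >= 0.4)
#>   site             status n_contrasts frac_within_band direction         verdict
#>   AV-D   degraded_drained          21            0.143     below degraded_signal
#>  AV-ED degraded_extracted          21            0.143     below degraded_signal
#>  BK-ER           restored          21            1.000     below    near_natural
#>  PI-ER           restored          21            1.000     below    near_natural
```

Restored sites sit within 2-fold of the natural reference on every
quantity; degraded sites fall below on everything except the scale-free
indices. A worked marker value from a published steroid table shipped
with the package:

```r
tab2 <- read_conc_table(system.file("extdata",
        "printed_steroids_subset.csv", package = "peatlipid"))
prof <- compound_profile(tab2, "AV-D", 10, compound_class = "steroid",
                         quiet = TRUE)
stanol_sterol_ratio(prof)   # stigmastanol / sitosterol = 208 / 895
#> [1] 0.2324022
```

about 23% of the sitosterol pool at 10 cm has been microbially
hydrogenated to stigmastanol.

`run_pipeline(tab, "out/", site_metadata = default_site_metadata())`
writes `indices.csv`, `calls.csv`, `markers.csv`, `contrasts.csv` and an
auditable `report.md` in one call; `inst/cli/peatlipid.R` wraps the same
functions for shell use.

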