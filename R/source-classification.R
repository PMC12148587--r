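## Threshold-based interpretation of the molecular indices: organic-matter
## source class from Paq, Sphagnum moisture preference from C23/C25, and
## qualitative vegetation hints from the modal chain. Every call records the
## rule that fired so classifications are auditable.

#' Classify organic-matter source from the Paq proxy
#'
#' Interpretation bands for the aquatic macrophyte proxy: terrestrial plants
#' typically fall below 0.1, emergent macrophytes between 0.1 and 0.4, and
#' fresh Sphagnum / submerged vegetation above 0.4. Both boundary values
#' (0.1 and 0.4) belong to the emergent band (closed interval).
#'
#' @param paq Numeric vector of Paq values in \[0, 1\] (`NA` allowed).
#' @return Character vector with levels `terrestrial`,
#'   `emergent_macrophyte`, `sphagnum_submerged`, `undefined`.
#' @export
classify_paq <- function(paq) {
  out <- rep("undefined", length(paq))
  out[!is.na(paq) & paq < 0.1] <- "terrestrial"
  out[!is.na(paq) & paq >= 0.1 & paq <= 0.4] <- "emergent_macrophyte"
  out[!is.na(paq) & paq > 0.4] <- "sphagnum_submerged"
  out
}

#' Classify moisture preference from the C23/C25 ratio
#'
#' Hollow (cold/wet-favouring) Sphagnum species peak at C23 and hummock
#' (warm/dry-favouring) species at C25, so C23/C25 above 1 reads as
#' wet-favouring and below 1 as dry-favouring. A tolerance band around 1
#' (default +/- 0.1) is classed `balanced`; no cut-off for "dominance" is
#' standardised, so the band is an explicit tunable.
#'
#' @param r23_25 Numeric vector of C23/C25 ratios (`NA` allowed).
#' @param tolerance Half-width of the balanced band around ratio 1.
#' @return Character vector with levels `wet_favoring`, `dry_favoring`,
#'   `balanced`, `undefined`.
#' @export
classify_moisture <- function(r23_25, tolerance = 0.1) {
  stopifnot(tolerance > 0)
  defined <- !is.na(r23_25)
  wet <- defined & r23_25 > 1 + tolerance
  dry <- defined & r23_25 < 1 - tolerance
  out <- rep("undefined", length(r23_25))
  out[wet] <- "wet_favoring"
  out[dry] <- "dry_favoring"
  out[defined & !wet & !dry] <- "balanced"   # totality: band is the default
  out
}

# chain -> taxa known to peak there; qualitative suggestions only
.vegetation_lookup <- list(
  `17` = c("algae/photosynthetic bacteria"),
  `23` = c("hollow Sphagnum (e.g. S. angustifolium, S. cuspidatum)"),
  `25` = c("hummock Sphagnum (e.g. S. medium/divinum, S. fuscum)"),
  `27` = c("Drosera sp."),
  `29` = c("Molinia caerulea", "Calluna vulgaris (stem)"),
  `31` = c("Rhynchospora alba", "Calluna vulgaris (leaf)",
           "some Sphagna (e.g. S. capillifolium, S. medium/divinum)"))

#' Vegetation hints from the modal chain length
#'
#' Looks up taxa known to synthesise their n-alkane maximum at the given
#' chain. The hints are qualitative suggestions, never exclusive
#' identifications; unmapped chains return an empty vector.
#'
#' @param cmax Integer modal chain length (see [cmax()]).
#' @return Character vector of taxon tags (possibly empty).
#' @export
vegetation_hints <- function(cmax) {
  if (is.na(cmax)) return(character(0))
  hits <- .vegetation_lookup[[as.character(cmax)]]
  if (is.null(hits)) character(0) else hits
}

#' Source classification for a table of per-sample indices
#'
#' Applies [classify_paq()], [classify_moisture()] and [vegetation_hints()]
#' to every row of an [alkane_indices()] result. The `rationale` column
#' lists the rule identifiers that fired, so each call can be traced back to
#' its threshold.
#'
#' @param indices Data frame from [alkane_indices()] (needs columns `paq`,
#'   `r23_25`, `cmax` plus the sample key).
#' @param tolerance Balanced-band half-width for [classify_moisture()].
#' @return Data frame with the sample key columns plus `paq_class`,
#'   `moisture_class`, `vegetation_hint` (semicolon-joined) and `rationale`.
#' @export
classify_sources <- function(indices, tolerance = 0.1) {
  stopifnot(all(c("paq", "r23_25", "cmax") %in% names(indices)))
  paq_class <- classify_paq(indices$paq)
  moisture_class <- classify_moisture(indices$r23_25, tolerance)
  hints <- vapply(indices$cmax, function(cm)
    paste(vegetation_hints(cm), collapse = ";"), character(1))
  paq_rule <- c(terrestrial = "paq<0.1",
                emergent_macrophyte = "0.1<=paq<=0.4",
                sphagnum_submerged = "paq>0.4",
                undefined = "paq_undefined")[paq_class]
  moist_rule <- c(wet_favoring = sprintf("r23_25>%g", 1 + tolerance),
                  dry_favoring = sprintf("r23_25<%g", 1 - tolerance),
                  balanced = sprintf("|r23_25-1|<=%g", tolerance),
                  undefined = "r23_25_undefined")[moisture_class]
  cmax_rule <- ifelse(nzchar(hints),
                      paste0("cmax=", indices$cmax), "cmax_unmapped")
  keep <- intersect(.sample_cols, names(indices))
  out <- cbind(indices[, keep, drop = FALSE],
               data.frame(paq_class = paq_class,
                          moisture_class = moisture_class,
                          vegetation_hint = hints,
                          rationale = paste(paq_rule, moist_rule, cmax_rule,
                                            sep = "|"),
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
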