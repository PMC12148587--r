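## Sterol, pentacyclic triterpenoid, hopanoid and archaeol summaries:
## stanol/sterol degradation ratios, the ergosterol fungal flag, alpha-beta
## vs. beta-beta hopane dominance, and archaeol presence checked against the
## site's water-table envelope.

#' Stanol/sterol degradation ratio
#'
#' Microbial hydrogenation converts sterols to their stanols, so the
#' stanol/sterol ratio indexes degradation of the sterol pool. The default
#' pair is stigmastanol/sitosterol; campestanol/campesterol and
#' cholestanol/cholesterol are the usual alternates.
#'
#' @param profile Named numeric vector of steroid concentrations (ug/g),
#'   e.g. from [compound_profile()].
#' @param stanol,sterol Compound names forming the ratio.
#' @return The ratio, or `NA` when the sterol is absent or zero.
#' @examples
#' stanol_sterol_ratio(c(stigmastanol = 208, sitosterol = 895))
#' @export
stanol_sterol_ratio <- function(profile, stanol = "stigmastanol",
                                sterol = "sitosterol") {
  num <- profile[stanol]
  den <- profile[sterol]
  num <- if (is.na(num)) 0 else unname(num)
  den <- if (is.na(den)) 0 else unname(den)
  if (den == 0) return(NA_real_)
  num / den
}

#' Fungal biomarker flag
#'
#' Ergosterol is a biomarker for fungi (and certain microalgae/protozoa) but
#' not for bacteria, insects or plants; the flag is `TRUE` iff ergosterol is
#' detected above zero.
#'
#' @inheritParams stanol_sterol_ratio
#' @param marker Compound name of the fungal marker.
#' @return Logical.
#' @export
fungal_marker_flag <- function(profile, marker = "ergosterol") {
  v <- profile[marker]
  !is.na(v) && v > 0
}

#' Classify a hopanoid compound name
#'
#' Parses the stereochemistry (17alpha(H),21beta(H) vs. 17beta(H),21beta(H))
#' and the compound type (hopane, hopanol, hopene/diploptene) from a
#' hopanoid name. Greek letters and their ASCII fallbacks (`a`/`b`) are both
#' accepted.
#'
#' @param name Character vector of hopanoid names.
#' @return Data frame with columns `stereo` (`alpha_beta`, `beta_beta`,
#'   `other`) and `type` (`hopane`, `hopanol`, `hopene`, `other`).
#' @examples
#' hopanoid_stereochemistry("17\u03b1(H),21\u03b2(H)-hopane")
#' @export
hopanoid_stereochemistry <- function(name) {
  norm <- tolower(chartr("\u03b1\u03b2", "ab", name))
  stereo <- rep("other", length(name))
  stereo[grepl("17a", norm) & grepl("21b", norm)] <- "alpha_beta"
  stereo[grepl("17b", norm) & grepl("21b", norm)] <- "beta_beta"
  type <- rep("other", length(name))
  type[grepl("hopene|diploptene|diplopterol", norm)] <- "hopene"
  type[grepl("hopane", norm)] <- "hopane"
  type[grepl("hopanol", norm)] <- "hopanol"
  data.frame(stereo = stereo, type = type, stringsAsFactors = FALSE)
}

#' Fraction of alpha-beta hopanes in the hopane + hopanol pool
#'
#' In acidic, Sphagnum-dominated peat the alpha-beta (17alpha(H),21beta(H))
#' geohopanoids dominate over the biological beta-beta configuration; this
#' fraction makes that qualitative dominance testable, with 0.5 as the
#' neutrality point. Hopenes (diploptene) are excluded from the pool.
#'
#' @param profile Named numeric vector of hopanoid concentrations (ug/g),
#'   names carrying the stereochemistry (see [hopanoid_stereochemistry()]).
#' @return Fraction in \[0, 1\], or `NA` when both stereo pools are zero.
#' @export
hopane_ab_fraction <- function(profile) {
  if (length(profile) == 0) return(NA_real_)
  info <- hopanoid_stereochemistry(names(profile))
  pool <- info$type %in% c("hopane", "hopanol")
  ab <- sum(profile[pool & info$stereo == "alpha_beta"])
  bb <- sum(profile[pool & info$stereo == "beta_beta"])
  if (ab + bb == 0) return(NA_real_)
  ab / (ab + bb)
}

#' Archaeol vs. water-table consistency
#'
#' Archaeol, the diether lipid of (mostly methanogenic, anaerobic) archaea,
#' is expected at and below the water table. The sample depth (positive cm
#' below surface) is compared with the site's signed water-table envelope
#' \[`wtl_min_cm`, `wtl_max_cm`\] (negative = below surface):
#' * detected at or below the deepest excursion (`depth_cm >=
#'   |wtl_min_cm|`, permanently saturated) -> `consistent`;
#' * detected strictly above the shallowest excursion (`depth_cm <
#'   |wtl_max_cm|`, never saturated) -> `inconsistent`;
#' * detection inside the fluctuation band -> `indeterminate` (anaerobic
#'   microsites are possible there);
#' * non-detects are never evidence against anoxia: `consistent` only when
#'   the depth is strictly above the band (the expected oxic outcome),
#'   `indeterminate` otherwise.
#'
#' @param archaeol_detected Logical; was archaeol detected above zero?
#' @param depth_cm Sample depth, positive cm below surface.
#' @param meta One site-metadata row (see [read_site_metadata()]) with
#'   `wtl_max_cm` and `wtl_min_cm`.
#' @return One of `"consistent"`, `"inconsistent"`, `"indeterminate"`.
#' @export
archaeol_wtl_consistency <- function(archaeol_detected, depth_cm, meta) {
  if (is.null(meta) || nrow(as.data.frame(meta)) != 1) {
    stop("configuration error: exactly one site-metadata row required",
         call. = FALSE)
  }
  wtl_max <- meta$wtl_max_cm
  wtl_min <- meta$wtl_min_cm
  if (is.na(wtl_max) || is.na(wtl_min)) return("indeterminate")
  z <- -depth_cm  # signed sample elevation, same convention as WTL
  if (archaeol_detected) {
    if (z <= wtl_min) "consistent"
    else if (z > wtl_max) "inconsistent"
    else "indeterminate"
  } else {
    if (z > wtl_max) "consistent" else "indeterminate"
  }
}

#' Marker summary for one sample
#'
#' Combines the sterol, hopanoid and archaeol diagnostics of a single sample
#' into one row: stanol/sterol ratio, fungal flag, alpha-beta hopane
#' fraction, diploptene presence and archaeol-water-table consistency.
#'
#' @param sterols Named steroid concentration vector for the sample.
#' @param hopanoids Named hopanoid concentration vector for the sample.
#' @param archaeol Archaeol concentration (ug/g) or `NA` for non-detect.
#' @param depth_cm Sample depth (positive cm below surface).
#' @param meta One site-metadata row.
#' @return One-row data frame with columns `stanol_sterol_ratio`,
#'   `fungal_flag`, `hopane_ab_fraction`, `diploptene_present`,
#'   `archaeol_wtl_consistent`.
#' @export
marker_summary_row <- function(sterols, hopanoids, archaeol, depth_cm, meta) {
  info <- hopanoid_stereochemistry(names(hopanoids))
  detected <- !is.na(archaeol) && archaeol > 0
  data.frame(
    stanol_sterol_ratio = stanol_sterol_ratio(sterols),
    fungal_flag = fungal_marker_flag(sterols),
    hopane_ab_fraction = hopane_ab_fraction(hopanoids),
    diploptene_present = any(info$type == "hopene" & hopanoids > 0),
    archaeol_wtl_consistent =
      archaeol_wtl_consistency(detected, depth_cm, meta),
    stringsAsFactors = FALSE)
}

#' Marker summaries for a whole concentration table
#'
#' Builds per-sample sterol/hopanoid/archaeol profiles from a concentration
#' table and summarises each with [marker_summary_row()]. Sites without a
#' metadata row raise a configuration error (the archaeol check needs the
#' water-table envelope).
#'
#' @param table A [conc_table] carrying `steroid`, `hopanoid` and/or
#'   `archaeol` records.
#' @param meta Site metadata data frame from [read_site_metadata()].
#' @param nondetect_sub Substitution value for non-detects in profiles.
#' @return Data frame, one row per sample: sample key plus the summary
#'   columns.
#' @export
marker_summary <- function(table, meta, nondetect_sub = 0) {
  keys <- sample_keys(table)
  missing_meta <- setdiff(unique(keys$site), meta$site)
  if (length(missing_meta) > 0) {
    stop("configuration error: no site metadata for: ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    st <- compound_profile(table, keys$site[i], keys$depth_cm[i],
                           keys$replicate[i], "steroid",
                           nondetect_sub = nondetect_sub, quiet = TRUE)
    ho <- compound_profile(table, keys$site[i], keys$depth_cm[i],
                           keys$replicate[i], "hopanoid",
                           nondetect_sub = nondetect_sub, quiet = TRUE)
    ar_rows <- table$site == keys$site[i] &
      table$depth_cm == keys$depth_cm[i] &
      table$replicate == keys$replicate[i] &
      table$compound_class == "archaeol"
    ar <- if (any(ar_rows)) {
      if (any(table$detect[ar_rows])) {
        sum(table$concentration[ar_rows & table$detect])
      } else NA_real_
    } else NA_real_
    cbind(keys[i, , drop = FALSE],
          marker_summary_row(st, ho, ar, keys$depth_cm[i],
                             meta[meta$site == keys$site[i], , drop = FALSE]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
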