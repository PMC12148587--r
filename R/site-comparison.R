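## Condition contrasts: how far each site sits from the reference (usually
## near-natural) condition, per depth and per biomarker quantity, expressed
## as log2 ratios with a configurable "similar to reference" band. The
## study design has one core per site, so no hypothesis testing is
## performed; the band construction is this package's operationalisation of
## the qualitative restored-approaches-natural / degraded-falls-below
## contrast.

.contrast_quantities <- c("total_alkane", "mid_chain_sum", "long_chain_sum",
                          "total_sterol", "total_hopanoid", "cpi", "paq")

# per-sample quantity values for the contrast; concentrations summed over
# the class, cpi/paq taken from the index table
.quantity_values <- function(table, indices, site, depth_cm,
                             boundaries = default_chain_boundaries()) {
  reps <- unique(table$replicate[table$site == site &
                                 table$depth_cm == depth_cm])
  if (length(reps) == 0) return(NULL)
  per_rep <- lapply(reps, function(r) {
    prof <- compound_profile(table, site, depth_cm, r, "alkane",
                             quiet = TRUE)
    sums <- chain_class_sums(prof, boundaries)
    cls_total <- function(cls) {
      rows <- table$site == site & table$depth_cm == depth_cm &
        table$replicate == r & table$compound_class == cls & table$detect
      if (!any(rows)) NA_real_ else sum(table$concentration[rows])
    }
    irow <- indices$site == site & indices$depth_cm == depth_cm &
      indices$replicate == r
    c(total_alkane = sum(prof),
      mid_chain_sum = unname(sums["mid"]),
      long_chain_sum = unname(sums["long"]),
      total_sterol = cls_total("steroid"),
      total_hopanoid = cls_total("hopanoid"),
      cpi = if (any(irow)) indices$cpi[irow][1] else NA_real_,
      paq = if (any(irow)) indices$paq[irow][1] else NA_real_)
  })
  colMeans(do.call(rbind, per_rep), na.rm = FALSE)
}

#' Contrast each site against a reference condition
#'
#' For every non-reference site, depth and quantity, computes
#' `log2(site value / reference value)`, where the reference value is the
#' mean (or median) of the per-site values across all reference-status sites
#' at the matched depth. `within_band` marks contrasts with
#' `|log2_ratio| <= band`; the default band of 1 reads as "within 2-fold of
#' the reference". Rows with a zero or missing reference value are kept with
#' `log2_ratio = NA` and a flag.
#'
#' @param table A [conc_table].
#' @param indices Per-sample index table from [alkane_indices()].
#' @param reference_status Condition class used as reference (default
#'   `"natural"`).
#' @param band Half-width of the similarity band on the log2 scale.
#' @param aggregate `"mean"` or `"median"` across reference sites.
#' @param boundaries Chain-class boundaries for the concentration sums.
#' @return Data frame with columns `site`, `status`, `reference_status`,
#'   `depth_cm`, `quantity`, `value`, `reference_value`, `log2_ratio`,
#'   `within_band`, `flag`.
#' @export
condition_contrast <- function(table, indices,
                               reference_status = "natural", band = 1,
                               aggregate = c("mean", "median"),
                               boundaries = default_chain_boundaries()) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") {
    function(x) mean(x, na.rm = TRUE)
  } else {
    function(x) stats::median(x, na.rm = TRUE)
  }
  keys <- sample_keys(table)
  site_status <- unique(keys[, c("site", "status")])
  ref_sites <- site_status$site[site_status$status == reference_status]
  if (length(ref_sites) == 0) {
    stop("configuration error: no site with reference status '",
         reference_status, "'", call. = FALSE)
  }
  depths <- sort(unique(keys$depth_cm))
  other <- site_status[site_status$status != reference_status, , drop = FALSE]
  rows <- list()
  for (d in depths) {
    ref_vals <- do.call(rbind, Filter(Negate(is.null), lapply(
      ref_sites, .quantity_values, table = table, indices = indices,
      depth_cm = d, boundaries = boundaries)))
    if (is.null(ref_vals)) next
    ref <- apply(ref_vals, 2, agg)
    for (i in seq_len(nrow(other))) {
      val <- .quantity_values(table, indices, other$site[i], d, boundaries)
      if (is.null(val)) next
      for (q in .contrast_quantities) {
        v <- val[[q]]; rv <- ref[[q]]
        undef <- is.na(v) || is.na(rv) || rv == 0 || v == 0
        lr <- if (undef) NA_real_ else log2(v / rv)
        rows[[length(rows) + 1]] <- data.frame(
          site = other$site[i], status = other$status[i],
          reference_status = reference_status, depth_cm = d, quantity = q,
          value = v, reference_value = rv, log2_ratio = lr,
          within_band = if (undef) NA else abs(lr) <= band,
          flag = if (undef) "undefined_ratio" else "",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    stop("configuration error: no contrastable sites/depths", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "band") <- band
  rownames(out) <- NULL
  out
}

#' Per-site restoration verdicts
#'
#' Aggregates a [condition_contrast()] table to one verdict per site: the
#' fraction of defined contrasts within the similarity band, the majority
#' direction of departure, and a three-level verdict. `near_natural` when at
#' least `near_frac` of contrasts sit inside the band, `partial` when at
#' least `partial_frac` do, `degraded_signal` otherwise.
#'
#' @param contrasts Output of [condition_contrast()].
#' @param near_frac,partial_frac Verdict cut-offs on the within-band
#'   fraction.
#' @return Data frame of class `restoration_report`: one row per site with
#'   `site`, `status`, `n_contrasts`, `frac_within_band`, `direction`
#'   (`below`, `above`, `mixed`), `verdict`.
#' @export
restoration_report <- function(contrasts, near_frac = 0.75,
                               partial_frac = 0.4) {
  if (nrow(contrasts) == 0) stop("empty contrast table", call. = FALSE)
  sites <- unique(contrasts[, c("site", "status")])
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    sub <- contrasts[contrasts$site == sites$site[i], ]
    defined <- !is.na(sub$log2_ratio)
    frac <- if (any(defined)) mean(sub$within_band[defined]) else NA_real_
    lr <- sub$log2_ratio[defined]
    neg <- sum(lr < 0); pos <- sum(lr > 0)
    direction <- if (neg > pos) "below" else if (pos > neg) "above" else
      "mixed"
    verdict <- if (is.na(frac)) "indeterminate"
      else if (frac >= near_frac) "near_natural"
      else if (frac >= partial_frac) "partial"
      else "degraded_signal"
    data.frame(site = sites$site[i], status = sites$status[i],
               n_contrasts = sum(defined), frac_within_band = frac,
               direction = direction, verdict = verdict,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("restoration_report", "data.frame"),
            band = attr(contrasts, "band"),
            near_frac = near_frac, partial_frac = partial_frac)
}

#' @export
print.restoration_report <- function(x, ...) {
  cat("Restoration report (band: |log2 ratio| <= ",
      attr(x, "band"), "; verdict cuts: near >= ", attr(x, "near_frac"),
      ", partial >= ", attr(x, "partial_frac"), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}
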