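## n-alkane (and n-alkanol) molecular indices.
##
## Profiles are named numeric vectors indexed by carbon chain length
## (names "14".."35" for alkanes); absent chains count as zero. All indices
## are ratios of concentrations and therefore unit- and scale-free; sums are
## in the units of the profile (ug/g dry weight). Undefined results (zero
## denominators) are returned as NA, never as errors, so whole-table batch
## runs complete and report coverage through flags.

# concentration at chain n (0 when the chain is absent from the vector)
.chain <- function(profile, n) {
  v <- profile[as.character(n)]
  v[is.na(v)] <- 0
  sum(v)
}

.check_profile <- function(profile) {
  if (is.null(names(profile)) || anyNA(suppressWarnings(
        as.integer(names(profile))))) {
    stop("profile must be a numeric vector named by carbon chain length",
         call. = FALSE)
  }
  if (any(profile < 0, na.rm = TRUE)) {
    stop("profile concentrations must be >= 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' Carbon preference index (CPI) of an n-alkane profile
#'
#' Quantifies the predominance of odd- over even-numbered long-chain
#' n-alkanes, high in fresh plant wax and approaching 1 with degradation or
#' microbial input:
#' \deqn{CPI = \frac{2 (C_{23}+C_{25}+C_{27}+C_{29}+C_{31})}{(C_{22}+C_{24}+C_{26}+C_{28}+C_{30}) + (C_{24}+C_{26}+C_{28}+C_{30}+C_{32})}}
#' C33 is deliberately excluded from the numerator and C34 from the
#' denominator; no extended variant is substituted.
#'
#' @param profile Named numeric vector of concentrations indexed by chain
#'   length (absent chains count as 0).
#' @return The CPI, or `NA` when the even-chain denominator is zero.
#' @examples
#' flat <- setNames(rep(1, 11), 22:32)
#' cpi(flat)  # exactly 1
#' @export
cpi <- function(profile) {
  .check_profile(profile)
  num <- 2 * sum(vapply(c(23, 25, 27, 29, 31), .chain,
                        numeric(1), profile = profile))
  den <- sum(vapply(c(22, 24, 26, 28, 30), .chain,
                    numeric(1), profile = profile)) +
         sum(vapply(c(24, 26, 28, 30, 32), .chain,
                    numeric(1), profile = profile))
  if (den == 0) return(NA_real_)
  num / den
}

#' Average chain length (ACL) of the long odd n-alkanes
#'
#' Abundance-weighted mean carbon number over the odd homologues C23-C33:
#' \deqn{ACL = \frac{\sum_n n\, C_n}{\sum_n C_n}, \quad n \in \{23,25,27,29,31,33\}}
#' Tracks shifts between shorter-chain (wetter/cooler, moss-associated) and
#' longer-chain (drier, vascular) wax sources.
#'
#' @inheritParams cpi
#' @return The ACL in carbon atoms, or `NA` when all six chains are zero.
#' @export
acl <- function(profile) {
  .check_profile(profile)
  chains <- c(23, 25, 27, 29, 31, 33)
  conc <- vapply(chains, .chain, numeric(1), profile = profile)
  if (sum(conc) == 0) return(NA_real_)
  sum(chains * conc) / sum(conc)
}

#' Paq: aquatic macrophyte / Sphagnum proxy
#'
#' Proportion of mid-chain (submerged/floating macrophyte and Sphagnum)
#' relative to mid- plus long-chain (terrestrial vascular) n-alkanes:
#' \deqn{P_{aq} = \frac{C_{23}+C_{25}}{C_{23}+C_{25}+C_{29}+C_{31}}}
#' Bounded in \[0, 1\].
#'
#' @inheritParams cpi
#' @return The Paq fraction, or `NA` when all four chains are zero.
#' @seealso [classify_paq()] for the interpretation bands.
#' @export
paq <- function(profile) {
  .check_profile(profile)
  mid <- .chain(profile, 23) + .chain(profile, 25)
  den <- mid + .chain(profile, 29) + .chain(profile, 31)
  if (den == 0) return(NA_real_)
  mid / den
}

#' Ratio of two chain-length concentrations
#'
#' Pairwise ratios such as C23/C29 and C25/C29 (Sphagnum vs. vascular input)
#' or C23/C25 (wet- vs. dry-favouring Sphagnum).
#'
#' @inheritParams cpi
#' @param numerator,denominator Chain lengths, each in 14-35.
#' @return `numerator`/`denominator` concentration ratio, or `NA` when the
#'   denominator concentration is zero.
#' @export
chain_ratio <- function(profile, numerator, denominator) {
  .check_profile(profile)
  if (!(numerator %in% ALKANE_CHAINS) || !(denominator %in% ALKANE_CHAINS)) {
    stop("chain lengths must lie in ", min(ALKANE_CHAINS), "-",
         max(ALKANE_CHAINS), call. = FALSE)
  }
  den <- .chain(profile, denominator)
  if (den == 0) return(NA_real_)
  .chain(profile, numerator) / den
}

#' Default chain-length class boundaries
#'
#' Short C15-C20 (algal/bacterial), mid C23-C25 (Sphagnum/aquatic), long
#' C27-C35 (vascular). C14, C21, C22 and C26 fall in none of the classes and
#' are reported as a remainder diagnostic.
#'
#' @return Named list of inclusive `c(lo, hi)` ranges.
#' @export
default_chain_boundaries <- function() {
  list(short = c(15L, 20L), mid = c(23L, 25L), long = c(27L, 35L))
}

#' Chain-length class sums
#'
#' Sums profile concentrations over the short/mid/long chain classes plus a
#' `remainder` for chains outside every class.
#'
#' @inheritParams cpi
#' @param boundaries Named list of three disjoint inclusive ranges, as
#'   returned by [default_chain_boundaries()].
#' @return Named numeric vector `c(short, mid, long, remainder)` in the
#'   units of the profile.
#' @export
chain_class_sums <- function(profile, boundaries = default_chain_boundaries()) {
  .check_profile(profile)
  stopifnot(all(c("short", "mid", "long") %in% names(boundaries)))
  spans <- lapply(boundaries[c("short", "mid", "long")],
                  function(b) seq(b[1], b[2]))
  all_chains <- unlist(spans)
  if (anyDuplicated(all_chains)) {
    stop("config error: chain-class ranges overlap", call. = FALSE)
  }
  chains <- as.integer(names(profile))
  sums <- vapply(spans, function(s) sum(profile[chains %in% s]), numeric(1))
  c(sums, remainder = sum(profile[!(chains %in% all_chains)]))
}

#' Modal chain length (Cmax)
#'
#' The chain with the greatest concentration, optionally restricted to a
#' chain range (e.g. `c(15, 20)` to ask for the short-chain maximum). Exact
#' ties break toward the lower chain.
#'
#' @inheritParams cpi
#' @param restrict Optional inclusive `c(lo, hi)` chain range.
#' @return Integer chain length, or `NA` when every chain in the (restricted)
#'   range is zero.
#' @export
cmax <- function(profile, restrict = NULL) {
  .check_profile(profile)
  chains <- as.integer(names(profile))
  ord <- order(chains)
  chains <- chains[ord]
  conc <- unname(profile[ord])
  if (!is.null(restrict)) {
    keep <- chains >= restrict[1] & chains <= restrict[2]
    chains <- chains[keep]
    conc <- conc[keep]
  }
  if (length(conc) == 0 || all(conc == 0)) return(NA_integer_)
  chains[which.max(conc)]  # first maximum = lowest chain on ties
}

#' Even-over-odd predominance of an n-alkanol profile
#'
#' n-Alkanols from plant waxes are even-carbon dominated; this index is the
#' even/odd mirror of the n-alkane CPI, a derived convenience metric:
#' \deqn{EOP = \frac{2 (C_{22}+C_{24}+C_{26}+C_{28}+C_{30})}{(C_{21}+C_{23}+C_{25}+C_{27}+C_{29}) + (C_{23}+C_{25}+C_{27}+C_{29}+C_{31})}}
#'
#' @param profile Named numeric alkanol concentration vector indexed by
#'   chain length (C12-C36 window).
#' @return The even-over-odd index, or `NA` when the odd-chain denominator
#'   is zero.
#' @export
alkanol_eop <- function(profile) {
  .check_profile(profile)
  num <- 2 * sum(vapply(c(22, 24, 26, 28, 30), .chain,
                        numeric(1), profile = profile))
  den <- sum(vapply(c(21, 23, 25, 27, 29), .chain,
                    numeric(1), profile = profile)) +
         sum(vapply(c(23, 25, 27, 29, 31), .chain,
                    numeric(1), profile = profile))
  if (den == 0) return(NA_real_)
  num / den
}

#' All n-alkane indices of one profile
#'
#' Computes CPI, ACL, Paq, the C23/C29, C25/C29 and C23/C25 ratios, the
#' chain-class sums and the modal chain in one pass. Undefined indices are
#' `NA` and their reasons are collected in the `flags` field
#' (`"<index>:zero_denominator"` tags, semicolon-separated).
#'
#' @inheritParams chain_class_sums
#' @return One-row data frame with columns `cpi`, `acl`, `paq`, `r23_29`,
#'   `r25_29`, `r23_25`, `short_sum`, `mid_sum`, `long_sum`, `remainder_sum`,
#'   `cmax`, `flags`.
#' @export
index_set <- function(profile, boundaries = default_chain_boundaries()) {
  sums <- chain_class_sums(profile, boundaries)
  out <- data.frame(
    cpi = cpi(profile),
    acl = acl(profile),
    paq = paq(profile),
    r23_29 = chain_ratio(profile, 23, 29),
    r25_29 = chain_ratio(profile, 25, 29),
    r23_25 = chain_ratio(profile, 23, 25),
    short_sum = unname(sums["short"]),
    mid_sum = unname(sums["mid"]),
    long_sum = unname(sums["long"]),
    remainder_sum = unname(sums["remainder"]),
    cmax = cmax(profile),
    stringsAsFactors = FALSE)
  undef <- c("cpi", "acl", "paq", "r23_29", "r25_29", "r23_25", "cmax")
  flagged <- undef[vapply(undef, function(f) is.na(out[[f]]), logical(1))]
  tag <- function(f) paste0(f, if (f == "cmax") ":all_zero"
                               else ":zero_denominator")
  out$flags <- paste(vapply(flagged, tag, character(1)), collapse = ";")
  out
}

#' Mid-chain summary statistics
#'
#' Mean (and range) of the mid-chain concentrations, either over the two
#' Sphagnum-diagnostic odd chains C23 and C25 (`odd_only = TRUE`, default)
#' or over every chain in the mid range including C24.
#'
#' @inheritParams chain_class_sums
#' @param odd_only Restrict to odd chains within the mid range.
#' @return Named vector `c(mean, min, max)` in the units of the profile.
#' @export
mid_chain_stats <- function(profile,
                            boundaries = default_chain_boundaries(),
                            odd_only = TRUE) {
  .check_profile(profile)
  span <- seq(boundaries$mid[1], boundaries$mid[2])
  if (odd_only) span <- span[span %% 2 == 1]
  conc <- vapply(span, .chain, numeric(1), profile = profile)
  c(mean = mean(conc), min = min(conc), max = max(conc))
}

#' Per-sample n-alkane indices for a whole table
#'
#' Applies [index_set()] to the alkane profile of every sample in a
#' concentration table; when the table carries alkanol records the
#' even-over-odd alkanol index ([alkanol_eop()]) is appended.
#'
#' @param table A [conc_table].
#' @param boundaries Chain-class boundaries, see
#'   [default_chain_boundaries()].
#' @param nondetect_sub Substitution value for non-detect records.
#' @return Data frame with one row per sample: the sample key columns
#'   followed by the [index_set()] columns (and `alkanol_eop` when alkanol
#'   data are present).
#' @export
alkane_indices <- function(table, boundaries = default_chain_boundaries(),
                           nondetect_sub = 0) {
  keys <- sample_keys(table)
  has_alkanol <- any(table$compound_class == "alkanol")
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    prof <- compound_profile(table, keys$site[i], keys$depth_cm[i],
                             keys$replicate[i], "alkane",
                             nondetect_sub = nondetect_sub, quiet = TRUE)
    idx <- index_set(prof, boundaries)
    if (has_alkanol) {
      aprof <- compound_profile(table, keys$site[i], keys$depth_cm[i],
                                keys$replicate[i], "alkanol",
                                nondetect_sub = nondetect_sub, quiet = TRUE)
      idx$alkanol_eop <- if (any(aprof > 0)) alkanol_eop(aprof) else NA_real_
    }
    cbind(keys[i, , drop = FALSE], idx)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
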