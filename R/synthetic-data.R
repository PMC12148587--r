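## End-member mixing simulator. Generates concentration tables with the
## statistical structure the analysis assumes: source end-members with
## field-anchored modal chains (algal C17, hollow Sphagnum C23, hummock
## Sphagnum C25, vascular C29/C31), strong odd-over-even predominance for
## alkanes (even-over-odd for alkanols), a mass-conserving decomposition
## operator that erodes the odd/even contrast (and hence CPI), and
## multiplicative lognormal noise mimicking strictly positive,
## heteroscedastic GC-MS quantification error.

# evaluate expr under a temporary RNG state; the caller's stream is restored
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      else suppressWarnings(rm(".Random.seed", envir = globalenv()))
    })
    set.seed(seed)
  }
  expr
}

#' End-member chain-length templates
#'
#' Normalised n-alkane chain-length distributions (C14-C35, summing to 1)
#' for the four organic-matter sources the mixing simulator draws from:
#' `algal_bacterial` (modal C17), `sphagnum_hollow` (modal C23),
#' `sphagnum_hummock` (modal C25) and `vascular` (modal C31, shoulder at
#' C29). Each template is a triangular distribution around its modal chain
#' with even chains suppressed by `odd_even_contrast` (default 10:1, which
#' puts the CPI of fresh material in the mid-teens, the range typical of
#' little-decomposed peat). The exact template numbers are simulator
#' constants, not measured values.
#'
#' @param odd_even_contrast Odd:even concentration contrast (> 1).
#' @return Named list of four normalised numeric vectors indexed by chain
#'   length.
#' @export
end_member_templates <- function(odd_even_contrast = 10) {
  stopifnot(odd_even_contrast > 1)
  tri <- function(mode, width) {
    t <- pmax(0, 1 - abs(ALKANE_CHAINS - mode) / width)
    t[ALKANE_CHAINS %% 2 == 0] <- t[ALKANE_CHAINS %% 2 == 0] /
      odd_even_contrast
    stats::setNames(t / sum(t), ALKANE_CHAINS)
  }
  list(algal_bacterial = tri(17, 3),
       sphagnum_hollow = tri(23, 3),
       sphagnum_hummock = tri(25, 3),
       vascular = tri(31, 5))
}

#' Decomposition operator on an n-alkane profile
#'
#' Models degradation as odd-to-even mass transfer: each odd chain n loses
#' `extent * Cn`, and half of the lost mass is added to each adjacent even
#' chain (n-1, n+1). At the window edge the whole lost half that would fall
#' outside C14-C35 goes to the in-window neighbour, so total alkane mass is
#' conserved exactly. The operator erodes the odd/even contrast, so CPI
#' strictly decreases for any profile with positive odd mass; total mass is
#' untouched because CPI - the degradation proxy - responds to the odd/even
#' contrast, not to mass loss.
#'
#' @param profile Named numeric vector over chains 14-35.
#' @param extent Fraction of each odd chain lost, in \[0, 1).
#' @return The transformed profile (same names, same total).
#' @export
apply_decomposition <- function(profile, extent) {
  .check_profile(profile)
  if (length(extent) != 1 || is.na(extent) || extent < 0 || extent >= 1) {
    stop("value error: extent must lie in [0, 1)", call. = FALSE)
  }
  chains <- as.integer(names(profile))
  out <- profile
  for (n in chains[chains %% 2 == 1]) {
    lost <- extent * profile[as.character(n)]
    if (lost == 0) next
    out[as.character(n)] <- out[as.character(n)] - lost
    lo <- as.character(n - 1)
    hi <- as.character(n + 1)
    lo_in <- lo %in% names(out)
    hi_in <- hi %in% names(out)
    if (lo_in && hi_in) {
      out[lo] <- out[lo] + lost / 2
      out[hi] <- out[hi] + lost / 2
    } else if (lo_in) {
      out[lo] <- out[lo] + lost
    } else if (hi_in) {
      out[hi] <- out[hi] + lost
    } else {
      out[as.character(n)] <- out[as.character(n)] + lost  # nothing adjacent
    }
  }
  out
}

#' Generate one synthetic n-alkane profile
#'
#' Mixes the end-member templates with the given weights, scales to
#' `total_mass`, applies [apply_decomposition()], then multiplies each chain
#' by lognormal noise with `sdlog = noise_sigma` (meanlog chosen as
#' `-noise_sigma^2/2` so the noise has unit mean). Deterministic for a fixed
#' seed.
#'
#' @param weights Named fractions over the end members of
#'   [end_member_templates()]; must be non-negative and sum to 1.
#' @param total_mass Total alkane mass of the noise-free profile (ug/g).
#' @param decomposition_extent Passed to [apply_decomposition()].
#' @param noise_sigma Lognormal sigma (0 = noise-free).
#' @param seed Optional integer seed.
#' @param templates End-member templates.
#' @return Named numeric profile over chains 14-35.
#' @examples
#' p <- generate_profile(c(vascular = 1), noise_sigma = 0, seed = 1)
#' paq(p)   # < 0.1: pure terrestrial end-member
#' @export
generate_profile <- function(weights, total_mass = 500,
                             decomposition_extent = 0, noise_sigma = 0,
                             seed = NULL,
                             templates = end_member_templates()) {
  if (is.null(names(weights)) ||
      !all(names(weights) %in% names(templates))) {
    stop("value error: weights must be named after end members: ",
         paste(names(templates), collapse = ", "), call. = FALSE)
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("value error: weights must be >= 0 and sum to 1", call. = FALSE)
  }
  stopifnot(total_mass > 0, noise_sigma >= 0)
  mix <- Reduce(`+`, Map(function(w, nm) w * templates[[nm]],
                         weights, names(weights)))
  prof <- apply_decomposition(total_mass * mix, decomposition_extent)
  if (noise_sigma > 0) {
    prof <- .with_seed(seed, prof * stats::rlnorm(
      length(prof), meanlog = -noise_sigma^2 / 2, sdlog = noise_sigma))
  }
  prof
}

#' Default six-site, three-depth study design
#'
#' Mirrors the layout of a two-sites-per-location bog survey: a drained and
#' an extracted degraded site (AV-D, AV-ED), two near-natural sites (PU-N,
#' BK-N) and two extracted-and-restored sites (PI-ER, BK-ER), each sampled
#' at 10, 30 and 80 cm.
#'
#' @return Data frame with columns `site`, `status`, `depth_cm`,
#'   `replicate`.
#' @export
default_design <- function() {
  sites <- data.frame(
    site = c("AV-D", "AV-ED", "PU-N", "PI-ER", "BK-N", "BK-ER"),
    status = c("degraded_drained", "degraded_extracted", "natural",
               "restored", "natural", "restored"),
    stringsAsFactors = FALSE)
  out <- merge(sites, data.frame(depth_cm = c(10L, 30L, 80L)))
  out$replicate <- 1L
  out[order(out$site, out$depth_cm), c("site", "status", "depth_cm",
                                       "replicate")]
}

#' Synthetic site metadata for the default design
#'
#' pH and mean water-table levels follow the six study-site conditions
#' (degraded sites deeply drained, natural/restored sites near-surface); the
#' max/min excursions around each mean are synthetic simulator constants.
#'
#' @return Data frame in the [read_site_metadata()] layout.
#' @export
default_site_metadata <- function() {
  data.frame(
    site = c("AV-D", "AV-ED", "PU-N", "PI-ER", "BK-N", "BK-ER"),
    ph = c(4.3, 4.3, 4.12, 4.23, 3.75, 3.75),
    wtl_mean_cm = c(-43, -50, -17, -7, -11, -18),
    stringsAsFactors = FALSE) |>
    transform(wtl_max_cm = wtl_mean_cm + 8,
              wtl_min_cm = wtl_mean_cm - 15)
}

# status-dependent simulator defaults: degraded sites carry less biomarker
# mass, are vascular-dominated and more decomposed; restored ~ natural
.status_defaults <- function() {
  list(
    scale = c(natural = 1, restored = 1,
              degraded_drained = 0.3, degraded_extracted = 0.3),
    weights = list(
      natural = c(sphagnum_hollow = 0.35, sphagnum_hummock = 0.25,
                  vascular = 0.30, algal_bacterial = 0.10),
      restored = c(sphagnum_hollow = 0.35, sphagnum_hummock = 0.25,
                   vascular = 0.30, algal_bacterial = 0.10),
      degraded_drained = c(sphagnum_hollow = 0.05, sphagnum_hummock = 0.10,
                           vascular = 0.80, algal_bacterial = 0.05),
      degraded_extracted = c(sphagnum_hollow = 0.05, sphagnum_hummock = 0.10,
                             vascular = 0.80, algal_bacterial = 0.05)),
    decomposition = c(natural = 0.05, restored = 0.05,
                      degraded_drained = 0.25, degraded_extracted = 0.25))
}

# fixed marker block templates (ug/g at status scale 1)
.sterol_template <- c(sitosterol = 900, stigmastanol = 210,
                      campesterol = 340, stigmasterol = 310,
                      brassicasterol = 70, ergosterol = 8)
.hopanoid_template <- c("17a(H),21b(H)-hopane" = 30,
                        "17b(H),21b(H)-hopane" = 10,
                        "17a(H),21b(H)-hopanol" = 20,
                        "17b(H),21b(H)-hopanol" = 25,
                        "diploptene" = 8)
.archaeol_base <- 15

# even-dominated alkanol template over C12-C36, modal C22
.alkanol_template <- function(odd_even_contrast = 10) {
  t <- pmax(0, 1 - abs(ALKANOL_CHAINS - 22) / 6)
  t[ALKANOL_CHAINS %% 2 == 1] <- t[ALKANOL_CHAINS %% 2 == 1] /
    odd_even_contrast
  stats::setNames(t / sum(t), ALKANOL_CHAINS)
}

#' Generate a full synthetic concentration table
#'
#' One n-alkane profile per design row (status-dependent mixing weights,
#' total mass and decomposition extent), plus optional even-dominated
#' alkanol, sterol, hopanoid and archaeol blocks whose masses scale with the
#' same status factors (degraded < natural ~ restored). Fully seeded: the
#' same seed reproduces the table exactly.
#'
#' @param design Data frame with columns `site`, `status`, `depth_cm` and
#'   optionally `replicate`; see [default_design()].
#' @param seed Optional integer seed.
#' @param total_mass Noise-free total alkane mass at status scale 1 (ug/g).
#' @param noise_sigma Lognormal noise sigma applied to every concentration.
#' @param status_scale Named mass scale factor per status.
#' @param status_weights Named list of end-member weight vectors per status.
#' @param status_decomposition Named decomposition extent per status.
#' @param include_alkanols,include_markers Include the alkanol and
#'   sterol/hopanoid/archaeol blocks.
#' @return A [conc_table] with provenance `"synthetic"`.
#' @export
generate_dataset <- function(design = default_design(), seed = NULL,
                             total_mass = 500, noise_sigma = 0.2,
                             status_scale = .status_defaults()$scale,
                             status_weights = .status_defaults()$weights,
                             status_decomposition =
                               .status_defaults()$decomposition,
                             include_alkanols = TRUE,
                             include_markers = TRUE) {
  stopifnot(nrow(design) > 0,
            all(c("site", "status", "depth_cm") %in% names(design)))
  if (!"replicate" %in% names(design)) design$replicate <- 1L
  key <- do.call(paste, c(design[c("site", "depth_cm", "replicate")],
                          sep = "\r"))
  if (anyDuplicated(key)) {
    stop("integrity error: duplicate sample keys in design", call. = FALSE)
  }
  .with_seed(seed, {
    blocks <- lapply(seq_len(nrow(design)), function(i) {
      st <- design$status[i]
      if (!st %in% names(status_scale)) {
        stop("no simulator parameters for status '", st, "'", call. = FALSE)
      }
      scale <- status_scale[[st]]
      noise <- function(n) if (noise_sigma > 0) {
        stats::rlnorm(n, -noise_sigma^2 / 2, noise_sigma)
      } else rep(1, n)
      prof <- generate_profile(status_weights[[st]],
                               total_mass = total_mass * scale,
                               decomposition_extent =
                                 status_decomposition[[st]],
                               noise_sigma = 0)
      prof <- prof * noise(length(prof))
      rec <- function(class, compound, conc) {
        data.frame(site = design$site[i], status = st,
                   depth_cm = design$depth_cm[i],
                   replicate = design$replicate[i], compound_class = class,
                   compound = compound, concentration = conc,
                   detect = TRUE, stringsAsFactors = FALSE)
      }
      out <- rec("alkane", paste0("C", names(prof)), unname(prof))
      if (include_alkanols) {
        al <- 2 * total_mass * scale * .alkanol_template()
        al <- al * noise(length(al))
        out <- rbind(out, rec("alkanol", paste0("C", names(al)), unname(al)))
      }
      if (include_markers) {
        st_conc <- scale * .sterol_template * noise(length(.sterol_template))
        ho_conc <- scale * .hopanoid_template *
          noise(length(.hopanoid_template))
        ar <- scale * .archaeol_base *
          (design$depth_cm[i] / 80) * noise(1)
        out <- rbind(out,
                     rec("steroid", names(.sterol_template), unname(st_conc)),
                     rec("hopanoid", names(.hopanoid_template),
                         unname(ho_conc)),
                     rec("archaeol", "archaeol", unname(ar)))
      }
      out
    })
    conc_table(do.call(rbind, blocks), provenance = "synthetic")
  })
}
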