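# Sterol/stanol degradation ratio, fungal flag, hopanoid stereochemistry
# and the archaeol-water-table consistency rule.

test_that("stanol/sterol ratio follows the printed worked example", {
  prof <- c(stigmastanol = 208, sitosterol = 895)
  expect_equal(stanol_sterol_ratio(prof), 208 / 895, tolerance = 1e-12)
  expect_true(is.na(stanol_sterol_ratio(c(stigmastanol = 10))))
  expect_equal(stanol_sterol_ratio(c(sitosterol = 10)), 0)
  # scale invariance and monotonicity in the stanol
  expect_equal(stanol_sterol_ratio(1000 * prof), stanol_sterol_ratio(prof))
  r <- vapply(seq(0, 400, by = 50), function(s)
    stanol_sterol_ratio(c(stigmastanol = s, sitosterol = 895)), numeric(1))
  expect_true(all(diff(r) > 0))
  # alternate pair
  expect_equal(stanol_sterol_ratio(c(campestanol = 5, campesterol = 10),
                                   "campestanol", "campesterol"), 0.5)
})

test_that("the worked stanol/sterol value is recovered from the shipped table", {
  path <- system.file("extdata", "printed_steroids_subset.csv",
                      package = "peatlipid")
  tab <- read_conc_table(path)
  prof <- compound_profile(tab, "AV-D", 10, compound_class = "steroid",
                           quiet = TRUE)
  expect_equal(stanol_sterol_ratio(prof), 0.2324, tolerance = 1e-4)
  expect_false(fungal_marker_flag(prof))  # ergosterol printed as non-detect
  pun <- compound_profile(tab, "PU-N", 30, compound_class = "steroid",
                          quiet = TRUE)
  expect_true(fungal_marker_flag(pun))
})

test_that("ergosterol flag requires detection strictly above zero", {
  expect_true(fungal_marker_flag(c(ergosterol = 82)))
  expect_false(fungal_marker_flag(c(ergosterol = 0)))
  expect_false(fungal_marker_flag(c(sitosterol = 10)))
})

test_that("hopanoid names parse to stereochemistry and type", {
  info <- hopanoid_stereochemistry(c(
    "17\u03b1(H),21\u03b2(H)-hopane", "17b(H),21b(H)-21-hopanol",
    "diploptene", "17a(H),21b(H)-hopanol"))
  expect_equal(info$stereo, c("alpha_beta", "beta_beta", "other",
                              "alpha_beta"))
  expect_equal(info$type, c("hopane", "hopanol", "hopene", "hopanol"))
})

test_that("alpha-beta fraction is bounded, scale invariant and excludes hopenes", {
  prof <- c("17a(H),21b(H)-hopane" = 3, "17b(H),21b(H)-hopane" = 1,
            "diploptene" = 100)
  expect_equal(hopane_ab_fraction(prof), 0.75)
  expect_equal(hopane_ab_fraction(10 * prof), 0.75)
  expect_equal(hopane_ab_fraction(c("17a(H),21b(H)-hopane" = 2)), 1)
  expect_equal(hopane_ab_fraction(c("17a(H),21b(H)-hopane" = 2,
                                    "17b(H),21b(H)-hopane" = 2)), 0.5)
  expect_true(is.na(hopane_ab_fraction(c(diploptene = 5))))
  withr::local_seed(5)
  for (i in 1:20) {
    p <- c("17a(H),21b(H)-hopane" = runif(1), "17b(H),21b(H)-hopane" =
             runif(1), "17a(H),21b(H)-hopanol" = runif(1))
    f <- hopane_ab_fraction(p)
    expect_gte(f, 0); expect_lte(f, 1)
  }
})

test_that("archaeol consistency respects the water-table envelope", {
  meta <- data.frame(site = "BK-N", ph = 3.75, wtl_max_cm = -11,
                     wtl_mean_cm = -20, wtl_min_cm = -35)
  # detected below the deepest excursion: permanently anoxic
  expect_equal(archaeol_wtl_consistency(TRUE, 80, meta), "consistent")
  # detected above the shallowest excursion: never saturated
  expect_equal(archaeol_wtl_consistency(TRUE, 5, meta), "inconsistent")
  # detected inside the fluctuation band: microsites possible
  expect_equal(archaeol_wtl_consistency(TRUE, 20, meta), "indeterminate")
  # absence is never evidence against anoxia
  expect_equal(archaeol_wtl_consistency(FALSE, 80, meta), "indeterminate")
  expect_equal(archaeol_wtl_consistency(FALSE, 5, meta), "consistent")
  # never inconsistent anywhere inside the band
  for (d in 11:35) {
    expect_false(archaeol_wtl_consistency(TRUE, d, meta) == "inconsistent")
  }
  expect_error(archaeol_wtl_consistency(TRUE, 10, meta[0, ]),
               "configuration error")
})

test_that("marker summaries recompute field-by-field over a synthetic table", {
  tab <- generate_dataset(seed = 99)
  meta <- default_site_metadata()
  ms <- marker_summary(tab, meta)
  expect_equal(nrow(ms), 18)
  withr::local_seed(3)
  for (i in sample(nrow(ms), 5)) {
    st <- compound_profile(tab, ms$site[i], ms$depth_cm[i], ms$replicate[i],
                           "steroid", quiet = TRUE)
    ho <- compound_profile(tab, ms$site[i], ms$depth_cm[i], ms$replicate[i],
                           "hopanoid", quiet = TRUE)
    expect_equal(ms$stanol_sterol_ratio[i], stanol_sterol_ratio(st))
    expect_equal(ms$hopane_ab_fraction[i], hopane_ab_fraction(ho))
    expect_equal(ms$fungal_flag[i], fungal_marker_flag(st))
  }
  # missing metadata is a configuration error
  expect_error(marker_summary(tab, meta[meta$site != "AV-D", ]),
               "no site metadata")
})
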