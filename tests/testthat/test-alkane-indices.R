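# n-alkane molecular indices: frozen worked examples, degenerate-input
# flags, and the scale/bound/monotonicity properties.

test_that("CPI matches hand-computed and degenerate cases", {
  flat <- setNames(rep(1, 11), 22:32)
  expect_identical(cpi(flat), 1)          # flat profile is exactly 1
  skew <- setNames(c(1, 10)[(22:32 %% 2) + 1], 22:32)  # odds 10, evens 1
  expect_equal(cpi(skew), 10)
  odd_only <- setNames(rep(2, 5), c(23, 25, 27, 29, 31))
  expect_true(is.na(cpi(odd_only)))       # zero even-chain denominator
})

test_that("ACL is the abundance-weighted mean odd chain length", {
  expect_equal(acl(c(`31` = 5)), 31)
  expect_equal(acl(c(`23` = 1, `33` = 1)), 28)
  expect_equal(acl(setNames(rep(3, 6), c(23, 25, 27, 29, 31, 33))), 28)
  expect_true(is.na(acl(c(`24` = 10))))   # no odd chains present
})

test_that("Paq covers its two degenerate corners and the interior", {
  expect_equal(paq(c(`29` = 3, `31` = 2)), 0)
  expect_equal(paq(c(`23` = 3, `25` = 2)), 1)
  expect_equal(paq(c(`23` = 2, `25` = 2, `29` = 1, `31` = 1)), 2 / 3)
  expect_true(is.na(paq(c(`27` = 5))))
})

test_that("chain ratios, class sums and cmax follow their definitions", {
  p <- c(`17` = 5, `23` = 39, `25` = 41, `29` = 2)
  expect_equal(chain_ratio(p, 23, 29), 19.5)
  expect_equal(chain_ratio(p, 27, 29), 0)
  expect_true(is.na(chain_ratio(p, 23, 27)))
  expect_error(chain_ratio(p, 23, 40), "14-35")

  sums <- chain_class_sums(p)
  expect_equal(unname(sums[c("short", "mid", "long")]), c(5, 80, 2))
  all1 <- setNames(rep(1, 22), 14:35)
  expect_equal(unname(chain_class_sums(all1)[c("short", "mid", "long",
                                               "remainder")]),
               c(6, 3, 9, 4))
  expect_error(
    chain_class_sums(p, list(short = c(15, 23), mid = c(23, 25),
                             long = c(27, 35))), "overlap")

  expect_equal(cmax(p), 25)
  expect_equal(cmax(p, restrict = c(15, 20)), 17)
  expect_equal(cmax(c(`29` = 3, `31` = 3)), 29)  # ties break low
  expect_true(is.na(cmax(c(`23` = 0))))
})

test_that("alkanol even-over-odd index mirrors the CPI identity", {
  flat <- setNames(rep(1, 11), 21:31)
  expect_equal(alkanol_eop(flat), 1)
  skew <- setNames(c(1, 10)[(21:31 %% 2 == 0) + 1], 21:31)
  expect_equal(alkanol_eop(skew), 10)
  expect_true(is.na(alkanol_eop(c(`22` = 5, `24` = 5))))
})

test_that("index formulas agree with independent transcriptions", {
  withr::local_seed(101)
  for (i in 1:200) {
    p <- random_profile()
    expect_equal(cpi(p), oracle_cpi(p), tolerance = 1e-12)
    expect_equal(acl(p), oracle_acl(p), tolerance = 1e-12)
    expect_equal(paq(p), oracle_paq(p), tolerance = 1e-12)
    expect_equal(chain_ratio(p, 23, 29),
                 unname(p["23"] / p["29"]), tolerance = 1e-12)
  }
})

test_that("indices are scale invariant and bounded", {
  withr::local_seed(7)
  for (i in 1:25) {
    p <- random_profile()
    for (k in c(1e-3, 1, 1000)) {
      s <- index_set(k * p)
      b <- index_set(p)
      for (f in c("cpi", "acl", "paq", "r23_29", "r25_29", "r23_25")) {
        expect_equal(s[[f]], b[[f]], tolerance = 1e-12)
      }
      expect_equal(s$mid_sum, k * b$mid_sum, tolerance = 1e-12)
    }
    expect_gte(b$paq, 0); expect_lte(b$paq, 1)
    expect_gte(b$acl, 23); expect_lte(b$acl, 33)
  }
})

test_that("Paq rises with C23 and CPI falls with added even-chain mass", {
  p <- c(`23` = 1, `25` = 2, `29` = 3, `31` = 1)
  paqs <- vapply(seq(1, 10, by = 0.5), function(c23) {
    p["23"] <- c23; paq(p)
  }, numeric(1))
  expect_true(all(diff(paqs) > 0))

  q <- setNames(rep(1, 5), c(23, 25, 27, 29, 31))
  cpis <- vapply(seq(0.25, 5, by = 0.25), function(ev) {
    cpi(c(q, `24` = ev, `28` = ev))
  }, numeric(1))
  expect_true(all(diff(cpis) < 0))
})

test_that("undefined indices are flagged, not raised", {
  even_only <- c(`22` = 1, `24` = 2)
  s <- index_set(even_only)
  expect_true(is.na(s$paq) && is.na(s$acl))
  expect_match(s$flags, "paq:zero_denominator")
  expect_match(s$flags, "acl:zero_denominator")
  expect_false(grepl("cpi:", s$flags))    # CPI is defined (0) here
})

test_that("per-table batch indices match per-profile computation", {
  withr::local_seed(21)
  tab <- random_table()
  idx <- alkane_indices(tab)
  expect_equal(nrow(idx), 3)
  for (i in seq_len(nrow(idx))) {
    prof <- compound_profile(tab, idx$site[i], idx$depth_cm[i],
                             idx$replicate[i], quiet = TRUE)
    expect_equal(idx$cpi[i], cpi(prof))
    expect_equal(idx$paq[i], paq(prof))
  }
})

test_that("mid-chain statistics expose both the odd-only and full-range mean", {
  p <- c(`23` = 39, `24` = 10, `25` = 41)
  expect_equal(unname(mid_chain_stats(p)["mean"]), 40)
  expect_equal(unname(mid_chain_stats(p, odd_only = FALSE)["mean"]), 30)
})
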