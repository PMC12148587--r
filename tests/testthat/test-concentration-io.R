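# Long-table reading, validation, non-detect policy and round-tripping.

test_that("single rows parse with correct values and non-detect sentinels", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,status,depth_cm,replicate,compound_class,compound,concentration",
               "AV-D,degraded_drained,10,1,alkane,C23,39.0"), path)
  tab <- read_conc_table(path)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$concentration, 39)
  expect_true(tab$detect)

  writeLines(c("site,status,depth_cm,replicate,compound_class,compound,concentration",
               "AV-D,degraded_drained,10,1,alkane,C23,ND"), path)
  nd <- read_conc_table(path)
  expect_false(nd$detect)
  expect_true(is.na(nd$concentration))
})

test_that("schema, value and integrity errors are raised with context", {
  path <- withr::local_tempfile(fileext = ".csv")
  # missing column
  writeLines(c("site,status,depth_cm,replicate,compound_class,compound",
               "AV-D,degraded_drained,10,1,alkane,C23"), path)
  expect_error(read_conc_table(path), "concentration")
  # negative concentration with row index
  writeLines(c("site,status,depth_cm,replicate,compound_class,compound,concentration",
               "AV-D,degraded_drained,10,1,alkane,C23,-5"), path)
  expect_error(read_conc_table(path), "negative concentration at row")
  # duplicate (sample, compound)
  writeLines(c("site,status,depth_cm,replicate,compound_class,compound,concentration",
               "AV-D,degraded_drained,10,1,alkane,C23,39",
               "AV-D,degraded_drained,10,1,alkane,C23,40"), path)
  expect_error(read_conc_table(path), "duplicate")
  # decimal comma must be a schema error, not a silent misparse
  writeLines(c("site,status,depth_cm,replicate,compound_class,compound,concentration",
               '"AV-D",degraded_drained,10,1,alkane,C23,"39,5"'), path)
  expect_error(read_conc_table(path), "decimal comma")
  # chain outside the class window
  expect_error(conc_table(transform(tiny_table_df(), compound = "C40")),
               "C14-C35")
  expect_error(conc_table(tiny_table_df()[0, ]), "at least one record")
})

test_that("write/read round-trips any valid table record-for-record", {
  withr::local_seed(11)
  tab <- random_table()
  # add a non-detect and a named-compound record to cover both branches
  extra <- data.frame(site = "S-N", status = "natural", depth_cm = 10L,
                      replicate = 1L,
                      compound_class = c("steroid", "archaeol"),
                      compound = c("sitosterol", "archaeol"),
                      concentration = c(NA, 12.345678901234567),
                      detect = c(FALSE, TRUE), stringsAsFactors = FALSE)
  tab <- conc_table(rbind(as.data.frame(tab), extra))
  path <- withr::local_tempfile(fileext = ".csv")
  write_conc_table(tab, path)
  back <- read_conc_table(path)
  records <- function(t) {
    d <- as.data.frame(t)
    attr(d, "provenance") <- NULL
    class(d) <- "data.frame"
    d
  }
  expect_equal(records(back), records(tab))
})

test_that("wide reader normalises to the canonical long layout", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,status,depth_cm,replicate,C23,C25,C29",
               "PU-N,natural,10,1,5,3,ND"), path)
  tab <- read_conc_wide(path)
  expect_equal(nrow(tab), 3)
  expect_equal(sort(tab$compound), c("C23", "C25", "C29"))
  expect_equal(sum(!tab$detect), 1)
  prof <- compound_profile(tab, "PU-N", 10, quiet = TRUE)
  expect_equal(unname(prof[c("23", "25", "29")]), c(5, 3, 0))
})

test_that("site metadata enforces pH range and water-table ordering", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,ph,wtl_max_cm,wtl_mean_cm,wtl_min_cm",
               "AV-D,4.3,,-43,", "BK-ER,3.75,-5,-18,-35"), path)
  meta <- read_site_metadata(path)
  expect_equal(meta$wtl_mean_cm, c(-43, -18))
  expect_true(is.na(meta$wtl_max_cm[1]))

  writeLines(c("site,ph,wtl_max_cm,wtl_mean_cm,wtl_min_cm",
               "X,15,-5,-18,-35"), path)
  expect_error(read_site_metadata(path), "ph")
  writeLines(c("site,ph,wtl_max_cm,wtl_mean_cm,wtl_min_cm",
               "X,4,-35,-18,-5"), path)
  expect_error(read_site_metadata(path), "ordering")
})

test_that("non-detect substitution is explicit and logged", {
  df <- tiny_table_df()
  df$concentration[2] <- NA
  df$detect <- c(TRUE, FALSE, TRUE)
  tab <- conc_table(df)
  expect_message(
    prof <- compound_profile(tab, "AV-D", 10, compound_class = "alkane"),
    "substituted 1 non-detect")
  expect_equal(unname(prof["25"]), 0)
  prof9 <- compound_profile(tab, "AV-D", 10, nondetect_sub = 9, quiet = TRUE)
  expect_equal(unname(prof9["25"]), 9)
})
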