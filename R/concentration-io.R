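## Reading, validating and writing long-format lipid concentration tables.
## The long table is the canonical exchange format for every other module:
## one row per (sample, compound), concentrations in ug/g dry weight,
## non-detects kept as explicit flags rather than silently dropped or zeroed.

#' Construct and validate a concentration table
#'
#' A concentration table is a data frame with one row per quantified analyte
#' in one physical subsample. Columns: `site` (code), `status` (one of
#' `natural`, `restored`, `degraded_drained`, `degraded_extracted`),
#' `depth_cm` (positive integer, cm below surface), `replicate` (integer >=
#' 1), `compound_class` (`alkane`, `alkanol`, `steroid`, `triterpenoid`,
#' `hopanoid`, `archaeol`), `compound` (chain label such as `"C23"` for
#' aliphatics, free-text analyte name otherwise), `concentration` (ug/g dry
#' weight, `NA` for non-detects) and `detect` (logical, `FALSE` for
#' non-detects).
#'
#' @param records Data frame with the columns above (`detect` optional; it
#'   defaults to `!is.na(concentration)`).
#' @param provenance Free-text source tag stored as an attribute.
#' @return The validated table, classed `conc_table`.
#' @examples
#' tab <- conc_table(data.frame(
#'   site = "AV-D", status = "degraded_drained", depth_cm = 10, replicate = 1,
#'   compound_class = "alkane", compound = "C23", concentration = 39))
#' print(tab)
#' @export
conc_table <- function(records, provenance = "in-memory") {
  stopifnot(is.data.frame(records))
  if (!"detect" %in% names(records)) {
    records$detect <- !is.na(records$concentration)
  }
  missing <- setdiff(c(.table_cols, "detect"), names(records))
  if (length(missing) > 0) {
    stop("concentration table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  records <- records[, c(.table_cols, "detect")]
  records$site <- as.character(records$site)
  records$compound <- as.character(records$compound)
  records$compound_class <- as.character(records$compound_class)
  records$depth_cm <- as.integer(records$depth_cm)
  records$replicate <- as.integer(records$replicate)
  records$concentration <- as.numeric(records$concentration)
  rownames(records) <- NULL
  validate_conc_table(records)
  structure(records, class = c("conc_table", "data.frame"),
            provenance = provenance)
}

#' Validate concentration table invariants
#'
#' Checks the structural invariants of a long concentration table: at least
#' one record, status and compound-class vocabularies, positive depths,
#' replicate >= 1, non-negative detected concentrations, `NA` concentration
#' exactly for non-detects, chain lengths inside the per-class windows
#' (alkanes C14-C35, alkanols C12-C36), and no duplicate (sample, compound)
#' pairs.
#'
#' @param records Data frame of concentration records.
#' @return Invisibly `TRUE`; otherwise an error describing the violation.
#' @export
validate_conc_table <- function(records) {
  if (nrow(records) == 0) {
    stop("concentration table must contain at least one record", call. = FALSE)
  }
  bad_status <- setdiff(unique(records$status), STATUS_LEVELS)
  if (length(bad_status) > 0) {
    stop("unknown status label(s): ", paste(bad_status, collapse = ", "),
         call. = FALSE)
  }
  bad_class <- setdiff(unique(records$compound_class), COMPOUND_CLASSES)
  if (length(bad_class) > 0) {
    stop("unknown compound_class value(s): ",
         paste(bad_class, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(records$depth_cm)) || any(records$depth_cm <= 0)) {
    stop("depth_cm must be a positive integer (cm below surface)",
         call. = FALSE)
  }
  if (any(is.na(records$replicate)) || any(records$replicate < 1)) {
    stop("replicate must be an integer >= 1", call. = FALSE)
  }
  neg <- which(records$detect & (is.na(records$concentration) |
                                 records$concentration < 0))
  if (length(neg) > 0) {
    stop("detected records must carry a concentration >= 0; offending row(s): ",
         paste(utils::head(neg, 5), collapse = ", "), call. = FALSE)
  }
  nd_bad <- which(!records$detect & !is.na(records$concentration))
  if (length(nd_bad) > 0) {
    stop("non-detect records must not carry a numeric value; row(s): ",
         paste(utils::head(nd_bad, 5), collapse = ", "), call. = FALSE)
  }
  .check_chain_windows(records)
  key <- do.call(paste, c(records[c(.sample_cols, "compound_class",
                                    "compound")], sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("duplicate (sample, compound) pair(s) at row(s): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

.check_chain_windows <- function(records) {
  for (cls in c("alkane", "alkanol")) {
    rows <- records$compound_class == cls
    if (!any(rows)) next
    chains <- .parse_chain(records$compound[rows])
    window <- if (cls == "alkane") ALKANE_CHAINS else ALKANOL_CHAINS
    bad <- is.na(chains) | !(chains %in% window)
    if (any(bad)) {
      stop(cls, " compounds must be chain labels C", min(window), "-C",
           max(window), "; offending label(s): ",
           paste(utils::head(unique(records$compound[rows][bad]), 5),
                 collapse = ", "), call. = FALSE)
    }
  }
  named <- records$compound_class %in% c("steroid", "triterpenoid",
                                         "hopanoid", "archaeol")
  if (any(named & !nzchar(trimws(records$compound)))) {
    stop("steroid/triterpenoid/hopanoid/archaeol records need a non-empty ",
         "compound name", call. = FALSE)
  }
  invisible(TRUE)
}

# "C23" -> 23L; anything that is not C<digits> -> NA
.parse_chain <- function(x) {
  out <- rep(NA_integer_, length(x))
  ok <- grepl("^C[0-9]+$", x)
  out[ok] <- as.integer(sub("^C", "", x[ok]))
  out
}

#' Read a long-format concentration table from CSV
#'
#' Expects an RFC-4180 CSV (UTF-8, header mandatory) with columns
#' `site,status,depth_cm,replicate,compound_class,compound,concentration`.
#' Configurable non-detect tokens in the concentration column (by default
#' `""`, `"ND"`, `"-"` and the en dash) become flagged non-detect records.
#' Decimal commas are rejected rather than silently misparsed.
#'
#' @param path Path to the CSV file.
#' @param nondetect_tokens Character vector of concentration-cell tokens to
#'   interpret as non-detects.
#' @return A [conc_table] with `provenance = path`.
#' @seealso [write_conc_table()] for the inverse, [read_conc_wide()] for
#'   wide (compound-per-column) layouts.
#' @export
read_conc_table <- function(path,
                            nondetect_tokens = c("", "ND", "-", "\u2013")) {
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = TRUE, fileEncoding = "UTF-8")
  missing <- setdiff(.table_cols, names(raw))
  if (length(missing) > 0) {
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  conc_raw <- trimws(raw$concentration)
  nd <- conc_raw %in% nondetect_tokens
  if (any(grepl(",", conc_raw[!nd]))) {
    bad <- which(!nd & grepl(",", conc_raw))
    stop("schema error: decimal comma in concentration at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (decimal point required)", call. = FALSE)
  }
  conc <- suppressWarnings(as.numeric(conc_raw))
  unparsed <- which(!nd & is.na(conc))
  if (length(unparsed) > 0) {
    stop("value error: unparseable concentration at row(s) ",
         paste(utils::head(unparsed, 5), collapse = ", "), call. = FALSE)
  }
  neg <- which(!nd & conc < 0)
  if (length(neg) > 0) {
    stop("value error: negative concentration at row(s) ",
         paste(utils::head(neg, 5), collapse = ", "), call. = FALSE)
  }
  conc[nd] <- NA_real_
  conc_table(data.frame(site = raw$site, status = raw$status,
                        depth_cm = raw$depth_cm, replicate = raw$replicate,
                        compound_class = raw$compound_class,
                        compound = raw$compound, concentration = conc,
                        detect = !nd, stringsAsFactors = FALSE),
             provenance = path)
}

#' Write a concentration table to CSV
#'
#' Non-detects are written as the token `"ND"`. Concentrations are printed
#' with enough digits (`%.17g`) that [read_conc_table()] recovers the table
#' record-for-record.
#'
#' @param table A [conc_table].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_conc_table <- function(table, path) {
  validate_conc_table(table)
  out <- as.data.frame(table)[, .table_cols]
  out$concentration <- ifelse(table$detect,
                              sprintf("%.17g", table$concentration), "ND")
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("could not write table to ", path, ": ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(path)
}

#' Read a wide (compound-per-column) concentration table
#'
#' Convenience reader for spreadsheets laid out one sample per row with one
#' column per compound (e.g. `C14`..`C35`). The result is normalised to the
#' canonical long format on load; empty or non-detect cells become flagged
#' non-detects.
#'
#' @inheritParams read_conc_table
#' @param compound_class Class assigned to every compound column.
#' @return A [conc_table].
#' @export
read_conc_wide <- function(path, compound_class = "alkane",
                           nondetect_tokens = c("", "ND", "-", "\u2013")) {
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(.sample_cols, names(raw))
  if (length(missing) > 0) {
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  compound_cols <- setdiff(names(raw), .sample_cols)
  if (length(compound_cols) == 0) {
    stop("wide table has no compound columns", call. = FALSE)
  }
  long <- do.call(rbind, lapply(compound_cols, function(cc) {
    data.frame(site = raw$site, status = raw$status, depth_cm = raw$depth_cm,
               replicate = raw$replicate, compound_class = compound_class,
               compound = cc, concentration = trimws(raw[[cc]]),
               stringsAsFactors = FALSE)
  }))
  nd <- long$concentration %in% nondetect_tokens
  conc <- suppressWarnings(as.numeric(long$concentration))
  if (any(!nd & is.na(conc))) {
    stop("value error: unparseable concentration in wide table", call. = FALSE)
  }
  long$concentration <- ifelse(nd, NA_real_, conc)
  long$detect <- !nd
  conc_table(long, provenance = path)
}

#' Read site metadata (pH and water-table summary)
#'
#' Reads a CSV with columns `site,ph,wtl_max_cm,wtl_mean_cm,wtl_min_cm`.
#' Water-table levels are signed centimetres relative to the peat surface
#' (negative = below surface), so `wtl_max_cm` is the *shallowest* excursion.
#' Sample depths elsewhere in the package are positive cm below surface; the
#' two conventions are reconciled only inside
#' [archaeol_wtl_consistency()].
#'
#' @param path Path to the metadata CSV. Missing `wtl_max_cm`/`wtl_min_cm`
#'   cells are allowed (stored as `NA`); when all three levels are present
#'   the ordering `wtl_min_cm <= wtl_mean_cm <= wtl_max_cm` is enforced.
#' @return Data frame with one row per site.
#' @export
read_site_metadata <- function(path) {
  if (!file.exists(path)) {
    stop("metadata file does not exist: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, check.names = TRUE, fileEncoding = "UTF-8",
                         stringsAsFactors = FALSE)
  need <- c("site", "ph", "wtl_max_cm", "wtl_mean_cm", "wtl_min_cm")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  raw <- raw[, need]
  for (col in need[-1]) raw[[col]] <- as.numeric(raw[[col]])
  if (any(is.na(raw$ph)) || any(raw$ph <= 0 | raw$ph >= 14)) {
    stop("value error: ph must lie in (0, 14)", call. = FALSE)
  }
  if (anyDuplicated(raw$site)) {
    stop("duplicate site code(s) in metadata", call. = FALSE)
  }
  full <- !is.na(raw$wtl_max_cm) & !is.na(raw$wtl_mean_cm) &
    !is.na(raw$wtl_min_cm)
  bad <- full & !(raw$wtl_min_cm <= raw$wtl_mean_cm &
                  raw$wtl_mean_cm <= raw$wtl_max_cm)
  if (any(bad)) {
    stop("value error: water-table ordering wtl_min <= wtl_mean <= wtl_max ",
         "violated for site(s): ", paste(raw$site[bad], collapse = ", "),
         call. = FALSE)
  }
  raw
}

#' @export
print.conc_table <- function(x, ...) {
  samp <- unique(as.data.frame(x)[, .sample_cols])
  cat("Lipid concentration table (", nrow(x), " records, ",
      nrow(samp), " samples)\n", sep = "")
  cat("  provenance: ", attr(x, "provenance"), "\n", sep = "")
  cat("  classes: ", paste(sort(unique(x$compound_class)), collapse = ", "),
      "\n", sep = "")
  nd <- sum(!x$detect)
  if (nd > 0) cat("  non-detects: ", nd, "\n", sep = "")
  NextMethod()
  invisible(x)
}

#' Extract a per-sample compound profile
#'
#' Returns the named concentration vector of one compound class for one
#' sample. For aliphatic classes (`alkane`, `alkanol`) the vector is indexed
#' by chain length over the full class window with absent chains filled with
#' 0; for named classes the vector is indexed by compound name. Non-detects
#' are substituted with `nondetect_sub` (default 0, the neutral choice for
#' ratio arithmetic: an undetected compound contributes no mass); a message
#' reports how many values were substituted.
#'
#' @param table A [conc_table].
#' @param site,depth_cm,replicate Sample key.
#' @param compound_class One compound class.
#' @param nondetect_sub Value substituted for non-detects.
#' @param quiet Suppress the substitution message.
#' @return Named numeric vector (possibly length 0 for named classes with no
#'   records).
#' @export
compound_profile <- function(table, site, depth_cm, replicate = 1,
                             compound_class = "alkane", nondetect_sub = 0,
                             quiet = FALSE) {
  compound_class <- match.arg(compound_class, COMPOUND_CLASSES)
  rows <- table$site == site & table$depth_cm == depth_cm &
    table$replicate == replicate & table$compound_class == compound_class
  sub <- as.data.frame(table)[rows, ]
  n_nd <- sum(!sub$detect)
  if (n_nd > 0 && !quiet) {
    message("substituted ", n_nd, " non-detect value(s) with ", nondetect_sub,
            " for ", site, " ", depth_cm, " cm (", compound_class, ")")
  }
  vals <- ifelse(sub$detect, sub$concentration, nondetect_sub)
  if (compound_class %in% c("alkane", "alkanol")) {
    window <- if (compound_class == "alkane") ALKANE_CHAINS else ALKANOL_CHAINS
    prof <- stats::setNames(numeric(length(window)), window)
    if (nrow(sub) > 0) {
      prof[as.character(.parse_chain(sub$compound))] <- vals
    }
    prof
  } else {
    stats::setNames(vals, sub$compound)
  }
}

#' List the unique samples in a concentration table
#'
#' @param table A [conc_table].
#' @return Data frame with columns `site`, `status`, `depth_cm`, `replicate`,
#'   one row per physical subsample.
#' @export
sample_keys <- function(table) {
  out <- unique(as.data.frame(table)[, .sample_cols])
  out <- out[order(out$site, out$depth_cm, out$replicate), ]
  rownames(out) <- NULL
  out
}
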