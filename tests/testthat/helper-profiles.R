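# Shared fixtures: random profiles and independent re-transcriptions of the
# index formulas, used as oracles against the package implementations.

random_profile <- function(chains = 14:35, max_conc = 100) {
  stats::setNames(stats::runif(length(chains), 0, max_conc), chains)
}

# direct formula transcriptions, deliberately written from the definitions
# and not sharing code with the package internals
.at <- function(p, n) {
  v <- unname(p[as.character(n)])
  if (length(v) == 0 || is.na(v)) 0 else v
}

oracle_cpi <- function(p) {
  odd <- .at(p, 23) + .at(p, 25) + .at(p, 27) + .at(p, 29) + .at(p, 31)
  ev1 <- .at(p, 22) + .at(p, 24) + .at(p, 26) + .at(p, 28) + .at(p, 30)
  ev2 <- .at(p, 24) + .at(p, 26) + .at(p, 28) + .at(p, 30) + .at(p, 32)
  if (ev1 + ev2 == 0) return(NA_real_)
  2 * odd / (ev1 + ev2)
}

oracle_acl <- function(p) {
  num <- 23 * .at(p, 23) + 25 * .at(p, 25) + 27 * .at(p, 27) +
    29 * .at(p, 29) + 31 * .at(p, 31) + 33 * .at(p, 33)
  den <- .at(p, 23) + .at(p, 25) + .at(p, 27) + .at(p, 29) + .at(p, 31) +
    .at(p, 33)
  if (den == 0) return(NA_real_)
  num / den
}

oracle_paq <- function(p) {
  den <- .at(p, 23) + .at(p, 25) + .at(p, 29) + .at(p, 31)
  if (den == 0) return(NA_real_)
  (.at(p, 23) + .at(p, 25)) / den
}

# small valid long table used across the IO tests
tiny_table_df <- function() {
  data.frame(
    site = "AV-D", status = "degraded_drained", depth_cm = 10L,
    replicate = 1L, compound_class = "alkane",
    compound = c("C23", "C25", "C29"),
    concentration = c(39, 41, 10), stringsAsFactors = FALSE)
}

random_table <- function(n_extra_sites = 2) {
  sites <- c("S-N", paste0("S-", seq_len(n_extra_sites)))
  status <- c("natural", rep("restored", n_extra_sites))
  rows <- do.call(rbind, lapply(seq_along(sites), function(i) {
    prof <- random_profile()
    data.frame(site = sites[i], status = status[i], depth_cm = 10L,
               replicate = 1L, compound_class = "alkane",
               compound = paste0("C", names(prof)),
               concentration = unname(prof), stringsAsFactors = FALSE)
  }))
  conc_table(rows)
}
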