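#' Write a per-subject metric table with a units header
#'
#' Tab-delimited text: the first line holds column names, the second a
#' `#units:`-prefixed row of units, then the data.
#'
#' @param metrics Data frame (e.g. from [flow_metric_table()]).
#' @param path Output file.
#' @param units Character vector of units, one per column.
#' @return Invisibly, `path`.
#' @export
write_metric_table <- function(metrics, path,
                               units = c(id = "-", csa = "mm^2", d = "m",
                                         u_pm = "m/s", u_max = "m/s",
                                         re_pm = "-", re_max = "-")) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(metrics), collapse = "\t"), con)
  u <- units[names(metrics)]
  u[is.na(u)] <- "-"
  writeLines(paste0("#units:\t", paste(u, collapse = "\t")), con)
  write.table(metrics, con, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a metric table written by [write_metric_table()]
#' @param path File path.
#' @return Data frame with a `units` attribute.
#' @export
read_metric_table <- function(path) {
  header <- readLines(path, n = 2)
  cols <- strsplit(header[1], "\t")[[1]]
  dat <- read.table(path, skip = 2, sep = "\t", col.names = cols,
                    stringsAsFactors = FALSE)
  units <- strsplit(sub("^#units:\t", "", header[2]), "\t")[[1]]
  attr(dat, "units") <- setNames(units, cols)
  dat
}

#' Write pedigree and covariates as one tab-delimited table
#'
#' Columns: family, id, father, mother, sex, phenotyped, age, bmi, sbp,
#' hypertension. Missing parents are written as `0` (PLINK convention).
#'
#' @param ped Pedigree data frame.
#' @param covariates Covariate table aligned by `id`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_cohort_table <- function(ped, covariates, path) {
  cv <- covariates[match(ped$id, covariates$id), ]
  out <- data.frame(family = ped$family, id = ped$id,
                    father = ifelse(is.na(ped$father), "0", ped$father),
                    mother = ifelse(is.na(ped$mother), "0", ped$mother),
                    sex = ped$sex, phenotyped = as.integer(ped$phenotyped),
                    age = cv$age, bmi = cv$bmi, sbp = cv$sbp,
                    hypertension = cv$hypertension)
  write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
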