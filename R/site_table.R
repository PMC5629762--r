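#' @keywords internal
"_PACKAGE"

# Required and optional columns of a site table (units: 2011 USD, counts/yr)
.req_cols <- c("site_id", "country", "province", "weight", "total_cost_usd",
               "doses", "dtp3", "govt_owned", "hospital", "rural",
               "fraction_outreach", "fraction_mgmt", "dtp3_per_dose",
               "anc4", "wealth_ratio", "gdp_pc")
.opt_cols <- c("district", "staffing_index", "dedication_index",
               "days_per_week", "distance_km", "inpatient_beds_cat",
               "catchment_pop", "dtp3_coverage")

validation_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("imcost_validation_error",
                                             "error", "condition")))
}

#' Validate a site table
#'
#' Checks the schema and invariants of a facility-level costing table:
#' required columns present, positive costs, doses and weights, DTP3 not
#' exceeding doses, fractions in [0, 1], non-empty identifiers and a unique
#' (country, province, site_id) key. Violations raise a classed condition
#' (`imcost_validation_error`) naming the offending column and row.
#'
#' @param table A data frame.
#' @return The validated table (invisibly unchanged).
#' @export
validate_site_table <- function(table) {
  miss <- setdiff(.req_cols, names(table))
  if (length(miss))
    validation_error("site table missing required column(s): ",
                     paste(miss, collapse = ", "))
  extra <- setdiff(names(table), c(.req_cols, .opt_cols))
  if (length(extra))
    validation_error("site table has unknown column(s): ",
                     paste(extra, collapse = ", "))
  if (!nrow(table)) validation_error("site table has zero rows")
  chk <- function(ok, col, what) {
    if (any(!ok)) validation_error("column '", col, "' ", what, " (row ",
                                   which(!ok)[[1]], ")")
  }
  chk(table$total_cost_usd > 0, "total_cost_usd", "must be > 0")
  chk(table$doses > 0, "doses", "must be > 0")
  chk(table$dtp3 >= 0, "dtp3", "must be >= 0")
  chk(table$dtp3 <= table$doses, "dtp3", "must not exceed doses")
  chk(table$weight > 0, "weight", "must be > 0")
  chk(table$gdp_pc > 0, "gdp_pc", "must be > 0")
  for (col in c("fraction_outreach", "fraction_mgmt", "dtp3_per_dose"))
    chk(table[[col]] >= 0 & table[[col]] <= 1, col, "must lie in [0,1]")
  for (col in c("govt_owned", "hospital", "rural"))
    chk(table[[col]] %in% c(0, 1), col, "must be 0/1")
  chk(nzchar(as.character(table$country)), "country", "must be non-empty")
  chk(nzchar(as.character(table$province)), "province", "must be non-empty")
  key <- paste(table$country, table$province, table$site_id)
  if (anyDuplicated(key))
    validation_error("duplicate (country, province, site_id) key at row ",
                     anyDuplicated(key))
  invisible(table)
}

#' Read a site table from CSV
#'
#' Reads and validates a facility costing table. Costs are interpreted as
#' 2011 USD per year and volumes as counts per year.
#'
#' @param path CSV file with a header row.
#' @return A validated site table (`data.frame`).
#' @export
read_site_table <- function(path) {
  if (!file.exists(path))
    stop(errorCondition(paste0("no such file: ", path),
                        class = c("imcost_io_error", "error", "condition")))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_site_table(tab)
  tab
}

#' Write a site table to CSV
#' @param table A validated site table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_site_table <- function(table, path) {
  validate_site_table(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Top-code a coverage measure at 100%
#'
#' Reported coverage ratios computed against noisy catchment denominators
#' can exceed 1; top-coding replaces values above 1 by exactly 1 and leaves
#' the rest unchanged.
#'
#' @param x Numeric vector of coverage values.
#' @return `pmin(x, 1)`.
#' @export
top_code <- function(x) pmin(x, 1)
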