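#' Validate a child table
#'
#' Checks the schema shared by the generator, the model and the descriptive
#' utilities: required columns, known category labels (with the offending row
#' reported), nesting of the id hierarchy (each child in exactly one
#' household, each household in one cluster, each cluster in one district),
#' ages within 6-59 months, positive survey weights, and — when haemoglobin is
#' present — consistency of `anaemic` with the strict `hb < 11` g/dL rule.
#'
#' @param children a child table `data.frame`.
#' @param require_outcome if `TRUE`, `anaemic` must be filled with 0/1.
#' @return `children`, invisibly.
#' @export
validate_child_table <- function(children, require_outcome = FALSE) {
  required <- setdiff(.child_table_columns, c("hb_adjusted_gdl", "anaemic"))
  miss <- setdiff(required, names(children))
  if (length(miss))
    stop("child table is missing column(s): ", paste(miss, collapse = ", "))
  for (v in names(.covariate_levels)) {
    bad <- which(!is.na(children[[v]]) &
                   !children[[v]] %in% .covariate_levels[[v]])
    if (length(bad))
      stop(sprintf("unknown %s label '%s' in row %d", v,
                   children[[v]][bad[1]], bad[1]))
  }
  if (any(children$age_months < 6 | children$age_months > 59, na.rm = TRUE))
    stop("age_months outside [6, 59]")
  if (any(children$survey_weight <= 0, na.rm = TRUE))
    stop("survey weights must be positive")
  # nested hierarchy: each lower-level id maps to exactly one parent
  nested <- function(child, parent) {
    tab <- unique(children[, c(child, parent)])
    !anyDuplicated(tab[[child]])
  }
  if (!nested("child_id", "household_id") ||
      !nested("household_id", "cluster_id") ||
      !nested("cluster_id", "district_id"))
    stop("id hierarchy is not nested (child < household < cluster < district)")
  if (require_outcome) {
    if (!"anaemic" %in% names(children) || anyNA(children$anaemic))
      stop("outcome 'anaemic' must be filled")
    if (!all(children$anaemic %in% c(0L, 1L)))
      stop("'anaemic' must be 0/1")
  }
  if ("hb_adjusted_gdl" %in% names(children) && "anaemic" %in% names(children)) {
    ok <- is.na(children$hb_adjusted_gdl) | is.na(children$anaemic) |
      (children$anaemic == as.integer(children$hb_adjusted_gdl < 11))
    if (!all(ok))
      stop(sprintf("row %d: anaemic flag inconsistent with hb < 11 g/dL rule",
                   which(!ok)[1]))
  }
  invisible(children)
}

#' Write / read a child table as CSV
#'
#' Plain UTF-8 CSV with a header and "." decimal, one row per child, columns
#' in the canonical order. Missing haemoglobin and outcome values are written
#' as empty fields. Reading validates the schema, so files with missing
#' columns or unknown category labels are rejected (naming the column or the
#' offending row).
#'
#' @param children a child table.
#' @param path file path.
#' @return `write_child_table` returns `path` invisibly; `read_child_table`
#'   returns the validated `data.frame`.
#' @export
write_child_table <- function(children, path) {
  validate_child_table(children)
  utils::write.csv(children[, .child_table_columns], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_child_table
#' @export
read_child_table <- function(path) {
  children <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (v in intersect(c("child_id", "household_id", "cluster_id",
                        "district_id"), names(children)))
    children[[v]] <- as.character(children[[v]])
  validate_child_table(children)
  children
}
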