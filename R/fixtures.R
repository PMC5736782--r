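## Packaged fixtures: the three published compound tables, transcribed
## verbatim into CSV.  "table1" = 18 compounds x 13 computed descriptors with
## A/B group labels; "table2" = IAM chromatography LogK and MLV partitioning;
## "table3" = Ussing-chamber Papp in wild-type and Mdr1a/1b(-/-) tissue with
## per-compound p-values and KO:WT ratios.

fixture_files <- c(table1 = "table1_descriptors.csv",
                   table2 = "table2_membrane_affinity.csv",
                   table3 = "table3_ussing_papp.csv")

#' Path to a packaged data fixture
#'
#' @param id One of `"table1"`, `"table2"`, `"table3"`.
#' @return Absolute path of the packaged CSV.
#' @export
pgplung_fixture <- function(id) {
  id <- match.arg(id, names(fixture_files))
  path <- system.file("extdata", fixture_files[[id]], package = "pgplung",
                      mustWork = TRUE)
  path
}

resolve_source <- function(source) {
  if (source %in% names(fixture_files)) pgplung_fixture(source) else source
}

schema_error <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("pgplung_schema_error", "error")))
}

#' Load and validate a compound descriptor table
#'
#' Reads a CSV holding one row per compound with a `name` column, a `group`
#' column (`A`, `B` or `UNKNOWN`) and the thirteen canonical descriptor
#' columns (see [descriptor_names()]).  Validation rejects duplicate compound
#' names, missing or non-numeric descriptor values, and count columns
#' (`hbd`, `hba`, `hb_total`, `rotatable_bonds`) that are negative or
#' non-integer; the internal consistency `hb_total = hbd + hba` is asserted
#' on every row.
#'
#' @param source A file path, or the fixture id `"table1"` for the packaged
#'   18-compound panel.
#' @return A `descriptor_matrix`: a data frame with columns `name`, `group`
#'   and the 13 descriptors, in stable input order.
#' @export
#' @examples
#' tab1 <- load_descriptor_table("table1")
#' table(tab1$group)
load_descriptor_table <- function(source) {
  path <- resolve_source(source)
  df <- tryCatch(read.csv(path, check.names = FALSE, strip.white = TRUE),
                 error = function(e) schema_error("cannot parse CSV: ",
                                                  conditionMessage(e)))
  if (nrow(df) == 0L) schema_error("descriptor table is empty: ", path)
  as_descriptor_matrix(df)
}

#' Coerce a data frame to a validated descriptor matrix
#'
#' @param df Data frame with `name`, `group` and the 13 canonical descriptor
#'   columns.  A missing `group` column is filled with `"UNKNOWN"`.
#' @return A `descriptor_matrix` data frame.
#' @export
as_descriptor_matrix <- function(df) {
  if (!"name" %in% names(df)) schema_error("missing column 'name'")
  if (!"group" %in% names(df)) df$group <- "UNKNOWN"
  missing <- setdiff(descriptor_names(), names(df))
  if (length(missing))
    schema_error("missing descriptor column(s): ",
                 paste(missing, collapse = ", "))
  extra <- setdiff(names(df), c("name", "group", descriptor_names()))
  if (length(extra))
    df <- df[, c("name", "group", descriptor_names())]
  df$name <- as.character(df$name)
  df$group <- as.character(df$group)
  if (anyDuplicated(df$name))
    schema_error("duplicate compound name(s): ",
                 paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  bad_group <- setdiff(unique(df$group), c("A", "B", "UNKNOWN"))
  if (length(bad_group))
    schema_error("group labels must be A, B or UNKNOWN; found: ",
                 paste(bad_group, collapse = ", "))
  for (col in descriptor_names()) {
    v <- df[[col]]
    if (!is.numeric(v))
      schema_error("non-numeric value in column '", col, "'")
    if (anyNA(v)) {
      row <- df$name[which(is.na(v))[1L]]
      schema_error("missing value in column '", col, "' (row ", row, ")")
    }
  }
  for (col in c("hbd", "hba", "hb_total", "rotatable_bonds")) {
    v <- df[[col]]
    if (any(v < 0) || any(v != round(v))) {
      row <- df$name[which(v < 0 | v != round(v))[1L]]
      schema_error("column '", col, "' must hold non-negative integers (row ",
                   row, ")")
    }
  }
  off <- df$hb_total != df$hbd + df$hba
  if (any(off))
    schema_error("hb_total != hbd + hba for row ",
                 paste(df$name[off], collapse = ", "))
  rownames(df) <- NULL
  class(df) <- c("descriptor_matrix", "data.frame")
  df
}

#' @export
as.matrix.descriptor_matrix <- function(x, ...) {
  m <- as.matrix(as.data.frame(x)[, descriptor_names()])
  rownames(m) <- x$name
  m
}

assay_schemas <- list(
  iam_mlv = c("name", "group", "logk_iam", "mlv_partitioning"),
  ussing_papp = c("name", "group", "papp_wt_e6", "papp_wt_sd_e6",
                  "papp_ko_e6", "papp_ko_sd_e6", "p_value", "ratio"))

#' Load a packaged or external assay results table
#'
#' Two published schemas are supported.  `kind = "iam_mlv"` holds the
#' membrane-affinity table (columns `name`, `group`, `logk_iam`,
#' `mlv_partitioning`); `kind = "ussing_papp"` holds the intestinal
#' permeability table (`papp_wt_e6`/`papp_ko_e6` in 1e-6 cm/s with their SDs,
#' the per-compound t-test `p_value`, and the printed KO:WT `ratio`).
#'
#' @param source File path, or fixture id `"table2"` / `"table3"`.
#' @param kind `"iam_mlv"` or `"ussing_papp"`.
#' @return A validated data frame in stable input order.
#' @export
#' @examples
#' tab2 <- load_assay_table("table2", "iam_mlv")
#' mean(tab2$logk_iam[tab2$group == "A"])
load_assay_table <- function(source, kind = c("iam_mlv", "ussing_papp")) {
  kind <- match.arg(kind)
  path <- resolve_source(source)
  df <- tryCatch(read.csv(path, check.names = FALSE, strip.white = TRUE),
                 error = function(e) schema_error("cannot parse CSV: ",
                                                  conditionMessage(e)))
  wanted <- assay_schemas[[kind]]
  missing <- setdiff(wanted, names(df))
  if (length(missing))
    schema_error("table does not match the '", kind, "' schema; missing: ",
                 paste(missing, collapse = ", "))
  df <- df[, wanted]
  if (nrow(df) == 0L) schema_error("assay table is empty: ", path)
  df$name <- as.character(df$name)
  df$group <- as.character(df$group)
  if (anyDuplicated(df$name))
    schema_error("duplicate compound name(s): ",
                 paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  for (col in setdiff(wanted, c("name", "group"))) {
    if (!is.numeric(df[[col]]) || anyNA(df[[col]]))
      schema_error("column '", col, "' must be numeric with no missing values")
  }
  rownames(df) <- NULL
  df
}

#' Write a fixture-format table to CSV
#'
#' Writes with full stored precision so that a write/read round trip
#' reproduces the values exactly.
#'
#' @param df Data frame as returned by [load_descriptor_table()] or
#'   [load_assay_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  write.csv(as.data.frame(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
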