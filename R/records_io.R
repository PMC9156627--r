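# Canonical record schema, database reading/validation/writing, subsetting.

META_COLUMNS <- c("patient_id", "article_id", "year", "semiology_text",
                  "semiology_category", "topological",
                  "gt_seizure_free", "gt_concordance", "gt_invasive",
                  "age_label", "laterality_semiology", "laterality_dominance")
TOPOLOGICAL_LEVELS <- c("epilepsy_topology", "stimulation", "spontaneous")
TOPOLOGICAL_SUBSET <- c("epilepsy_topology", "stimulation")
AGE_LEVELS <- c("adult", "child_under_7", "unknown")
LAT_SEMIOLOGY_LEVELS <- c("ipsilateral", "contralateral", "unknown")
LAT_DOMINANCE_LEVELS <- c("dominant", "non_dominant", "unknown")
GROUND_TRUTHS <- c("seizure_free", "concordance", "invasive")

#' Region allocation columns of a record table
#' @param records A `semio_records` data frame.
#' @return Character vector of region column names.
#' @export
region_cols <- function(records) attr(records, "region_cols")

gt_flag_cols <- function() paste0("gt_", GROUND_TRUTHS)

as_bool <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no", "")] <- FALSE
  out
}

#' Construct a patient-semiology record table
#'
#' Coerces a data frame in the canonical wide layout (one row per
#' patient-semiology, metadata columns followed by one numeric column per
#' region node) into a validated `semio_records` object. Rows lacking every
#' ground-truth flag violate the inclusion criterion and are dropped, with
#' the failure collected (not fatal) in the attached read report. Duplicate
#' (patient, semiology) rows within an article are merged by summing their
#' allocations, with a warning.
#'
#' @param df A data frame containing the columns listed in [META_COLUMNS]
#'   plus at least one region column.
#' @param tree A `region_tree`; region columns not present in the tree (or
#'   its junction names) are rejected.
#' @return A `semio_records` data frame with attributes `region_cols` and
#'   `read_report` (data frame of collected row-level errors).
#' @export
as_semio_records <- function(df, tree = load_region_tree()) {
  missing_cols <- setdiff(META_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop_semioloc(paste0("missing mandatory column(s): ",
                         paste(missing_cols, collapse = ", ")),
                  "semioloc_schema_error")
  }
  rcols <- setdiff(names(df), META_COLUMNS)
  unknown <- setdiff(rcols, region_names(tree))
  if (length(unknown)) {
    stop_semioloc(paste0("unknown region column(s) not in region tree: ",
                         paste(unknown, collapse = ", ")),
                  "semioloc_schema_error")
  }
  if (!length(rcols)) {
    stop_semioloc("no region allocation columns present", "semioloc_schema_error")
  }
  df$patient_id <- as.character(df$patient_id)
  df$article_id <- as.character(df$article_id)
  df$year <- suppressWarnings(as.integer(df$year))
  df$semiology_text <- as.character(df$semiology_text)
  df$semiology_category <- as.character(df$semiology_category)
  for (cl in gt_flag_cols()) df[[cl]] <- as_bool(df[[cl]])
  enum_check <- function(col, levels) {
    v <- as.character(df[[col]])
    v[is.na(v) | v == ""] <- "unknown"
    bad <- setdiff(unique(v), levels)
    if (length(bad)) {
      stop_semioloc(sprintf("invalid %s value(s): %s", col,
                            paste(bad, collapse = ", ")),
                    "semioloc_schema_error")
    }
    v
  }
  df$topological <- enum_check("topological", TOPOLOGICAL_LEVELS)
  df$age_label <- enum_check("age_label", AGE_LEVELS)
  df$laterality_semiology <- enum_check("laterality_semiology", LAT_SEMIOLOGY_LEVELS)
  df$laterality_dominance <- enum_check("laterality_dominance", LAT_DOMINANCE_LEVELS)
  for (cl in rcols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    v[is.na(v)] <- 0
    if (any(v < 0)) {
      stop_semioloc(sprintf("negative allocation in region column '%s'", cl),
                    "semioloc_schema_error")
    }
    df[[cl]] <- v
  }

  # inclusion criterion: at least one ground truth
  gtm <- as.matrix(df[gt_flag_cols()])
  gtm[is.na(gtm)] <- FALSE
  for (cl in gt_flag_cols()) df[[cl]] <- gtm[, cl]
  has_gt <- rowSums(gtm) > 0
  errors <- data.frame(row = which(!has_gt),
                       rule = rep("ground_truth", sum(!has_gt)),
                       message = rep("record has no true ground-truth flag",
                                     sum(!has_gt)),
                       stringsAsFactors = FALSE)
  df <- df[has_gt, , drop = FALSE]

  # merge duplicated (patient, semiology) rows within an article
  key <- paste(df$article_id, df$patient_id, df$semiology_category, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (patient, semiology) rows merged by summing allocations")
    first <- !duplicated(key)
    alloc <- rowsum(as.matrix(df[rcols]), group = key, reorder = FALSE)
    out <- df[first, , drop = FALSE]
    out[rcols] <- alloc[match(key[first], rownames(alloc)), , drop = FALSE]
    df <- out
  }
  rownames(df) <- NULL
  structure(df, region_cols = rcols, read_report = errors,
            class = c("semio_records", "data.frame"))
}

#' Read a semiology-localization database
#'
#' Reads the canonical flattened export: one row per (patient, semiology)
#' with the metadata columns of [META_COLUMNS] followed by one column per
#' region node. Lines starting with `#` (provenance headers) are skipped in
#' the text dialects.
#'
#' @param path File path.
#' @param dialect One of `"csv"`, `"tsv"`, `"xlsx"` (xlsx requires the
#'   `readxl` package).
#' @param tree A `region_tree` used to vet region column names.
#' @return A `semio_records` object; row-level inclusion failures are
#'   collected in `attr(, "read_report")`.
#' @seealso [write_semio_db()], [validate_records()]
#' @export
read_semio_db <- function(path, dialect = c("csv", "tsv", "xlsx"),
                          tree = load_region_tree()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_semioloc(sprintf("file not found: %s", path), "semioloc_io_error")
  }
  df <- switch(dialect,
    csv = utils::read.csv(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = "character"),
    tsv = utils::read.csv(path, sep = "\t", check.names = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character"),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop_semioloc("reading xlsx requires the 'readxl' package",
                      "semioloc_io_error")
      }
      as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
    })
  as_semio_records(df, tree = tree)
}

#' Write records in the canonical CSV/TSV schema
#'
#' @param records A `semio_records` object.
#' @param path Output file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @param provenance Optional named list written as `# key: value` comment
#'   lines before the header.
#' @return `path`, invisibly.
#' @export
write_semio_db <- function(records, path, dialect = c("csv", "tsv"),
                           provenance = NULL) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    for (k in names(provenance)) {
      writeLines(sprintf("# %s: %s", k, as.character(provenance[[k]])), con)
    }
  }
  utils::write.table(as.data.frame(records), con, sep = sep, row.names = FALSE,
                     qmethod = "double", quote = TRUE)
  invisible(path)
}

#' Audit a record table
#'
#' Report-only validation: counts records, patients and articles; flags
#' records whose localizations are all zero, duplicated (patient, semiology)
#' rows, and articles carrying both topological and non-topological labels.
#' Missing lobar allocations are the dominant error mode in literature
#' curation, so all-zero rows are errors rather than warnings.
#'
#' @param records A `semio_records` object.
#' @return A `semio_validation` list: `n_records`, `n_patients`,
#'   `n_articles`, `errors` and `warnings` data frames. The dataset is
#'   accepted iff `errors` is empty.
#' @export
validate_records <- function(records) {
  rcols <- region_cols(records)
  alloc <- as.matrix(as.data.frame(records)[rcols])
  errors <- data.frame(row = integer(), rule = character(),
                       message = character(), stringsAsFactors = FALSE)
  warnings <- errors
  zero <- which(rowSums(alloc) <= 0)
  if (length(zero)) {
    errors <- rbind(errors, data.frame(
      row = zero, rule = "no_localization",
      message = "record has no positive localization", stringsAsFactors = FALSE))
  }
  key <- paste(records$article_id, records$patient_id,
               records$semiology_category, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    errors <- rbind(errors, data.frame(
      row = dup, rule = "duplicate_unit",
      message = "duplicated (patient, semiology) row", stringsAsFactors = FALSE))
  }
  mixed <- tapply(records$topological %in% TOPOLOGICAL_SUBSET,
                  records$article_id, function(v) length(unique(v)) > 1)
  for (art in names(mixed)[which(mixed)]) {
    warnings <- rbind(warnings, data.frame(
      row = NA_integer_, rule = "inconsistent_topology",
      message = sprintf("article '%s' mixes topological and non-topological labels", art),
      stringsAsFactors = FALSE))
  }
  structure(list(
    n_records = nrow(records),
    n_patients = length(unique(paste(records$article_id, records$patient_id))),
    n_articles = length(unique(records$article_id)),
    errors = errors, warnings = warnings),
    class = "semio_validation")
}

#' @export
print.semio_validation <- function(x, ...) {
  cat(sprintf("Validation: %d records | %d patients | %d articles\n",
              x$n_records, x$n_patients, x$n_articles))
  cat(sprintf("  errors: %d | warnings: %d | %s\n", nrow(x$errors),
              nrow(x$warnings),
              if (nrow(x$errors) == 0) "ACCEPTED" else "REJECTED"))
  invisible(x)
}

#' Serialize a validation report to JSON
#' @param report A `semio_validation` object.
#' @return JSON string.
#' @export
validation_json <- function(report) {
  jsonlite::toJSON(unclass(report), dataframe = "rows", auto_unbox = TRUE,
                   pretty = TRUE)
}

#' Filter records by study design, ground truth and age
#'
#' Keeps a record iff it satisfies all provided filters. `ground_truth_any_of`
#' is a disjunction over the three flags; `exclude_age` removes only records
#' explicitly labelled as children under 7 years (unknown ages are retained,
#' since exclusion applies only where the age label was available).
#'
#' @param records A `semio_records` object.
#' @param topological_in `NULL` (keep all) or a subset of
#'   `c("epilepsy_topology", "stimulation", "spontaneous")`.
#' @param ground_truth_any_of `NULL` or a subset of
#'   `c("seizure_free", "concordance", "invasive")`.
#' @param exclude_age Logical; drop records with `age_label == "child_under_7"`.
#' @param filters Alternative list interface, e.g.
#'   `list(topological_in = "spontaneous")`; unknown keys raise a
#'   configuration error.
#' @return Filtered `semio_records`.
#' @examples
#' \dontrun{
#' nontop <- filter_subset(records, topological_in = "spontaneous")
#' }
#' @export
filter_subset <- function(records, topological_in = NULL,
                          ground_truth_any_of = NULL, exclude_age = FALSE,
                          filters = NULL) {
  if (!is.null(filters)) {
    known <- c("topological_in", "ground_truth_any_of", "exclude_age")
    bad <- setdiff(names(filters), known)
    if (length(bad)) {
      stop_semioloc(paste0("unknown filter key(s): ", paste(bad, collapse = ", ")),
                    "semioloc_config_error")
    }
    topological_in <- filters$topological_in %||% topological_in
    ground_truth_any_of <- filters$ground_truth_any_of %||% ground_truth_any_of
    exclude_age <- filters$exclude_age %||% exclude_age
  }
  keep <- rep(TRUE, nrow(records))
  if (!is.null(topological_in)) {
    bad <- setdiff(topological_in, TOPOLOGICAL_LEVELS)
    if (length(bad)) {
      stop_semioloc(paste0("invalid topological value(s): ",
                           paste(bad, collapse = ", ")), "semioloc_config_error")
    }
    keep <- keep & records$topological %in% topological_in
  }
  if (!is.null(ground_truth_any_of)) {
    bad <- setdiff(ground_truth_any_of, GROUND_TRUTHS)
    if (length(bad)) {
      stop_semioloc(paste0("invalid ground truth value(s): ",
                           paste(bad, collapse = ", ")), "semioloc_config_error")
    }
    any_gt <- rep(FALSE, nrow(records))
    for (g in ground_truth_any_of) any_gt <- any_gt | records[[paste0("gt_", g)]]
    keep <- keep & any_gt
  }
  if (isTRUE(exclude_age)) keep <- keep & records$age_label != "child_under_7"
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, region_cols = region_cols(records),
            class = c("semio_records", "data.frame"))
}

#' @export
print.semio_records <- function(x, ...) {
  cat(sprintf("semio_records: %d patient-semiology rows | %d region columns\n",
              nrow(x), length(region_cols(x))))
  tab <- table(x$topological)
  cat("  topological labels:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  NextMethod()
}
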