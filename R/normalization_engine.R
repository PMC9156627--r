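# Per-patient-semiology normalization: the unit of analysis is a single
# patient's semiology, whose localizing allocations sum to one.

#' Normalize one patient-semiology allocation vector
#'
#' Divides every weight by the vector total, so a semiology reported to
#' localize to several brain regions is penalized inversely proportionally
#' to the number of regions, and each single-patient semiology contributes
#' exactly one unit of localizing mass. Junction redistribution must already
#' have been applied. Raw counts above one (merged duplicate rows) are
#' handled by the same proportional division.
#'
#' @param x Named non-negative numeric vector with at least one positive
#'   entry.
#' @return Named numeric vector summing to 1 (tolerance 1e-9).
#' @examples
#' normalize_patient_semiology(c(Frontal = 1, `Mesial Temporal` = 1))
#' @export
normalize_patient_semiology <- function(x) {
  tot <- sum(x)
  if (!is.finite(tot) || tot <= 0) {
    stop_semioloc("degenerate input: allocation vector has no positive weight",
                  "semioloc_degenerate_error")
  }
  if (any(x < 0)) {
    stop_semioloc("allocation weights must be non-negative",
                  "semioloc_degenerate_error")
  }
  x / tot
}

#' Build the normalized cohort weight matrix
#'
#' Applies junction redistribution to every record's raw allocations, then
#' normalizes each (patient, semiology) row to sum one. The total weight for
#' a semiology therefore equals the number of patients reported with it.
#' Record metadata is preserved for subset filtering and bootstrapping.
#'
#' @param records A `semio_records` object with categories assigned.
#' @param tree A `region_tree`.
#' @return A `semio_weights` object: list with `W` (matrix, one row per
#'   patient-semiology unit, one column per tree node), `meta` (data frame
#'   of unit metadata) and `tree`.
#' @export
cohort_weight_matrix <- function(records, tree = load_region_tree()) {
  rcols <- region_cols(records)
  nodes <- tree$nodes
  W <- matrix(0, nrow = nrow(records), ncol = length(nodes),
              dimnames = list(NULL, nodes))
  raw <- as.matrix(as.data.frame(records)[rcols])
  plain <- intersect(rcols, nodes)
  W[, plain] <- raw[, plain, drop = FALSE]
  for (j in intersect(rcols, names(tree$junctions))) {
    cons <- tree$junctions[[j]]
    for (cn in cons) W[, cn] <- W[, cn] + raw[, j] / length(cons)
  }
  tot <- rowSums(W)
  bad <- which(tot <= 0)
  if (length(bad)) {
    stop_semioloc(
      sprintf("degenerate input: record(s) with no positive localization (patient %s)",
              paste(unique(records$patient_id[bad]), collapse = ", ")),
      "semioloc_degenerate_error")
  }
  W <- W / tot
  meta <- as.data.frame(records)[c("patient_id", "article_id", "year",
                                   "semiology_category", "topological",
                                   gt_flag_cols(), "age_label")]
  rownames(meta) <- NULL
  structure(list(W = W, meta = meta, tree = tree), class = "semio_weights")
}

#' @export
print.semio_weights <- function(x, ...) {
  cat(sprintf("semio_weights: %d patient-semiology units x %d region nodes\n",
              nrow(x$W), ncol(x$W)))
  cat(sprintf("  semiologies: %d | topological units: %d | non-topological: %d\n",
              length(unique(x$meta$semiology_category)),
              sum(x$meta$topological %in% TOPOLOGICAL_SUBSET),
              sum(x$meta$topological == "spontaneous")))
  invisible(x)
}

#' Restrict a weight matrix to a data subset
#'
#' @param weights A `semio_weights` object.
#' @param subset_label One of `"all_data"` (topological plus
#'   non-topological), `"non_topological"`, `"topological"`.
#' @return A `semio_weights` object restricted to the subset.
#' @export
subset_units <- function(weights,
                         subset_label = c("all_data", "non_topological",
                                          "topological")) {
  subset_label <- match.arg(subset_label)
  keep <- switch(subset_label,
                 all_data = rep(TRUE, nrow(weights$W)),
                 non_topological = weights$meta$topological == "spontaneous",
                 topological = weights$meta$topological %in% TOPOLOGICAL_SUBSET)
  structure(list(W = weights$W[keep, , drop = FALSE],
                 meta = weights$meta[keep, , drop = FALSE],
                 tree = weights$tree),
            class = "semio_weights")
}

#' Export the weight matrix as TSV for audit
#'
#' @param weights A `semio_weights` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weight_matrix <- function(weights, path) {
  out <- cbind(weights$meta, as.data.frame(weights$W, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = TRUE)
  invisible(path)
}
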