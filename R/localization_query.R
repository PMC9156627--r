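# Conditional localization probabilities p(region | semiology) with
# bootstrap CIs, the estimated unbiased prior distribution of localizations
# (EUD-Loc), reporting eligibility, and the forest table.

#' Per-unit rolled-up weight for a region
#'
#' For each patient-semiology unit, the normalized weight allocated to a
#' region node plus all of its descendants (so the temporal lobe includes
#' undifferentiated temporal allocations and all five subregions).
#'
#' @param weights A `semio_weights` object.
#' @param region Node name in the tree.
#' @return Numeric vector, one value in `[0, 1]` per unit.
#' @export
unit_rollup_values <- function(weights, region) {
  fam <- c(region, region_descendants(weights$tree, region))
  fam <- intersect(fam, colnames(weights$W))
  rowSums(weights$W[, fam, drop = FALSE])
}

select_semiology <- function(weights, semiology) {
  idx <- which(weights$meta$semiology_category == semiology)
  if (!length(idx)) {
    stop_semioloc(sprintf("no units for semiology '%s'", semiology),
                  "semioloc_undefined_probability_error")
  }
  idx
}

#' Conditional localization probability p(region | semiology)
#'
#' The mean, over all (patient, semiology) units of the given semiology, of
#' the normalized weight rolled up to the region. Because every unit sums to
#' one, the denominator equals the number of patients reported with that
#' semiology.
#'
#' @param weights A `semio_weights` object (already restricted to the data
#'   subset of interest, see [subset_units()]).
#' @param semiology Category name.
#' @param region Region node name.
#' @return Probability in `[0, 1]`.
#' @export
localizing_probability <- function(weights, semiology, region) {
  idx <- select_semiology(weights, semiology)
  mean(unit_rollup_values(weights, region)[idx])
}

#' Bootstrap percentile confidence interval for p(region | semiology)
#'
#' Resamples the (patient, semiology) units with replacement and returns the
#' percentile interval of the localizing probability. Deterministic given
#' `seed`.
#'
#' @inheritParams localizing_probability
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param level Confidence level (default 0.95, i.e. the 2.5/97.5
#'   percentiles).
#' @param seed Integer seed (default 0); the caller's RNG state is restored.
#' @return Named numeric vector `c(ci_low, ci_high)`.
#' @export
bootstrap_ci <- function(weights, semiology, region, n_boot = 10000,
                         level = 0.95, seed = 0) {
  if (n_boot < 1) {
    stop_semioloc("n_boot must be >= 1", "semioloc_config_error")
  }
  idx <- select_semiology(weights, semiology)
  v <- unit_rollup_values(weights, region)[idx]
  n <- length(v)
  stats <- with_seed(seed, {
    samp <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    colMeans(matrix(v[samp], nrow = n))
  })
  percentile_ci(stats, level = level)
}

#' Estimated prior distribution of localizations over top-level regions
#'
#' Pools all semiologies in the requested subset and reports the share of
#' total normalized weight rolled up to each top-level region. Restricting
#' to the non-topological subset gives the estimated unbiased distribution
#' of localizations (EUD-Loc); `"all_data"` gives the publication-biased
#' prior. The seven forest-plot regions are reported explicitly and the
#' remainder (cerebellum plus standalone nodes) as `"Other"`, so the
#' distribution sums to one.
#'
#' @param weights A `semio_weights` object.
#' @param tree A `region_tree` (defaults to the tree inside `weights`).
#' @param subset_label One of `"non_topological"`, `"all_data"`,
#'   `"topological"`.
#' @return An `eud_loc` data frame with columns `region` and `p`, and
#'   attributes `subset_label` and `n_units`.
#' @examples
#' \dontrun{
#' prior <- eud_loc(cohort_weight_matrix(records), subset_label = "non_topological")
#' }
#' @export
eud_loc <- function(weights, tree = weights$tree,
                    subset_label = c("non_topological", "all_data",
                                     "topological")) {
  subset_label <- match.arg(subset_label)
  ws <- subset_units(weights, subset_label)
  if (!nrow(ws$W)) {
    stop_semioloc(sprintf("empty subset '%s'", subset_label),
                  "semioloc_undefined_probability_error")
  }
  total <- sum(ws$W)
  p <- vapply(FOREST_REGIONS,
              function(r) sum(unit_rollup_values(ws, r)) / total,
              numeric(1))
  out <- data.frame(region = c(FOREST_REGIONS, "Other"),
                    p = c(p, 1 - sum(p)),
                    stringsAsFactors = FALSE)
  structure(out, subset_label = subset_label, n_units = nrow(ws$W),
            class = c("eud_loc", "data.frame"))
}

#' @export
print.eud_loc <- function(x, ...) {
  cat(sprintf("Prior distribution of localizations (%s subset, %d units):\n",
              attr(x, "subset_label"), attr(x, "n_units")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-14s %6.1f%%\n", x$region[i], 100 * x$p[i]))
  }
  invisible(x)
}

#' Semiologies eligible for probabilistic reporting
#'
#' A category is reported only when at least `min_patients` patients carry
#' it in *both* the topological and the non-topological subsets, so that the
#' localizing distribution is adequately sampled on each side.
#'
#' @param records A `semio_records` object with categories assigned.
#' @param min_patients Strict lower bound applied to both subsets
#'   (default 100).
#' @return Character vector of eligible category names.
#' @export
eligible_semiologies <- function(records, min_patients = 100) {
  is_topo <- records$topological %in% TOPOLOGICAL_SUBSET
  pat <- paste(records$article_id, records$patient_id)
  count_patients <- function(keep) {
    tab <- table(unique(data.frame(
      cat = records$semiology_category[keep], pat = pat[keep]))$cat)
    tab
  }
  topo <- count_patients(is_topo)
  nontopo <- count_patients(!is_topo)
  cats <- union(names(topo), names(nontopo))
  ok <- vapply(cats, function(cc) {
    t1 <- if (cc %in% names(topo)) topo[[cc]] else 0L
    t2 <- if (cc %in% names(nontopo)) nontopo[[cc]] else 0L
    t1 >= min_patients && t2 >= min_patients
  }, logical(1))
  sort(cats[ok])
}

#' Forest table of localizing probabilities
#'
#' For each eligible semiology and each of the seven top-level regions plus
#' the five temporal subregions, computes the localizing probability with a
#' bootstrap percentile CI in both the all-data and the non-topological
#' subsets (the two series of the forest plots). Bit-identical across reruns
#' with the same seed.
#'
#' @param records A `semio_records` object with categories assigned.
#' @param tree A `region_tree`.
#' @param filters Optional filter list passed to [filter_subset()] (e.g.
#'   restricting ground truths or excluding young children for sensitivity
#'   analyses).
#' @param min_patients Eligibility threshold (default 100).
#' @param n_boot Bootstrap resamples per cell (default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed (default 0).
#' @return A `forest_table` data frame with columns `semiology`, `region`,
#'   `subset_label`, `p_hat`, `ci_low`, `ci_high`, `n_units`,
#'   `n_patients_all`, `n_patients_subset`.
#' @export
forest_table <- function(records, tree = load_region_tree(), filters = NULL,
                         min_patients = 100, n_boot = 10000, level = 0.95,
                         seed = 0) {
  empty <- data.frame(semiology = character(), region = character(),
                      subset_label = character(), p_hat = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      n_units = integer(), n_patients_all = integer(),
                      n_patients_subset = integer(), stringsAsFactors = FALSE)
  if (!is.null(filters)) records <- filter_subset(records, filters = filters)
  if (!nrow(records)) {
    return(structure(empty, n_boot = n_boot, seed = seed, level = level,
                     class = c("forest_table", "data.frame")))
  }
  weights <- cohort_weight_matrix(records, tree)
  cats <- eligible_semiologies(records, min_patients = min_patients)
  regions <- c(FOREST_REGIONS, TEMPORAL_SUBREGIONS)
  out <- list()
  for (ss in c("all_data", "non_topological")) {
    ws <- subset_units(weights, ss)
    for (cc in cats) {
      idx <- which(ws$meta$semiology_category == cc)
      if (length(idx) < 2) next
      n_all <- sum(weights$meta$semiology_category == cc)
      V <- vapply(regions, function(r) unit_rollup_values(ws, r)[idx],
                  numeric(length(idx)))
      n <- length(idx)
      cis <- with_seed(seed, {
        samp <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
        vapply(regions, function(r) {
          percentile_ci(colMeans(matrix(V[, r][samp], nrow = n)), level = level)
        }, numeric(2))
      })
      out[[length(out) + 1L]] <- data.frame(
        semiology = cc, region = regions, subset_label = ss,
        p_hat = colMeans(V), ci_low = cis[1, ], ci_high = cis[2, ],
        n_units = n, n_patients_all = n_all, n_patients_subset = n,
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  structure(res, n_boot = n_boot, seed = seed, level = level,
            class = c("forest_table", "data.frame"))
}
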