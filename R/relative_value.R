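# Intrinsic localizing value of a semiology relative to all other
# semiologies: weighted 2x2 contingency tables and bootstrapped odds ratios.

#' Weighted 2x2 contingency table (semiology vs rest, region vs rest)
#'
#' Cells are weighted sums over normalized patient-semiology units:
#' `a` = weight of the semiology's units rolled up to the region,
#' `b` = remaining weight of those units, `c`/`d` analogously over all other
#' units (all semiologies present in the weight matrix, including the less
#' frequent ones). `a + b` equals the unit count of the semiology and
#' `c + d` the unit count of the rest.
#'
#' @param weights A `semio_weights` object (restricted to the subset of
#'   interest beforehand).
#' @param semiology Category name.
#' @param region Region node name.
#' @return Named numeric vector `c(a, b, c, d)` with attribute `degenerate`
#'   flagging a zero margin.
#' @export
contingency_table <- function(weights, semiology, region) {
  idx <- select_semiology(weights, semiology)
  v <- unit_rollup_values(weights, region)
  a <- sum(v[idx])
  b <- length(idx) - a
  c_ <- sum(v[-idx])
  d <- (length(v) - length(idx)) - c_
  out <- c(a = a, b = b, c = c_, d = d)
  attr(out, "degenerate") <- any(abs(out) < 1e-12)
  out
}

#' Odds ratio with Haldane-Anscombe continuity correction
#'
#' Returns `(a*d) / (b*c)`. When any cell is zero, `correction` (default
#' 0.5) is added to all four cells first.
#'
#' @param a,b,c,d Non-negative cell totals (weighted counts allowed).
#' @param correction Continuity correction applied when a cell is zero.
#' @return Positive odds ratio.
#' @examples
#' odds_ratio(4, 1, 2, 8)
#' odds_ratio(0, 5, 5, 5)
#' @export
odds_ratio <- function(a, b, c, d, correction = 0.5) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) {
    stop_semioloc("contingency cells must be non-negative",
                  "semioloc_config_error")
  }
  if (all(cells == 0)) {
    stop_semioloc("odds ratio undefined: all cells zero",
                  "semioloc_degenerate_error")
  }
  if (any(cells == 0)) cells <- cells + correction
  (cells[1] * cells[4]) / (cells[2] * cells[3])
}

#' Odds ratio with bootstrap percentile CI and significance flag
#'
#' Point estimate from the full subset; the CI is the percentile interval of
#' the odds ratio over resamples of *all* units (the semiology's and the
#' rest, pooled) drawn with replacement. Significance means the CI excludes
#' 1 at the given level (alpha = 0.05 by default).
#'
#' @inheritParams contingency_table
#' @param n_boot Bootstrap resamples (default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed (default 0).
#' @param correction Haldane-Anscombe correction for zero cells.
#' @param subset_label Label stored with the result.
#' @return A one-row `contingency_result` data frame: `semiology`, `region`,
#'   `a`, `b`, `c`, `d`, `odds_ratio`, `ci_low`, `ci_high`, `significant`,
#'   `subset_label`.
#' @export
or_with_ci <- function(weights, semiology, region, n_boot = 10000,
                       level = 0.95, seed = 0, correction = 0.5,
                       subset_label = "all_data") {
  if (n_boot < 1) {
    stop_semioloc("n_boot must be >= 1", "semioloc_config_error")
  }
  idx <- select_semiology(weights, semiology)
  n <- nrow(weights$W)
  if (length(idx) < 2 || (n - length(idx)) < 2) {
    stop_semioloc("insufficient data: need >= 2 units in both groups",
                  "semioloc_insufficient_data_error")
  }
  v <- unit_rollup_values(weights, region)
  s <- as.numeric(seq_len(n) %in% idx)
  tab <- contingency_table(weights, semiology, region)
  point <- odds_ratio(tab["a"], tab["b"], tab["c"], tab["d"],
                      correction = correction)
  ors <- with_seed(seed, {
    out <- numeric(n_boot)
    done <- 0L
    chunk <- max(1L, min(n_boot, ceiling(2e6 / n)))
    while (done < n_boot) {
      B <- min(chunk, n_boot - done)
      samp <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
      sv <- matrix(s[samp], nrow = n)
      vv <- matrix(v[samp], nrow = n)
      a <- colSums(sv * vv)
      nS <- colSums(sv)
      cc <- colSums(vv) - a
      b <- nS - a
      d <- (n - nS) - cc
      zero <- a < 1e-12 | b < 1e-12 | cc < 1e-12 | d < 1e-12
      a[zero] <- a[zero] + correction; b[zero] <- b[zero] + correction
      cc[zero] <- cc[zero] + correction; d[zero] <- d[zero] + correction
      out[done + seq_len(B)] <- (a * d) / (b * cc)
      done <- done + B
    }
    out
  })
  ci <- percentile_ci(ors, level = level)
  res <- data.frame(semiology = semiology, region = region,
                    a = unname(tab["a"]), b = unname(tab["b"]),
                    c = unname(tab["c"]), d = unname(tab["d"]),
                    odds_ratio = unname(point),
                    ci_low = unname(ci["ci_low"]),
                    ci_high = unname(ci["ci_high"]),
                    significant = !(ci["ci_low"] <= 1 && 1 <= ci["ci_high"]),
                    subset_label = subset_label,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(res, class = c("contingency_result", "data.frame"))
}

#' Odds-ratio table across semiologies, regions and subsets
#'
#' Mirrors the probability forest: for each eligible semiology and each of
#' the seven top-level regions plus five temporal subregions, the odds ratio
#' of localizing there versus all other semiologies, in both the all-data
#' and non-topological subsets. Odds ratios are computed against *all*
#' semiologies present in the records, including those below the reporting
#' threshold.
#'
#' @inheritParams forest_table
#' @return A `contingency_result` data frame.
#' @export
or_table <- function(records, tree = load_region_tree(), filters = NULL,
                     min_patients = 100, n_boot = 10000, level = 0.95,
                     seed = 0) {
  if (!is.null(filters)) records <- filter_subset(records, filters = filters)
  weights <- cohort_weight_matrix(records, tree)
  cats <- eligible_semiologies(records, min_patients = min_patients)
  regions <- c(FOREST_REGIONS, TEMPORAL_SUBREGIONS)
  out <- list()
  for (ss in c("all_data", "non_topological")) {
    ws <- subset_units(weights, ss)
    for (cc in cats) {
      for (r in regions) {
        res <- tryCatch(
          or_with_ci(ws, cc, r, n_boot = n_boot, level = level, seed = seed,
                     subset_label = ss),
          semioloc_insufficient_data_error = function(e) NULL)
        if (!is.null(res)) out[[length(out) + 1L]] <- res
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    semiology = character(), region = character(), a = numeric(),
    b = numeric(), c = numeric(), d = numeric(), odds_ratio = numeric(),
    ci_low = numeric(), ci_high = numeric(), significant = logical(),
    subset_label = character(), stringsAsFactors = FALSE)
  structure(res, n_boot = n_boot, seed = seed, level = level,
            class = c("contingency_result", "data.frame"))
}
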