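make_weights <- function(rows) cohort_weight_matrix(build_records(rows), default_tree)

test_that("localizing probability averages rolled-up unit weights", {
  rows <- lapply(1:10, function(i) {
    rec_row(paste0("P", i), "A1", "Tonic", c(Frontal = 1))
  })
  w <- make_weights(rows)
  expect_equal(localizing_probability(w, "Tonic", "Frontal"), 1.0)

  rows2 <- c(
    lapply(1:3, function(i) rec_row(paste0("P", i), "A1", "Tonic",
                                    c(Temporal = 1))),
    list(rec_row("P4", "A1", "Tonic", c(Frontal = 1, Temporal = 1))))
  w2 <- make_weights(rows2)
  expect_equal(localizing_probability(w2, "Tonic", "Temporal"), 3.5 / 4)

  # subregion-only allocations roll up into the temporal estimate
  rows3 <- lapply(1:5, function(i) {
    rec_row(paste0("P", i), "A1", "Epigastric", c("Mesial Temporal" = 1))
  })
  w3 <- make_weights(rows3)
  expect_equal(localizing_probability(w3, "Epigastric", "Temporal"),
               localizing_probability(w3, "Epigastric", "Mesial Temporal"))
  expect_error(localizing_probability(w3, "Gelastic", "Temporal"),
               class = "semioloc_undefined_probability_error")
})

test_that("probabilities over the top-level partition sum to one and nest subregions", {
  cohort <- generate_cohort(default_paper_like_config(seed = 5, n_articles = 15))
  w <- cohort_weight_matrix(cohort$records, default_tree)
  part <- c(default_tree$top_level, default_tree$standalone)
  for (cc in head(unique(w$meta$semiology_category), 5)) {
    total <- sum(vapply(part, function(r) localizing_probability(w, cc, r),
                        numeric(1)))
    expect_equal(total, 1, tolerance = 1e-9)
    p_sub <- vapply(default_tree$children$Temporal,
                    function(r) localizing_probability(w, cc, r), numeric(1))
    expect_gte(localizing_probability(w, cc, "Temporal"), max(p_sub))
  }
})

test_that("bootstrap CIs are deterministic, degenerate on constant cohorts, and ordered", {
  rows <- lapply(1:12, function(i) {
    rec_row(paste0("P", i), "A1", "Tonic", c(Temporal = 1))
  })
  w <- make_weights(rows)
  ci <- bootstrap_ci(w, "Tonic", "Temporal", n_boot = 200, seed = 3)
  expect_equal(unname(ci), c(1, 1))

  rows2 <- c(rows, lapply(13:20, function(i) {
    rec_row(paste0("P", i), "A1", "Tonic", c(Frontal = 1))
  }))
  w2 <- make_weights(rows2)
  ci_a <- bootstrap_ci(w2, "Tonic", "Temporal", n_boot = 500, seed = 9)
  ci_b <- bootstrap_ci(w2, "Tonic", "Temporal", n_boot = 500, seed = 9)
  expect_identical(ci_a, ci_b)
  p <- localizing_probability(w2, "Tonic", "Temporal")
  expect_lte(ci_a[["ci_low"]], p)
  expect_gte(ci_a[["ci_high"]], p)
  expect_error(bootstrap_ci(w2, "Tonic", "Temporal", n_boot = 0),
               class = "semioloc_config_error")
})

test_that("bootstrap CI width shrinks as the cohort grows", {
  row_probs <- c(.3, .3, .1, .1, .1, .05, .05, 0)
  widths <- vapply(c(60, 500, 5000), function(n) {
    cfg <- one_category_config(n, row_probs, seed = n + 1)
    w <- cohort_weight_matrix(generate_cohort(cfg)$records, default_tree)
    ci <- bootstrap_ci(subset_units(w, "non_topological"), "Tonic", "Temporal",
                       n_boot = 1000, seed = 2)
    ci[["ci_high"]] - ci[["ci_low"]]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("non-topological estimates track generator truth within three sampling SEs", {
  cohort <- generate_cohort(default_paper_like_config(seed = 17, n_articles = 150))
  w <- subset_units(cohort_weight_matrix(cohort$records, default_tree),
                    "non_topological")
  truth <- cohort$truth$true_conditional
  cats <- rownames(truth)[1:12]  # the named, non-placeholder categories
  checks <- c()
  for (cc in cats) {
    n_cc <- sum(w$meta$semiology_category == cc)
    if (n_cc < 30) next
    for (r in colnames(truth)) {
      p_hat <- localizing_probability(w, cc, r)
      p <- truth[cc, r]
      # SE under the generator truth: the plug-in SE degenerates to zero in
      # cells whose realized count is zero, which would flag small-p cells
      se <- sqrt(p * (1 - p) / n_cc)
      checks <- c(checks, abs(p_hat - p) < 3 * se + 1e-9)
    }
  }
  expect_gte(mean(checks), 0.95)
})

test_that("eud_loc concentrates where the cohort localizes and sums to one", {
  rows <- lapply(1:6, function(i) {
    rec_row(paste0("P", i), "A1", "Epigastric", c(Temporal = 1))
  })
  w <- make_weights(rows)
  prior <- eud_loc(w, subset_label = "all_data")
  expect_equal(prior$p[prior$region == "Temporal"], 1.0)
  expect_equal(sum(prior$p), 1, tolerance = 1e-9)
  expect_error(eud_loc(w, subset_label = "topological"),
               class = "semioloc_undefined_probability_error")
})

test_that("eud_loc recovers the generator marginal and exposes selection bias", {
  cohort <- generate_cohort(default_paper_like_config(seed = 23, n_articles = 150))
  w <- cohort_weight_matrix(cohort$records, default_tree)
  prior_nt <- eud_loc(w, subset_label = "non_topological")
  truth <- cohort$truth$region_marginal_nontopological
  for (r in c("Temporal", "Frontal", "Parietal")) {
    expect_lt(abs(prior_nt$p[prior_nt$region == r] - truth[[r]]), 0.03)
  }
  prior_all <- eud_loc(w, subset_label = "all_data")
  # topological articles oversample the temporal lobe, inflating the pooled prior
  expect_gt(prior_all$p[prior_all$region == "Temporal"],
            prior_nt$p[prior_nt$region == "Temporal"])
})

test_that("eligibility requires the patient threshold in both subsets", {
  mk <- function(n_topo, n_nontopo, cat = "Tonic") {
    c(lapply(seq_len(n_topo), function(i) {
        rec_row(sprintf("T%03d", i), "A1", cat, c(Temporal = 1),
                topo = "epilepsy_topology")
      }),
      lapply(seq_len(n_nontopo), function(i) {
        rec_row(sprintf("N%03d", i), "A2", cat, c(Temporal = 1))
      }))
  }
  expect_equal(eligible_semiologies(build_records(mk(150, 99))), character(0))
  expect_equal(eligible_semiologies(build_records(mk(100, 100))), "Tonic")
  expect_equal(eligible_semiologies(build_records(mk(99, 101))), character(0))
  expect_equal(eligible_semiologies(build_records(mk(101, 101))), "Tonic")
  # threshold is configurable
  expect_equal(eligible_semiologies(build_records(mk(5, 4)), min_patients = 4),
               "Tonic")
})

test_that("forest_table covers eligible semiologies x 12 regions x 2 subsets", {
  rows <- c(
    lapply(1:6, function(i) rec_row(sprintf("P%02d", i), "A1", "Epigastric",
                                    c("Mesial Temporal" = 1),
                                    topo = "epilepsy_topology")),
    lapply(7:12, function(i) rec_row(sprintf("P%02d", i), "A2", "Epigastric",
                                     c(Temporal = 1))),
    lapply(13:18, function(i) rec_row(sprintf("P%02d", i), "A3", "Tonic",
                                      c(Frontal = 1),
                                      topo = "stimulation")),
    lapply(19:24, function(i) rec_row(sprintf("P%02d", i), "A4", "Tonic",
                                      c(Frontal = 1))))
  rec <- build_records(rows)
  ft <- forest_table(rec, min_patients = 5, n_boot = 100, seed = 1)
  expect_equal(nrow(ft), 2 * 12 * 2)
  expect_setequal(unique(ft$subset_label), c("all_data", "non_topological"))
  expect_true(all(ft$ci_low <= ft$p_hat + 1e-12 & ft$p_hat <= ft$ci_high + 1e-12))

  ft2 <- forest_table(rec, min_patients = 5, n_boot = 100, seed = 1)
  expect_identical(ft, ft2)  # bit-identical rerun

  empty <- forest_table(rec, filters = list(ground_truth_any_of = "invasive"),
                        min_patients = 5, n_boot = 50, seed = 1)
  expect_equal(nrow(empty), 0L)
})
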