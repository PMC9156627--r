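# Fixture builders and independent oracles used across the suite.
# Oracles use their own flat parent map and naive loops so they never share
# code paths with the package implementation they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

default_tree <- load_region_tree()
top_regions <- c("Temporal", "Frontal", "Parietal", "Occipital",
                 "Cingulate", "Insula", "Hypothalamus", "Cerebellum")

# Build a canonical wide record table from compact row specs.
# Each row: list(pid, art, cat, alloc = named numeric, topo, gt, age, year)
rec_row <- function(pid, art, cat, alloc, topo = "spontaneous",
                    gt = c(TRUE, FALSE, FALSE), age = "adult",
                    year = 2000, text = NULL) {
  list(pid = pid, art = art, cat = cat, alloc = alloc, topo = topo,
       gt = gt, age = age, year = year, text = text %||% tolower(cat))
}

build_records <- function(rows, tree = default_tree) {
  all_regions <- sort(unique(unlist(lapply(rows, function(r) names(r$alloc)))))
  df <- do.call(rbind, lapply(rows, function(r) {
    base <- data.frame(
      patient_id = r$pid, article_id = r$art, year = r$year,
      semiology_text = r$text, semiology_category = r$cat,
      topological = r$topo,
      gt_seizure_free = r$gt[1], gt_concordance = r$gt[2],
      gt_invasive = r$gt[3],
      age_label = r$age, laterality_semiology = "unknown",
      laterality_dominance = "unknown", stringsAsFactors = FALSE)
    for (rg in all_regions) base[[rg]] <- if (rg %in% names(r$alloc)) r$alloc[[rg]] else 0
    base
  }))
  as_semio_records(df, tree = tree)
}

# --- independent oracle machinery ----------------------------------------

# flat parent map of the default tree (subregions -> Temporal)
oracle_parents <- c("Mesial Temporal" = "Temporal",
                    "Anterior Temporal" = "Temporal",
                    "Lateral Temporal" = "Temporal",
                    "Posterior Temporal" = "Temporal",
                    "Basal Temporal" = "Temporal")

# rolled-up weight of a normalized unit vector at a region, by naive loop
oracle_rolled <- function(vec, region) {
  tot <- 0
  for (nm in names(vec)) {
    anc <- nm
    if (nm %in% names(oracle_parents)) anc <- c(anc, oracle_parents[[nm]])
    if (region %in% anc) tot <- tot + vec[[nm]]
  }
  tot
}

# weighted 2x2 table by brute-force enumeration over units:
# units = list of RAW integer allocation vectors, s_flag marks semiology S
oracle_contingency <- function(units, s_flag, region) {
  a <- b <- cc <- d <- 0
  for (i in seq_along(units)) {
    v <- units[[i]] / sum(units[[i]])
    w <- oracle_rolled(v, region)
    if (s_flag[i]) {
      a <- a + w
      b <- b + (1 - w)
    } else {
      cc <- cc + w
      d <- d + (1 - w)
    }
  }
  c(a = a, b = b, c = cc, d = d)
}

# single-category generator config used for calibration-style tests
one_category_config <- function(n_patients, conditional_row, seed,
                                category = "Tonic", p_multiregion = 0.2) {
  stopifnot(n_patients %% 20 == 0)
  cond <- matrix(conditional_row, nrow = 1,
                 dimnames = list(category, top_regions))
  synthetic_cohort_config(
    n_articles = n_patients / 20,
    patients_per_article = c(20L, 20L),
    pi_topological = 0,
    focus_distribution = c(Temporal = 1),
    true_conditional = cond,
    semiology_marginal = stats::setNames(1, category),
    semiologies_per_patient = c(1L, 1L),
    p_multiregion = p_multiregion,
    seed = seed)
}
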