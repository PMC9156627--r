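# Seeded generator of literature-like cohorts with known ground truth:
# a true conditional localization matrix, a study-design mix, and a
# topological selection-bias mechanism that oversamples prespecified focus
# regions (predominantly temporal).

CATEGORY_TEXT_TEMPLATES <- c(
  "Tonic" = "sustained tonic posturing of one limb",
  "Oral and manual automatisms" = "lip smacking and chewing",
  "Dialeptic-LOA-LOC" = "blank stare with loss of awareness",
  "Epigastric" = "rising epigastric aura",
  "Vocalization - unintelligible noises" = "unintelligible vocalization with grunting",
  "Autonomic" = "autonomic features with pilomotor erection",
  "Olfactory" = "olfactory aura with smell of burning",
  "Head version" = "forced head deviation over the shoulder",
  "Dystonic" = "dystonic posturing of the right hand",
  "Other automatisms" = "gelastic laughter episodes",
  "Mimetic automatisms" = "grimacing with fearful expression",
  "Somatosensory" = "tingling sensation of the hand")

#' Construct and validate a synthetic cohort configuration
#'
#' All generative parameters for parameter-recovery testing: the true
#' conditional localization matrix P(region | semiology) over top-level
#' regions, the semiology marginal, the study-design mix, and the selection
#' bias of topological articles.
#'
#' @param n_articles Number of articles to simulate.
#' @param patients_per_article Integer range `c(lo, hi)` (uniform).
#' @param pi_topological Probability that an article is topological
#'   (preselected by region).
#' @param p_stimulation Probability that a topological article is a
#'   stimulation study rather than an epilepsy-topology study (pooled in all
#'   analyses).
#' @param focus_distribution Named probability vector over top-level regions:
#'   the focus of topological articles.
#' @param true_conditional Matrix, rows = semiology categories, columns =
#'   the eight top-level regions, each row summing to 1.
#' @param semiology_marginal Named probability vector over the rows of
#'   `true_conditional`.
#' @param semiologies_per_patient Integer range `c(lo, hi)`: distinct
#'   categories per patient (uniform).
#' @param p_multiregion Probability that a non-topological unit localizes to
#'   two regions (each drawn from the same conditional row, allocated
#'   half/half raw).
#' @param temporal_subregion_probs Named probability vector over
#'   `"Temporal"` (undifferentiated) and the five temporal subregions, used
#'   to refine any allocation drawn as temporal.
#' @param ground_truth_probs Named per-flag probabilities
#'   (`seizure_free`, `concordance`, `invasive`), drawn independently with
#'   rejection so that every record has at least one flag.
#' @param age_probs Named probability vector over
#'   `c("adult", "child_under_7", "unknown")`.
#' @param year_range Publication-year range.
#' @param seed Integer seed; the generated cohort is a deterministic
#'   function of the configuration including this seed.
#' @return A `synthetic_cohort_config` list.
#' @seealso [default_paper_like_config()], [generate_cohort()]
#' @export
synthetic_cohort_config <- function(n_articles,
                                    patients_per_article = c(5L, 40L),
                                    pi_topological,
                                    p_stimulation = 0.5,
                                    focus_distribution,
                                    true_conditional,
                                    semiology_marginal,
                                    semiologies_per_patient = c(1L, 3L),
                                    p_multiregion = 0.2,
                                    temporal_subregion_probs = c(
                                      "Temporal" = 0.30,
                                      "Mesial Temporal" = 0.35,
                                      "Anterior Temporal" = 0.10,
                                      "Lateral Temporal" = 0.10,
                                      "Posterior Temporal" = 0.08,
                                      "Basal Temporal" = 0.07),
                                    ground_truth_probs = c(
                                      seizure_free = 0.55,
                                      concordance = 0.45,
                                      invasive = 0.25),
                                    age_probs = c(adult = 0.62,
                                                  child_under_7 = 0.08,
                                                  unknown = 0.30),
                                    year_range = c(1954L, 2021L),
                                    seed = 0L) {
  true_conditional <- as.matrix(true_conditional)
  if (is.null(rownames(true_conditional)) ||
      !setequal(colnames(true_conditional), TOP_LEVEL_REGIONS)) {
    stop_semioloc("true_conditional needs semiology rownames and the eight top-level regions as columns",
                  "semioloc_config_error")
  }
  true_conditional <- true_conditional[, TOP_LEVEL_REGIONS, drop = FALSE]
  for (i in seq_len(nrow(true_conditional))) {
    assert_prob_vector(true_conditional[i, ],
                       sprintf("true_conditional row '%s'",
                               rownames(true_conditional)[i]))
  }
  if (!setequal(names(semiology_marginal), rownames(true_conditional))) {
    stop_semioloc("semiology_marginal names must match true_conditional rows",
                  "semioloc_config_error")
  }
  semiology_marginal <- semiology_marginal[rownames(true_conditional)]
  assert_prob_vector(semiology_marginal, "semiology_marginal")
  if (!all(names(focus_distribution) %in% TOP_LEVEL_REGIONS)) {
    stop_semioloc("focus_distribution names must be top-level regions",
                  "semioloc_config_error")
  }
  assert_prob_vector(focus_distribution, "focus_distribution")
  assert_prob_vector(temporal_subregion_probs, "temporal_subregion_probs")
  if (!setequal(names(temporal_subregion_probs),
                c("Temporal", TEMPORAL_SUBREGIONS))) {
    stop_semioloc("temporal_subregion_probs must cover 'Temporal' and its five subregions",
                  "semioloc_config_error")
  }
  assert_prob_vector(age_probs, "age_probs")
  ranges_ok <- function(r) length(r) == 2 && r[1] >= 1 && r[2] >= r[1]
  if (!ranges_ok(patients_per_article) || !ranges_ok(semiologies_per_patient)) {
    stop_semioloc("patients_per_article / semiologies_per_patient must be non-empty integer ranges",
                  "semioloc_config_error")
  }
  if (semiologies_per_patient[2] > length(semiology_marginal)) {
    stop_semioloc("semiologies_per_patient exceeds number of categories",
                  "semioloc_config_error")
  }
  # Bayes inversion P(s | focus) must have mass for every focus region used
  for (f in names(focus_distribution)[focus_distribution > 0]) {
    if (sum(true_conditional[, f] * semiology_marginal) <= 0) {
      stop_semioloc(sprintf("infeasible Bayes inversion: no semiology mass localizes to focus '%s'", f),
                    "semioloc_config_error")
    }
  }
  structure(list(
    n_articles = as.integer(n_articles),
    patients_per_article = as.integer(patients_per_article),
    pi_topological = pi_topological,
    p_stimulation = p_stimulation,
    focus_distribution = focus_distribution,
    true_conditional = true_conditional,
    semiology_marginal = semiology_marginal,
    semiologies_per_patient = as.integer(semiologies_per_patient),
    p_multiregion = p_multiregion,
    temporal_subregion_probs = temporal_subregion_probs,
    ground_truth_probs = ground_truth_probs,
    age_probs = age_probs,
    year_range = as.integer(year_range),
    seed = as.integer(seed)),
    class = "synthetic_cohort_config")
}

#' Default literature-like configuration
#'
#' Shape constants follow the published landscape of the semiology
#' literature: the non-topological (unbiased) region marginal puts 44% of
#' localizing mass on the temporal and 31% on the frontal lobe; the
#' semiology marginal assigns the twelve most common ictal categories their
#' reported shares of non-topological data (tonic 9.8%, ..., somatosensory
#' 2.9%; 65.5% together), with the remaining 34.5% spread uniformly over 23
#' placeholder categories; topological articles focus on the temporal lobe
#' 75% of the time; and the topological article share (0.71) is chosen so
#' that the pooled all-data temporal share is about 66%.
#'
#' The conditional rows of the twelve named categories encode their
#' characteristic localizations (e.g. epigastric auras temporal in 83%,
#' tonic seizures frontal in 54%); the shared placeholder row is the unique
#' residual making the mixture marginal hit the unbiased target exactly.
#'
#' @param seed Integer seed stored in the configuration.
#' @param n_articles Number of simulated articles; the default (222) yields
#'   about 5,000 patients at 5-40 patients per article.
#' @return A `synthetic_cohort_config`.
#' @export
default_paper_like_config <- function(seed = 0L, n_articles = 222L) {
  target <- c(Temporal = 0.44, Frontal = 0.31, Parietal = 0.07,
              Occipital = 0.06, Cingulate = 0.045, Insula = 0.03,
              Hypothalamus = 0.04, Cerebellum = 0.005)
  marg12 <- c("Tonic" = 0.098,
              "Oral and manual automatisms" = 0.097,
              "Dialeptic-LOA-LOC" = 0.083,
              "Epigastric" = 0.061,
              "Vocalization - unintelligible noises" = 0.055,
              "Autonomic" = 0.047,
              "Olfactory" = 0.046,
              "Head version" = 0.043,
              "Dystonic" = 0.034,
              "Other automatisms" = 0.031,
              "Mimetic automatisms" = 0.031,
              "Somatosensory" = 0.029)
  cond12 <- rbind(
    c(.20, .54, .08, .05, .07, .03, .02, .01),   # Tonic
    c(.47, .31, .04, .03, .10, .02, .03, .00),   # Oral and manual automatisms
    c(.42, .28, .08, .09, .03, .02, .08, .00),   # Dialeptic-LOA-LOC
    c(.83, .06, .04, .02, .02, .02, .01, .00),   # Epigastric
    c(.36, .44, .04, .04, .09, .02, .01, .00),   # Vocalization
    c(.58, .13, .05, .03, .03, .03, .15, .00),   # Autonomic
    c(.40, .21, .28, .03, .02, .04, .02, .00),   # Olfactory
    c(.46, .33, .07, .06, .04, .02, .02, .00),   # Head version
    c(.25, .53, .07, .04, .05, .03, .02, .01),   # Dystonic
    c(.35, .11, .04, .03, .04, .02, .41, .00),   # Other automatisms
    c(.20, .40, .05, .04, .26, .03, .02, .00),   # Mimetic automatisms
    c(.31, .23, .38, .03, .02, .02, .01, .00))   # Somatosensory
  dimnames(cond12) <- list(names(marg12), names(target))
  n_other <- 23L
  p_other_total <- 1 - sum(marg12)
  residual <- (target - as.vector(marg12 %*% cond12)) / p_other_total
  if (any(residual < 0)) {
    stop_semioloc("residual placeholder row is not a probability vector",
                  "semioloc_config_error")
  }
  other_names <- sprintf("Other semiology %02d", seq_len(n_other))
  cond <- rbind(cond12,
                matrix(rep(residual, n_other), nrow = n_other, byrow = TRUE,
                       dimnames = list(other_names, names(target))))
  marg <- c(marg12, setNames(rep(p_other_total / n_other, n_other),
                             other_names))
  focus <- c(Temporal = 0.75, Frontal = 0.08, Parietal = 0.03,
             Occipital = 0.06, Cingulate = 0.01, Insula = 0.05,
             Hypothalamus = 0.02)
  synthetic_cohort_config(
    n_articles = n_articles,
    pi_topological = 0.71,
    focus_distribution = focus,
    true_conditional = cond,
    semiology_marginal = marg,
    seed = seed)
}

#' @export
print.synthetic_cohort_config <- function(x, ...) {
  cat(sprintf("synthetic_cohort_config: %d articles (%d-%d patients each), pi_topological=%.2f, seed=%d\n",
              x$n_articles, x$patients_per_article[1], x$patients_per_article[2],
              x$pi_topological, x$seed))
  cat(sprintf("  %d semiology categories x %d regions; focus: %s\n",
              nrow(x$true_conditional), ncol(x$true_conditional),
              paste(sprintf("%s=%.2f", names(x$focus_distribution),
                            x$focus_distribution), collapse = " ")))
  invisible(x)
}

draw_int_range <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

# refine an allocation drawn as "Temporal" into undifferentiated temporal or
# one of the five subregions
refine_temporal <- function(region_vec, probs) {
  is_t <- region_vec == "Temporal"
  if (any(is_t)) {
    region_vec[is_t] <- sample(names(probs), sum(is_t), replace = TRUE,
                               prob = probs)
  }
  region_vec
}

#' Generate a synthetic literature cohort with known ground truth
#'
#' Non-topological articles sample each patient-semiology unit's category
#' from the semiology marginal and its region from the true conditional row
#' (optionally a second region from the same row, allocated half/half raw).
#' Topological articles first draw a focus region, then sample categories
#' from the Bayes inversion P(semiology | focus) of the same truth, and set
#' every unit's region to the focus exactly (sharp preselection, as in
#' resection or stimulation series). Temporal allocations are refined into
#' subregions. Ground-truth flags are drawn independently with rejection so
#' that every record satisfies the inclusion criterion. Deterministic given
#' the configuration seed.
#'
#' @param config A `synthetic_cohort_config`.
#' @param tree A `region_tree` used to assemble the canonical record table.
#' @return A list with `records` (a `semio_records` object) and `truth`
#'   (generator ground truth: the conditional matrix, marginals, the implied
#'   non-topological and pooled region marginals, and realized per-category
#'   patient counts per subset).
#' @examples
#' cohort <- generate_cohort(default_paper_like_config(seed = 1, n_articles = 5))
#' nrow(cohort$records)
#' @export
generate_cohort <- function(config, tree = load_region_tree()) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  cats <- rownames(config$true_conditional)
  regions <- colnames(config$true_conditional)
  marg <- config$semiology_marginal
  cond <- config$true_conditional

  out <- with_seed(config$seed, {
    n_art <- config$n_articles
    art_topo <- stats::runif(n_art) < config$pi_topological
    art_label <- ifelse(art_topo,
                        ifelse(stats::runif(n_art) < config$p_stimulation,
                               "stimulation", "epilepsy_topology"),
                        "spontaneous")
    art_focus <- rep(NA_character_, n_art)
    if (any(art_topo)) {
      art_focus[art_topo] <- sample(names(config$focus_distribution),
                                    sum(art_topo), replace = TRUE,
                                    prob = config$focus_distribution)
    }
    art_year <- sample(seq(config$year_range[1], config$year_range[2]),
                       n_art, replace = TRUE)
    art_npat <- draw_int_range(n_art, config$patients_per_article)

    # posterior semiology mix inside topological articles: P(s|f) ~ P(f|s) P(s)
    posterior <- lapply(setNames(nm = names(config$focus_distribution)),
                        function(f) {
                          w <- cond[, f] * marg
                          w / sum(w)
                        })

    unit_rows <- vector("list", n_art)
    for (a in seq_len(n_art)) {
      npat <- art_npat[a]
      nsem <- draw_int_range(npat, config$semiologies_per_patient)
      prob <- if (art_topo[a]) posterior[[art_focus[a]]] else marg
      pat_cat <- lapply(nsem, function(k) sample(cats, k, prob = prob))
      unit_rows[[a]] <- data.frame(
        article = a,
        patient = rep(seq_len(npat), nsem),
        category = unlist(pat_cat),
        stringsAsFactors = FALSE)
    }
    units <- do.call(rbind, unit_rows)
    n_units <- nrow(units)
    units$topological <- art_label[units$article]
    units$is_topo <- art_topo[units$article]

    # region draws
    units$r1 <- NA_character_
    units$r2 <- NA_character_
    topo_idx <- which(units$is_topo)
    units$r1[topo_idx] <- art_focus[units$article[topo_idx]]
    for (cc in cats) {
      sel <- which(!units$is_topo & units$category == cc)
      if (!length(sel)) next
      units$r1[sel] <- sample(regions, length(sel), replace = TRUE,
                              prob = cond[cc, ])
      multi <- sel[stats::runif(length(sel)) < config$p_multiregion]
      if (length(multi)) {
        units$r2[multi] <- sample(regions, length(multi), replace = TRUE,
                                  prob = cond[cc, ])
      }
    }
    units$r1 <- refine_temporal(units$r1, config$temporal_subregion_probs)
    has_r2 <- !is.na(units$r2)
    units$r2[has_r2] <- refine_temporal(units$r2[has_r2],
                                        config$temporal_subregion_probs)

    # ground truths: independent flags, rejection guarantees >= 1
    gtp <- config$ground_truth_probs
    gt <- matrix(FALSE, n_units, 3,
                 dimnames = list(NULL, gt_flag_cols()))
    todo <- seq_len(n_units)
    while (length(todo)) {
      for (k in 1:3) {
        gt[todo, k] <- stats::runif(length(todo)) < gtp[k]
      }
      todo <- todo[rowSums(gt[todo, , drop = FALSE]) == 0]
    }

    age <- sample(names(config$age_probs), n_units, replace = TRUE,
                  prob = config$age_probs)

    # assemble wide allocation columns
    alloc_nodes <- unique(c(regions, names(config$temporal_subregion_probs)))
    alloc <- matrix(0, n_units, length(alloc_nodes),
                    dimnames = list(NULL, alloc_nodes))
    alloc[cbind(seq_len(n_units), match(units$r1, alloc_nodes))] <-
      ifelse(has_r2, 0.5, 1)
    idx2 <- which(has_r2)
    for (i in idx2) {
      alloc[i, units$r2[i]] <- alloc[i, units$r2[i]] + 0.5
    }

    txt <- CATEGORY_TEXT_TEMPLATES[units$category]
    txt[is.na(txt)] <- tolower(units$category[is.na(txt)])
    df <- data.frame(
      patient_id = sprintf("A%03d-P%03d", units$article, units$patient),
      article_id = sprintf("A%03d", units$article),
      year = art_year[units$article],
      semiology_text = unname(txt),
      semiology_category = units$category,
      topological = units$topological,
      gt_seizure_free = gt[, "gt_seizure_free"],
      gt_concordance = gt[, "gt_concordance"],
      gt_invasive = gt[, "gt_invasive"],
      age_label = age,
      laterality_semiology = "unknown",
      laterality_dominance = "unknown",
      stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(alloc, check.names = FALSE))
    list(df = df, units = units)
  })

  records <- as_semio_records(out$df, tree = tree)

  is_topo_unit <- out$units$is_topo
  counts <- function(keep) {
    table(factor(out$units$category[keep], levels = cats))
  }
  w_topo <- mean(is_topo_unit)
  marginal_nontopo <- as.vector(marg %*% cond)
  names(marginal_nontopo) <- regions
  focus_full <- setNames(numeric(length(regions)), regions)
  focus_full[names(config$focus_distribution)] <- config$focus_distribution
  marginal_pooled <- (1 - config$pi_topological) * marginal_nontopo +
    config$pi_topological * focus_full
  truth <- list(
    true_conditional = cond,
    semiology_marginal = marg,
    region_marginal_nontopological = marginal_nontopo,
    region_marginal_pooled_expected = marginal_pooled,
    focus_distribution = config$focus_distribution,
    pi_topological = config$pi_topological,
    realized_topological_unit_fraction = w_topo,
    n_units = nrow(out$units),
    n_patients = length(unique(paste(out$units$article, out$units$patient))),
    units_per_category_topological = counts(is_topo_unit),
    units_per_category_nontopological = counts(!is_topo_unit),
    seed = config$seed)
  list(records = records, truth = truth)
}
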