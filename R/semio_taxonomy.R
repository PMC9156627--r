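# Free-text semiology -> category mapping with negation and
# string-similarity safeguards.

NEGATION_CUES <- c("no", "not", "without", "denies", "denied", "absence",
                   "absent", "never")

#' Load a semiology taxonomy
#'
#' Reads a YAML/JSON taxonomy mapping each category to its kind (`ictal`,
#' `postictal`, `asymptomatic`), case-insensitive include patterns, optional
#' exclude patterns (longer terms that must not trigger the category, e.g.
#' so that "dystonic" never fires a tonic rule), and a per-rule negation
#' window in tokens. The shipped default covers the twelve most common ictal
#' categories plus the postictal and asymptomatic categories; larger
#' inventories load from file the same way.
#'
#' @param path Path to a YAML/JSON taxonomy; `NULL` loads the shipped default.
#' @return A `semio_taxonomy` object (list with `version` and `categories`).
#' @examples
#' tax <- load_taxonomy()
#' names(tax$categories)
#' @export
load_taxonomy <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "semiology_taxonomy.yaml",
                        package = "semioloc", mustWork = TRUE)
  }
  def <- tryCatch(
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    },
    error = function(e) {
      stop_semioloc(paste0("cannot parse taxonomy definition: ",
                           conditionMessage(e)),
                    "semioloc_definition_error")
    })
  cats <- def$categories %||% list()
  if (anyDuplicated(names(cats))) {
    stop_semioloc("duplicate category names in taxonomy",
                  "semioloc_definition_error")
  }
  categories <- list()
  for (nm in names(cats)) {
    rule <- cats[[nm]]
    include <- as.character(rule$include %||% character())
    exclude <- as.character(rule$exclude %||% character())
    if (!length(include)) {
      stop_semioloc(sprintf("category '%s' has no include patterns", nm),
                    "semioloc_definition_error")
    }
    if (length(intersect(include, exclude))) {
      stop_semioloc(sprintf("category '%s' lists a pattern as both include and exclude", nm),
                    "semioloc_definition_error")
    }
    kind <- match.arg(rule$kind %||% "ictal",
                      c("ictal", "postictal", "asymptomatic"))
    categories[[nm]] <- list(
      name = nm, kind = kind, include = include, exclude = exclude,
      negation_window = as.integer(rule$negation_window %||% 3L))
  }
  structure(list(version = as.character(def$version %||% "unversioned"),
                 categories = categories),
            class = "semio_taxonomy")
}

#' @export
print.semio_taxonomy <- function(x, ...) {
  kinds <- vapply(x$categories, `[[`, "", "kind")
  cat(sprintf("semio_taxonomy v%s: %d categories (%d ictal, %d postictal, %d asymptomatic)\n",
              x$version, length(kinds), sum(kinds == "ictal"),
              sum(kinds == "postictal"), sum(kinds == "asymptomatic")))
  invisible(x)
}

#' Names of taxonomy categories, optionally by kind
#' @param taxonomy A `semio_taxonomy`.
#' @param kind `NULL` for all, or one of `"ictal"`, `"postictal"`,
#'   `"asymptomatic"`.
#' @return Character vector of category names.
#' @export
taxonomy_categories <- function(taxonomy, kind = NULL) {
  nms <- names(taxonomy$categories)
  if (is.null(kind)) return(nms)
  nms[vapply(taxonomy$categories, `[[`, "", "kind") == kind]
}

# token start offsets, for negation-window lookup
tokenize_starts <- function(text) {
  m <- gregexpr("[A-Za-z0-9']+", text)[[1]]
  if (m[1] == -1) integer() else as.integer(m)
}

negated_at <- function(text, starts, tokens_lower, match_start, window) {
  if (window <= 0 || !length(starts)) return(FALSE)
  tok_idx <- findInterval(match_start, starts)
  lo <- max(1L, tok_idx - window)
  hi <- tok_idx - 1L
  if (hi < lo) return(FALSE)
  cues <- which(tokens_lower[lo:hi] %in% NEGATION_CUES) + lo - 1L
  if (!length(cues)) return(FALSE)
  # a cue only reaches across its own clause: punctuation blocks it
  punct <- as.integer(gregexpr("[,;.]", text)[[1]])
  any(vapply(cues, function(j) {
    !any(punct > starts[j] & punct < match_start)
  }, logical(1)))
}

#' Classify a free-text semiology description
#'
#' Applies each category's include patterns (case-insensitive, word-boundary
#' regular expressions). A match is suppressed when (a) its span lies inside
#' a longer excluded term for that category, or (b) a negation cue ("no",
#' "not", "without", "denies", "absence of", ...) occurs within the rule's
#' negation window of tokens before the span. Classification is deterministic
#' and invariant to letter case and surrounding whitespace. An empty result
#' means unclassified.
#'
#' @param taxonomy A `semio_taxonomy`.
#' @param text Character scalar, non-empty.
#' @return Character vector of matching category names (sorted, unique).
#' @examples
#' tax <- load_taxonomy()
#' classify_text(tax, "lip smacking and chewing")
#' classify_text(tax, "dystonic posturing of right hand")
#' @export
classify_text <- function(taxonomy, text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) {
    stop_semioloc("text must be non-empty", "semioloc_config_error")
  }
  starts <- tokenize_starts(text)
  tokens_lower <- tolower(regmatches(text, gregexpr("[A-Za-z0-9']+", text))[[1]])
  hits <- character()
  for (rule in taxonomy$categories) {
    # mask spans of excluded longer terms so includes cannot fire inside them
    masked <- text
    for (ex in rule$exclude) {
      m <- gregexpr(ex, masked, ignore.case = TRUE, perl = TRUE)[[1]]
      if (m[1] != -1) {
        for (k in seq_along(m)) {
          len <- attr(m, "match.length")[k]
          substr(masked, m[k], m[k] + len - 1L) <-
            paste(rep("\r", len), collapse = "")
        }
      }
    }
    matched <- FALSE
    for (pat in rule$include) {
      m <- gregexpr(pat, masked, ignore.case = TRUE, perl = TRUE)[[1]]
      if (m[1] == -1) next
      for (k in seq_along(m)) {
        if (!negated_at(masked, starts, tokens_lower, m[k],
                        rule$negation_window)) {
          matched <- TRUE
          break
        }
      }
      if (matched) break
    }
    if (matched) hits <- c(hits, rule$name)
  }
  sort(unique(hits))
}

#' Assign taxonomy categories to records
#'
#' Classifies each record's free text (and any pre-assigned category string,
#' mirroring how both the exact wording and summary categories are searched)
#' and expands multi-category texts so that each (patient, category) pair
#' becomes its own analysis unit. Records whose text matches no category
#' keep their pre-assigned category if present, otherwise they are dropped
#' with a message.
#'
#' @param records A `semio_records` object.
#' @param taxonomy A `semio_taxonomy`.
#' @return A `semio_records` object with `semiology_category` filled.
#' @export
classify_records <- function(records, taxonomy) {
  rows <- list()
  dropped <- 0L
  for (i in seq_len(nrow(records))) {
    pre_cat <- records$semiology_category[i]
    if (is.na(pre_cat)) pre_cat <- ""
    query <- trimws(paste(records$semiology_text[i], pre_cat))
    cats <- classify_text(taxonomy, if (nzchar(query)) query else "unclassifiable")
    if (!length(cats)) {
      if (nzchar(pre_cat)) {
        cats <- pre_cat
      } else {
        dropped <- dropped + 1L
        next
      }
    }
    for (cc in cats) {
      r <- records[i, , drop = FALSE]
      r$semiology_category <- cc
      rows[[length(rows) + 1L]] <- r
    }
  }
  if (dropped > 0L) {
    message(sprintf("classify_records: %d record(s) unclassified and dropped", dropped))
  }
  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    records[0, , drop = FALSE]
  }
  structure(out, region_cols = region_cols(records),
            class = c("semio_records", "data.frame"))
}

#' Remove postictal and asymptomatic records
#'
#' Only symptomatic ictal semiologies carry localizing information for the
#' analyses here; postictal and asymptomatic categories are removed before
#' any probability or odds-ratio computation.
#'
#' @param records A `semio_records` object with categories assigned.
#' @param taxonomy A `semio_taxonomy` defining category kinds.
#' @return Filtered `semio_records`.
#' @export
strip_nonictal <- function(records, taxonomy) {
  nonictal <- c(taxonomy_categories(taxonomy, "postictal"),
                taxonomy_categories(taxonomy, "asymptomatic"))
  out <- records[!(records$semiology_category %in% nonictal), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, region_cols = region_cols(records),
            class = c("semio_records", "data.frame"))
}
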