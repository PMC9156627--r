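# Hierarchical brain-region tree: loading, junction redistribution, roll-up.

TOP_LEVEL_REGIONS <- c("Temporal", "Frontal", "Parietal", "Occipital",
                       "Cingulate", "Insula", "Hypothalamus", "Cerebellum")
TEMPORAL_SUBREGIONS <- c("Mesial Temporal", "Anterior Temporal",
                         "Lateral Temporal", "Posterior Temporal",
                         "Basal Temporal")
# Seven regions shown in forest reports (Cerebellum and standalone nodes are
# folded into an "Other" remainder where a full partition is required).
FOREST_REGIONS <- c("Temporal", "Frontal", "Parietal", "Occipital",
                    "Cingulate", "Insula", "Hypothalamus")

#' Load a hierarchical brain-region tree
#'
#' Reads a YAML/JSON adjacency definition with the eight fixed top-level
#' regions (temporal, frontal, parietal, occipital, cingulate, insula,
#' hypothalamus, cerebellum), five named temporal subregions, interlobar
#' junction categories mapping to their constituent lobes, and standalone
#' nodes kept outside the hierarchy (subcallosal cortex). Additional
#' descendants under any node are permitted, so the tree extends to finer
#' descriptive regions of interest.
#'
#' @param path Path to a YAML or JSON definition. `NULL` loads the tree
#'   shipped with the package.
#' @return A `region_tree` object: list with elements `nodes`, `parent`
#'   (named character), `children` (named list), `top_level`, `junctions`
#'   (named list of constituent top-level regions), `standalone`.
#' @examples
#' tree <- load_region_tree()
#' tree$top_level
#' tree$children$Temporal
#' @export
load_region_tree <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "region_tree.yaml", package = "semioloc",
                        mustWork = TRUE)
  }
  def <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  top <- as.character(def$top_level %||% character())
  if (!setequal(top, TOP_LEVEL_REGIONS)) {
    stop_semioloc(paste0("top-level region set is fixed; expected exactly: ",
                         paste(TOP_LEVEL_REGIONS, collapse = ", ")),
                  "semioloc_definition_error")
  }
  children <- lapply(def$children %||% list(), as.character)
  junctions <- lapply(def$junctions %||% list(), as.character)
  standalone <- as.character(def$standalone %||% character())

  parent <- character()
  for (p in names(children)) {
    for (ch in children[[p]]) {
      if (ch %in% names(parent)) {
        stop_semioloc(sprintf("node '%s' has more than one parent", ch),
                      "semioloc_definition_error")
      }
      parent[[ch]] <- p
    }
  }
  nodes <- unique(c(TOP_LEVEL_REGIONS, names(parent), unlist(children),
                    standalone))
  # every non-top node must attach (directly or transitively) to a top-level
  for (nd in setdiff(nodes, c(TOP_LEVEL_REGIONS, standalone))) {
    cur <- nd
    seen <- character()
    repeat {
      if (cur %in% seen) {
        stop_semioloc(sprintf("cycle detected at node '%s'", nd),
                      "semioloc_definition_error")
      }
      seen <- c(seen, cur)
      if (cur %in% TOP_LEVEL_REGIONS) break
      if (!cur %in% names(parent)) {
        stop_semioloc(sprintf("orphan node '%s' (no path to a top-level region)", nd),
                      "semioloc_definition_error")
      }
      cur <- parent[[cur]]
    }
  }
  if (!setequal(children[["Temporal"]] %||% character(), TEMPORAL_SUBREGIONS)) {
    stop_semioloc("Temporal must have exactly the five named subregions",
                  "semioloc_definition_error")
  }
  for (j in names(junctions)) {
    cons <- junctions[[j]]
    if (length(cons) == 0) {
      stop_semioloc(sprintf("junction '%s' has no constituents", j),
                    "semioloc_definition_error")
    }
    if (!all(cons %in% TOP_LEVEL_REGIONS)) {
      stop_semioloc(sprintf("junction '%s' has non-top-level constituents", j),
                    "semioloc_definition_error")
    }
  }
  structure(list(nodes = nodes, parent = parent, children = children,
                 top_level = top[match(TOP_LEVEL_REGIONS, top)],
                 junctions = junctions, standalone = standalone),
            class = "region_tree")
}

#' @export
print.region_tree <- function(x, ...) {
  cat("Brain-region tree:", length(x$nodes), "nodes\n")
  cat("  top level: ", paste(x$top_level, collapse = ", "), "\n", sep = "")
  cat("  junctions: ", length(x$junctions),
      " | standalone: ", paste(x$standalone, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' All region names addressable in a record (tree nodes + junctions)
#' @param tree A `region_tree`.
#' @return Character vector of valid allocation column names.
#' @export
region_names <- function(tree) {
  unique(c(tree$nodes, names(tree$junctions)))
}

#' Descendants of a region node
#'
#' @param tree A `region_tree`.
#' @param node A node name in the tree.
#' @return Character vector of all strict descendants (may be empty).
#' @export
region_descendants <- function(tree, node) {
  if (!node %in% tree$nodes) {
    stop_semioloc(sprintf("unknown region node '%s'", node),
                  "semioloc_lookup_error")
  }
  out <- character()
  frontier <- tree$children[[node]] %||% character()
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- unlist(lapply(frontier, function(n) tree$children[[n]] %||% character()),
                       use.names = FALSE)
  }
  out
}

#' Redistribute interlobar-junction allocations to top-level lobes
#'
#' Junction categories (e.g. temporo-parietal) exist only as a data-entry
#' convenience; before analysis their mass is split equally among the
#' constituent top-level lobes, so an allocation of weight `w` over a
#' junction with `k` constituents becomes `w/k` on each lobe. Non-junction
#' weights, including the standalone subcallosal cortex, are untouched.
#' Total weight is conserved.
#'
#' @param x Named numeric vector of non-negative allocations over region
#'   nodes and/or junction names.
#' @param tree A `region_tree`.
#' @return Named numeric vector with junction names removed.
#' @examples
#' tree <- load_region_tree()
#' redistribute_junctions(c("Temporo-parietal" = 1), tree)
#' @export
redistribute_junctions <- function(x, tree) {
  bad <- setdiff(names(x), region_names(tree))
  if (length(bad)) {
    stop_semioloc(paste0("unknown region node(s): ", paste(bad, collapse = ", ")),
                  "semioloc_lookup_error")
  }
  jn <- intersect(names(x), names(tree$junctions))
  out <- x[setdiff(names(x), jn)]
  for (j in jn) {
    cons <- tree$junctions[[j]]
    add <- x[[j]] / length(cons)
    for (cn in cons) out[cn] <- (if (cn %in% names(out)) out[[cn]] else 0) + add
  }
  out
}

#' Roll up allocation weight from a node and all its descendants
#'
#' A lobe's weight includes undifferentiated allocations to the lobe itself
#' plus allocations to any of its subregions.
#'
#' @param x Named numeric vector of allocations over tree nodes.
#' @param node Node at which to aggregate.
#' @param tree A `region_tree`.
#' @return Single numeric weight.
#' @examples
#' tree <- load_region_tree()
#' rollup(c("Mesial Temporal" = 0.6, Temporal = 0.4), "Temporal", tree)
#' @export
rollup <- function(x, node, tree) {
  fam <- c(node, region_descendants(tree, node))
  sum(x[intersect(names(x), fam)])
}
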