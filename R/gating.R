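# Declarative gating engine.  A gating tree is a DAG of threshold gates
# over the marker panel; events are classified by traversing the tree, and
# population counts are read off the nodes that population definitions
# point to.

#' Path to the packaged default gating configuration
#' @return file path of the YAML config encoding the default 30-population
#'   hierarchy.
#' @export
default_gating_config <- function() {
  system.file("extdata", "gating_default.yaml", package = "tilprofiler",
              mustWork = TRUE)
}

#' Load and validate a gating tree
#'
#' Reads a YAML gating configuration (panel, per-channel thresholds, gate
#' nodes, population definitions, denominator map) and validates its
#' structure: known markers, existing parents, acyclicity, unique
#' population ids.
#'
#' @param path YAML file; defaults to the packaged configuration.
#' @return a validated `gating_tree` list.
#' @export
load_gating_config <- function(path = default_gating_config()) {
  if (!file.exists(path)) stop("gating config not found: ", path)
  cfg <- yaml::read_yaml(path)
  panel_channels <- c(cfg$panel$markers, cfg$panel$scatter,
                      cfg$panel$viability)

  node_ids <- vapply(cfg$nodes, function(n) n$id, character(1))
  if (anyDuplicated(node_ids)) {
    stop("duplicate node id(s): ",
         paste(unique(node_ids[duplicated(node_ids)]), collapse = ", "))
  }
  polarities <- c("positive", "negative", "low", "high", "expressed")
  for (n in cfg$nodes) {
    if (is.null(n$parent)) stop("node '", n$id, "' has no parent")
    if (n$parent != "root" && !n$parent %in% node_ids) {
      stop("node '", n$id, "' references missing parent '", n$parent, "'")
    }
    for (g in n$gates) {
      if (!g$marker %in% panel_channels) {
        stop("node '", n$id, "' gates on unknown marker '", g$marker, "'")
      }
      if (!g$polarity %in% polarities) {
        stop("node '", n$id, "' has unknown polarity '", g$polarity, "'")
      }
    }
  }
  # acyclicity / reachability: every node must resolve to root by parents
  parent <- stats::setNames(vapply(cfg$nodes, function(n) n$parent,
                                   character(1)), node_ids)
  for (id in node_ids) {
    seen <- character(0)
    cur <- id
    while (cur != "root") {
      if (cur %in% seen) stop("cycle detected at node '", cur, "'")
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
  }
  pop_ids <- vapply(cfg$populations, function(p) p$id, character(1))
  if (anyDuplicated(pop_ids)) {
    stop("duplicate population id(s): ",
         paste(unique(pop_ids[duplicated(pop_ids)]), collapse = ", "))
  }
  for (p in cfg$populations) {
    if (!p$node %in% node_ids) {
      stop("population '", p$id, "' references missing node '", p$node, "'")
    }
  }
  structure(list(
    panel = cfg$panel,
    thresholds = cfg$thresholds,
    nodes = cfg$nodes,
    node_ids = node_ids,
    parent = parent,
    populations = cfg$populations,
    population_ids = pop_ids,
    denominators = cfg$denominators
  ), class = "gating_tree")
}

# thresholds for one channel, falling back to the default pair
.channel_thresholds <- function(tree, marker) {
  th <- tree$thresholds[[marker]] %||% tree$thresholds$default
  c(negative = th$negative, positive = th$positive)
}

#' Enumerate populations in deterministic depth-first order
#'
#' @param tree a `gating_tree`.
#' @return character vector of population ids, ordered by a depth-first
#'   traversal of the node hierarchy in configuration order.
#' @export
enumerate_populations <- function(tree) {
  stopifnot(inherits(tree, "gating_tree"))
  node_pop <- stats::setNames(rep(NA_character_, length(tree$node_ids)),
                              tree$node_ids)
  for (p in tree$populations) node_pop[[p$node]] <- p$id
  children <- split(tree$node_ids, tree$parent[tree$node_ids])
  out <- character(0)
  visit <- function(id) {
    if (!is.na(node_pop[[id]])) out <<- c(out, node_pop[[id]])
    for (ch in tree$node_ids[tree$node_ids %in% (children[[id]] %||% character(0))]) {
      visit(ch)
    }
  }
  roots <- tree$node_ids[tree$parent[tree$node_ids] == "root"]
  for (r in roots) visit(r)
  out
}

#' Gate an event table into population counts
#'
#' Classifies every event through the threshold hierarchy and returns
#' per-population counts plus the denominator totals (`cd45`, `cd4`,
#' `cd8`, `myeloid`) needed for fraction tables.  Child counts never exceed
#' their parent count by construction.
#'
#' @param events numeric matrix or data.frame with one row per event and a
#'   column per panel channel.
#' @param tree a `gating_tree`.
#' @param sample_id identifier stored in the result.
#' @return a `population_counts` list: `sample_id`, `counts` (named
#'   integers over the tree's populations), `totals`, `n_events`.
#' @export
gate_events <- function(events, tree = load_gating_config(),
                        sample_id = "sample") {
  stopifnot(inherits(tree, "gating_tree"))
  if (is.data.frame(events)) events <- as.matrix(events)
  channels <- c(tree$panel$markers, tree$panel$scatter, tree$panel$viability)
  n <- if (is.null(events)) 0L else nrow(events)
  if (n > 0) {
    missing <- setdiff(channels, colnames(events))
    if (length(missing)) {
      stop("event table is missing channel(s): ",
           paste(missing, collapse = ", "))
    }
  }
  masks <- list(root = rep(TRUE, n))
  for (nd in tree$nodes) {
    m <- masks[[nd$parent]]
    for (g in nd$gates) {
      th <- .channel_thresholds(tree, g$marker)
      x <- if (n > 0) events[, g$marker] else numeric(0)
      pass <- switch(g$polarity,
        positive = x >= th[["positive"]],
        high     = x >= th[["positive"]],
        negative = x < th[["positive"]],
        low      = x >= th[["negative"]] & x < th[["positive"]],
        expressed = x >= th[["negative"]]
      )
      m <- m & pass
    }
    masks[[nd$id]] <- m
  }
  counts <- vapply(tree$populations, function(p) sum(masks[[p$node]]),
                   numeric(1))
  names(counts) <- tree$population_ids
  den <- tree$denominators
  tot_myeloid <- sum(vapply(den$myeloid, function(id) {
    nd <- tree$populations[[match(id, tree$population_ids)]]$node
    sum(masks[[nd]])
  }, numeric(1)))
  totals <- c(
    events = n,
    live = sum(masks[["live"]]),
    cd45 = sum(masks[[den$cd45]]),
    cd4 = sum(masks[[den$cd4]]),
    cd8 = sum(masks[[den$cd8]]),
    myeloid = tot_myeloid
  )
  structure(list(sample_id = sample_id, counts = counts, totals = totals),
            class = "population_counts")
}

#' Gate every sample of a cohort bundle
#'
#' @param samples named list of event matrices (as from
#'   [simulate_cohort()]`$samples`).
#' @param tree a `gating_tree`.
#' @return named list of `population_counts`.
#' @export
gate_cohort <- function(samples, tree = load_gating_config()) {
  out <- lapply(names(samples), function(id) {
    gate_events(samples[[id]], tree, sample_id = id)
  })
  stats::setNames(out, names(samples))
}

#' Assemble a samples-by-populations count matrix
#'
#' @param counts_list list of `population_counts`.
#' @return integer matrix, rows = samples, columns = populations.
#' @export
counts_matrix <- function(counts_list) {
  stopifnot(length(counts_list) > 0)
  m <- do.call(rbind, lapply(counts_list, function(x) x$counts))
  rownames(m) <- vapply(counts_list, function(x) x$sample_id, character(1))
  m
}

#' Assemble the denominator totals of gated samples
#'
#' @param counts_list list of `population_counts`.
#' @return numeric matrix, rows = samples, columns = totals (`events`,
#'   `live`, `cd45`, `cd4`, `cd8`, `myeloid`).
#' @export
totals_matrix <- function(counts_list) {
  m <- do.call(rbind, lapply(counts_list, function(x) x$totals))
  rownames(m) <- vapply(counts_list, function(x) x$sample_id, character(1))
  m
}

#' @export
print.population_counts <- function(x, ...) {
  cat("Population counts for sample '", x$sample_id, "' (",
      x$totals[["events"]], " events, ", x$totals[["cd45"]],
      " CD45+)\n", sep = "")
  print(x$counts)
  invisible(x)
}
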