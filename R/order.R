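#' Temporal total order of the studies
#'
#' Studies are ordered by calendar year; within a year, every lineage parent
#' precedes its children, remaining ties break on the `seq` ordinal and then
#' the id. The result is a linear extension of the DAG restricted to
#' non-same-report edges: for every such edge the parent's position is
#' strictly earlier than the child's.
#'
#' @param g An `aero_graph`.
#' @return Character vector of study ids, earliest first.
#' @examples
#' temporal_order(fixture_toy("figure2"))
#' @export
temporal_order <- function(g) {
  s <- g$studies
  if (nrow(s) == 0L) return(character())
  e <- g$edges
  yp <- s$year[match(e$parent, s$id)]
  yc <- s$year[match(e$child, s$id)]
  within <- e[yp == yc, , drop = FALSE]
  # lineage within a year must not contradict the seq ordinals
  if (nrow(within)) {
    sp <- s$seq[match(within$parent, s$id)]
    sc <- s$seq[match(within$child, s$id)]
    bad <- !within$same_report & sp > sc
    if (any(bad)) {
      rlang::abort(paste0(
        "within-year lineage contradicts seq ordinals on edge(s): ",
        paste(within$parent[bad], "->", within$child[bad], collapse = "; ")),
        class = "aero_error_order")
    }
  }
  out <- character(0)
  for (yr in sort(unique(s$year))) {
    block <- s[s$year == yr, , drop = FALSE]
    eb <- within[within$parent %in% block$id & within$child %in% block$id, ,
                 drop = FALSE]
    out <- c(out, kahn_min_key(block, eb))
  }
  out
}

# Kahn's algorithm picking, at each step, the available study with the
# smallest (seq, id) key; deterministic and respects within-year lineage.
kahn_min_key <- function(block, eb) {
  ids <- block$id
  indeg <- stats::setNames(integer(length(ids)), ids)
  tab <- table(eb$child)
  indeg[names(tab)] <- as.integer(tab)
  key <- order(block$seq, block$id)
  ids_by_key <- ids[key]
  placed <- character(0)
  remaining <- ids_by_key
  while (length(remaining)) {
    avail <- remaining[indeg[remaining] == 0L]
    if (!length(avail)) {
      rlang::abort("within-year lineage contains a cycle",
                   class = "aero_error_order")
    }
    nxt <- avail[1]
    placed <- c(placed, nxt)
    remaining <- setdiff(remaining, nxt)
    kids <- eb$child[eb$parent == nxt]
    indeg[kids] <- indeg[kids] - 1L
  }
  placed
}

#' Transitive reduction of the lineage edges
#'
#' Distils the lineage network to its unique minimal edge set with the same
#' reachability: an edge is dropped exactly when its endpoints are also
#' joined by a longer directed path. On a DAG the reduction is unique.
#' Same-report edges are always retained, since they record co-publication
#' rather than an inferable citation step.
#'
#' @param g An `aero_graph`.
#' @return The graph with redundant edges removed.
#' @examples
#' g <- fixture_moxifloxacin()
#' nrow(transitive_reduction(g)$edges) # one shortcut edge removed
#' @export
transitive_reduction <- function(g) {
  e <- g$edges
  if (nrow(e) < 2L) return(g)
  ig <- as_igraph(g)
  d <- igraph::distances(ig, mode = "out", weights = NA)
  ids <- igraph::V(ig)$name
  rownames(d) <- colnames(d) <- ids
  succ <- split(e$child, e$parent)
  redundant <- purrr::map2_lgl(e$parent, e$child, function(u, v) {
    via <- setdiff(succ[[u]], v)
    length(via) > 0L && any(is.finite(d[via, v]))
  })
  g$edges <- e[!(redundant & !e$same_report), , drop = FALSE]
  g
}

assert_known_ids <- function(g, ids) {
  unknown <- setdiff(ids, g$studies$id)
  if (length(unknown)) {
    rlang::abort(paste0("unknown study id(s): ", paste(unknown, collapse = ", ")),
                 class = "aero_error_validate")
  }
}

#' Reachability and path enumeration over lineage edges
#'
#' `ancestors()` returns every study upstream of `id` in the intellectual
#' lineage; `descendants()` every study downstream; `all_paths()` enumerates
#' the simple directed paths from `source` to `target`.
#'
#' @param g An `aero_graph`.
#' @param id,source,target Study ids.
#' @return For `ancestors()`/`descendants()`, a character vector of ids
#'   (excluding the query id); for `all_paths()`, a list of character
#'   vectors, each a directed path.
#' @examples
#' descendants(fixture_toy("figure2"), "a1")
#' @export
ancestors <- function(g, id) {
  assert_known_ids(g, id)
  reach(g, id, mode = "in")
}

#' @rdname ancestors
#' @export
descendants <- function(g, id) {
  assert_known_ids(g, id)
  reach(g, id, mode = "out")
}

reach <- function(g, id, mode) {
  ig <- as_igraph(g)
  v <- igraph::subcomponent(ig, id, mode = mode)
  setdiff(igraph::V(ig)$name[as.integer(v)], id)
}

#' @rdname ancestors
#' @export
all_paths <- function(g, source, target) {
  assert_known_ids(g, c(source, target))
  ig <- as_igraph(g)
  p <- igraph::all_simple_paths(ig, from = source, to = target, mode = "out")
  purrr::map(p, ~ igraph::V(ig)$name[as.integer(.x)])
}
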