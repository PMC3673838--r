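# Independent oracles used by the property tests. These deliberately avoid
# the package's own graph code: reachability is computed by Warshall's
# algorithm over a boolean matrix, paths by plain recursive enumeration.

# boolean reachability matrix (strictly positive path lengths)
closure_matrix <- function(g) {
  ids <- g$studies$id
  n <- length(ids)
  m <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  e <- g$edges
  for (i in seq_len(nrow(e))) m[e$parent[i], e$child[i]] <- TRUE
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      if (m[i, k]) m[i, ] <- m[i, ] | m[k, ]
    }
  }
  m
}

# brute-force transitive reduction: keep edge u->v unless some other
# successor w of u reaches v
tr_oracle_edges <- function(g) {
  cl <- closure_matrix(g)
  e <- g$edges
  keep <- vapply(seq_len(nrow(e)), function(i) {
    u <- e$parent[i]; v <- e$child[i]
    others <- e$child[e$parent == u & e$child != v]
    e$same_report[i] || !any(cl[others, v])
  }, logical(1))
  e[keep, , drop = FALSE]
}

# random small DAG on a single-phase ladder; edges only run forward in time
random_dag <- function(n, seed, p_edge = 0.3) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  studies <- tibble::tibble(
    id = ids, phase = "stage", year = 2000L + seq_len(n),
    outcome = sample(c("positive", "negative", "inconclusive"), n, TRUE)
  )
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  pick <- stats::runif(nrow(pairs)) < p_edge
  edges <- tibble::tibble(parent = ids[pairs[pick, "row"]],
                          child = ids[pairs[pick, "col"]])
  aero_graph(studies, if (nrow(edges)) edges else NULL,
             phases = aero_phases("stage"))
}

# every simple directed path in the graph, by plain DFS
enumerate_paths <- function(g) {
  succ <- split(g$edges$child, g$edges$parent)
  out <- list()
  walk <- function(path) {
    out[[length(out) + 1L]] <<- path
    for (nxt in succ[[path[length(path)]]]) walk(c(path, nxt))
  }
  for (id in g$studies$id) walk(id)
  out
}

edge_key <- function(edges) sort(paste(edges$parent, edges$child))
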