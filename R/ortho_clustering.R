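# Orthogroup inference: Markov clustering (MCL) of a bitscore-weighted
# protein similarity graph across inflation parameters, and the
# isolate-specific protein fraction statistic.  This is plain MCL on the
# hit graph (no length normalisation or reciprocal-best-hit phase); the
# granularity-versus-inflation behaviour is what the statistic depends
# on.

#' Build a protein similarity graph from homology hits
#'
#' Undirected graph on protein ids; the weight of an edge is the maximum
#' bitscore over the two hit directions.  Self hits are dropped.
#'
#' @param hits A [homology_hits()] table (cross- and within-isolate hits
#'   allowed).
#' @param node_isolates Named character vector mapping protein id to
#'   isolate id; proteins absent from `hits` are kept as isolated nodes.
#' @return Object of class `similarity_graph`: list with `nodes`,
#'   `isolate` (named by node) and `edges` (data frame `from`, `to`,
#'   `weight`).
#' @export
build_graph <- function(hits, node_isolates) {
  h <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  nodes <- sort(unique(c(names(node_isolates), h$query_id, h$subject_id)))
  missing <- setdiff(nodes, names(node_isolates))
  if (length(missing)) {
    stop("protein(s) without isolate tag: ",
         paste(head(missing, 5), collapse = ", "))
  }
  if (nrow(h)) {
    a <- pmin(h$query_id, h$subject_id)
    b <- pmax(h$query_id, h$subject_id)
    w <- tapply(h$bitscore, paste(a, b, sep = "\r"), max)
    ab <- strsplit(names(w), "\r", fixed = TRUE)
    edges <- data.frame(from = vapply(ab, `[`, "", 1L),
                        to = vapply(ab, `[`, "", 2L),
                        weight = as.numeric(w), stringsAsFactors = FALSE)
    if (any(edges$weight <= 0 | !is.finite(edges$weight))) {
      stop("edge weights must be finite and positive")
    }
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0))
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes,
                 isolate = node_isolates[nodes],
                 edges = edges),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat("similarity_graph:", length(x$nodes), "proteins,",
      nrow(x$edges), "edges,", length(unique(x$isolate)), "isolate(s)\n")
  invisible(x)
}

#' Markov clustering of a similarity graph
#'
#' Standard MCL: the weighted adjacency matrix gains self loops (loop
#' weight = the node's maximum incident edge weight, 1 for isolated
#' nodes), is column-normalised, then expansion (matrix square) and
#' inflation (elementwise power `inflation`, renormalise) alternate,
#' pruning entries below `prune`, until the largest column change falls
#' below `tol`.  Clusters are the connected components of the converged
#' matrix's support.  Deterministic for a fixed node order (nodes are
#' sorted lexicographically).
#'
#' @param graph A [build_graph()] result.
#' @param inflation Inflation parameter (> 1); larger values give finer
#'   clusters.
#' @param expansion Matrix power used for expansion (default 2).
#' @param prune Entries below this are zeroed each iteration.
#' @param max_iter Iteration cap; non-convergence returns the current
#'   clustering with a warning.
#' @param tol Convergence threshold on the max absolute entry change.
#' @return Object of class `orthogroup_set`: list with `clusters` (list
#'   of character vectors partitioning the node set), `inflation`,
#'   `iterations`, `converged`.
#' @export
mcl <- function(graph, inflation, expansion = 2L, prune = 1e-5,
                max_iter = 100L, tol = 1e-8) {
  if (inflation <= 1) stop("inflation must be > 1")
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0L) {
    return(structure(list(clusters = list(), inflation = inflation,
                          iterations = 0L, converged = TRUE),
                     class = "orthogroup_set"))
  }
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(graph$edges)) {
    i <- match(graph$edges$from, nodes)
    j <- match(graph$edges$to, nodes)
    A[cbind(i, j)] <- graph$edges$weight
    A[cbind(j, i)] <- graph$edges$weight
  }
  loop <- apply(A, 1, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    M2 <- M
    for (e in seq_len(expansion - 1L)) M2 <- M2 %*% M
    M2 <- M2^inflation
    M2[M2 < prune] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge in ", max_iter,
            " iterations; returning current clustering")
  }
  support <- (M > prune) | (t(M) > prune)
  g <- igraph::graph_from_adjacency_matrix(support, mode = "undirected")
  comp <- igraph::components(g)$membership
  clusters <- split(nodes, comp)
  names(clusters) <- NULL
  structure(list(clusters = clusters, inflation = inflation,
                 iterations = it, converged = converged),
            class = "orthogroup_set")
}

#' @export
print.orthogroup_set <- function(x, ...) {
  cat("orthogroup_set:", length(x$clusters), "cluster(s) at inflation",
      x$inflation, "\n")
  invisible(x)
}

#' Isolate-specific protein fraction
#'
#' A cluster is isolate-specific when all of its members carry the same
#' isolate tag; singletons count (`include_singletons = FALSE` excludes
#' size-1 clusters).  The statistic is 100 x (proteins in
#' isolate-specific clusters) / (total proteins).
#'
#' @param ogs An [mcl()] result.
#' @param node_isolates Named character vector protein id -> isolate id.
#' @param include_singletons Count size-1 clusters as isolate-specific?
#' @return Percentage (numeric scalar).
#' @export
isolate_specific_fraction <- function(ogs, node_isolates,
                                      include_singletons = TRUE) {
  members <- unlist(ogs$clusters)
  missing <- setdiff(members, names(node_isolates))
  if (length(missing)) {
    stop("protein(s) without isolate tag: ",
         paste(head(missing, 5), collapse = ", "))
  }
  total <- length(members)
  if (total == 0L) return(NA_real_)
  spec <- vapply(ogs$clusters, function(cl) {
    if (!include_singletons && length(cl) == 1L) return(0L)
    if (length(unique(node_isolates[cl])) == 1L) length(cl) else 0L
  }, 1L)
  100 * sum(spec) / total
}

#' Isolate-specific fraction across inflation parameters
#'
#' @param graph A [build_graph()] result.
#' @param inflations Numeric vector of inflation parameters.
#' @param ... Passed to [mcl()].
#' @return Data frame with columns `inflation`, `n_clusters`,
#'   `isolate_specific_pct`.
#' @export
inflation_profile <- function(graph,
                              inflations = c(1.5, 2, 4, 6, 8, 10), ...) {
  rows <- lapply(inflations, function(I) {
    ogs <- mcl(graph, inflation = I, ...)
    data.frame(inflation = I, n_clusters = length(ogs$clusters),
               isolate_specific_pct =
                 isolate_specific_fraction(ogs, graph$isolate))
  })
  do.call(rbind, rows)
}
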