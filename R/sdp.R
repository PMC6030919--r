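#' Build the dependency graph of a sentence
#'
#' One labelled edge per non-root token, from its syntactic head to the
#' token. The edge set forms a tree when direction is ignored.
#'
#' @param tokens token tibble for one sentence (`head` 1-based, `NA` root;
#'   `deprel` labels).
#' @return an object of class `ddi_depgraph`: list with `n_nodes` and an
#'   `edges` tibble (`head`, `dep`, `deprel`).
#' @export
dependency_graph <- function(tokens) {
  n <- nrow(tokens)
  if (sum(is.na(tokens$head)) != 1L) {
    abort(paste0("dependency structure is a forest: ",
                 sum(is.na(tokens$head)), " roots"))
  }
  check_head_tree(tokens$head, tokens$sentence_id[1] %||% "?")
  dep <- which(!is.na(tokens$head))
  structure(
    list(
      n_nodes = n,
      edges = tibble::new_tibble(
        list(head = as.integer(tokens$head[dep]), dep = dep,
             deprel = tokens$deprel[dep]),
        nrow = length(dep)
      )
    ),
    class = "ddi_depgraph"
  )
}

#' Shortest dependency path between two tokens
#'
#' Breadth-first search on the undirected view of the dependency graph.
#' On a tree the shortest path is unique, so BFS tie-breaking is
#' immaterial; per-edge direction along the walk is recorded anyway
#' (`"HD"` when the walk follows a head-to-dependent edge, `"DH"`
#' otherwise).
#'
#' @param graph a `ddi_depgraph`.
#' @param src,dst distinct 1-based token indices (the two entity tokens).
#' @return an object of class `ddi_sdp`: list with `nodes` (ordered token
#'   indices from `src` to `dst`), `rels` (deprel per edge) and `dirs`.
#' @export
sdp_extract <- function(graph, src, dst) {
  stopifnot(inherits(graph, "ddi_depgraph"))
  n <- graph$n_nodes
  if (src == dst) abort("src and dst must differ")
  if (src < 1L || src > n || dst < 1L || dst > n) abort("src/dst out of bounds")

  # undirected adjacency with edge bookkeeping
  ei <- c(graph$edges$head, graph$edges$dep)
  ej <- c(graph$edges$dep, graph$edges$head)
  eid <- rep(seq_len(nrow(graph$edges)), 2L)

  prev <- rep(NA_integer_, n)
  prev_edge <- rep(NA_integer_, n)
  seen <- logical(n)
  queue <- integer(n)
  queue[1L] <- src
  qhead <- 1L
  qtail <- 1L
  seen[src] <- TRUE
  while (qhead <= qtail) {
    v <- queue[qhead]
    qhead <- qhead + 1L
    if (v == dst) break
    for (k in which(ei == v)) {
      w <- ej[k]
      if (!seen[w]) {
        seen[w] <- TRUE
        prev[w] <- v
        prev_edge[w] <- k
        qtail <- qtail + 1L
        queue[qtail] <- w
      }
    }
  }
  if (!seen[dst]) abort("src and dst are not connected in the dependency graph")

  nodes <- dst
  edges <- integer(0)
  while (nodes[1] != src) {
    edges <- c(prev_edge[nodes[1]], edges)
    nodes <- c(prev[nodes[1]], nodes)
  }
  rels <- graph$edges$deprel[eid[edges]]
  # walk step i goes nodes[i] -> nodes[i+1]; stored edge k traverses
  # ei[k] -> ej[k], and the first copy of the edge list runs head -> dep
  dirs <- ifelse(edges <= nrow(graph$edges), "HD", "DH")
  structure(list(nodes = nodes, rels = rels, dirs = dirs), class = "ddi_sdp")
}

#' @export
print.ddi_sdp <- function(x, ...) {
  cat("<ddi_sdp> ", paste(x$nodes, collapse = " - "), "\n", sep = "")
  invisible(x)
}

#' Tokens on a shortest dependency path
#'
#' @param sdp a `ddi_sdp` from [sdp_extract()].
#' @param tokens the sentence's token tibble.
#' @return the on-path tokens in walk order, with columns `rel_to_next`
#'   and `dir_to_next` (`NA` on the last row) giving the dependency
#'   relation of the edge to the following path token.
#' @export
sdp_tokens <- function(sdp, tokens) {
  out <- tokens[sdp$nodes, ]
  out$rel_to_next <- c(sdp$rels, NA_character_)
  out$dir_to_next <- c(sdp$dirs, NA_character_)
  out
}

#' Attach shortest dependency paths to anonymized instances
#'
#' Extracts the SDP between the two placeholder tokens of every instance
#' and stores it in list-columns.
#'
#' @param instances tibble from [anonymize_instances()].
#' @return the tibble with list-columns `sdp` (node index vectors),
#'   `sdp_rels` and `sdp_dirs`.
#' @export
attach_sdp <- function(instances) {
  paths <- lapply(seq_len(nrow(instances)), function(i) {
    g <- dependency_graph(instances$tokens[[i]])
    sdp_extract(g, instances$e0_tok[i], instances$e1_tok[i])
  })
  instances$sdp <- map(paths, "nodes")
  instances$sdp_rels <- map(paths, "rels")
  instances$sdp_dirs <- map(paths, "dirs")
  instances
}
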