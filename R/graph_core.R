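# Directed word multigraph and its attributes.
#
# A speech graph has one node per distinct word and one edge occurrence per
# transition between successive tokens; immediate repetitions give self-loop
# occurrences and repeated transitions raise edge multiplicity. Counting
# measures (E, RE, L1, ATD) use multiplicities; density and the topology
# measures (D, DI, ASP, CC) use the simple (distinct-edge) structure.

ATTRIBUTE_NAMES <- c("N", "E", "WC", "RE", "PE", "L1", "L2", "L3",
                     "LCC", "LSC", "ATD", "D", "DI", "ASP", "CC")

#' Build a speech graph from a token window
#'
#' Nodes are the distinct tokens; each consecutive token pair contributes one
#' directed edge occurrence (self-pairs included). Edge multiplicities are
#' kept, so the object is a true multigraph.
#'
#' @param tokens Character vector of word tokens (or a `token_sequence`).
#' @return An object of class `speech_graph` with fields `nodes` (sorted
#'   character vector), `edges` (data frame `from`, `to`, `count`, ordered
#'   lexicographically for run-to-run stability) and `token_count`.
#' @export
speech_graph <- function(tokens) {
  if (inherits(tokens, "token_sequence")) tokens <- tokens$tokens
  stopifnot(is.character(tokens))
  if (length(tokens) == 0L) stop("empty token window: cannot build a graph")
  nodes <- sort(unique(tokens), method = "radix")
  k <- length(tokens)
  if (k >= 2L) {
    from <- tokens[-k]
    to <- tokens[-1L]
    key <- paste(from, to, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    edges <- data.frame(from = vapply(parts, `[[`, character(1), 1L),
                        to = vapply(parts, `[[`, character(1), 2L),
                        count = as.integer(tab),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to, method = "radix"), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        count = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, token_count = k),
            class = "speech_graph")
}

#' @export
print.speech_graph <- function(x, ...) {
  cat(sprintf("<speech_graph: %d nodes, %d edge occurrences (%d distinct), %d tokens>\n",
              length(x$nodes), sum(x$edges$count), nrow(x$edges),
              x$token_count))
  invisible(x)
}

#' Export a speech graph as an edge list
#'
#' @param g A `speech_graph`.
#' @param path Optional path; when given, writes a tab-separated file with
#'   columns `source`, `target`, `multiplicity`.
#' @return The edge-list data frame, invisibly when written to file.
#' @export
edge_list <- function(g, path = NULL) {
  stopifnot(inherits(g, "speech_graph"))
  out <- data.frame(source = g$edges$from, target = g$edges$to,
                    multiplicity = g$edges$count, stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}

# distinct-edge igraph view (multiplicities dropped); vertices = all nodes
as_igraph_simple <- function(g, drop_loops = FALSE) {
  e <- g$edges
  if (drop_loops) e <- e[e$from != e$to, , drop = FALSE]
  igraph::graph_from_data_frame(e[, c("from", "to")], directed = TRUE,
                                vertices = data.frame(name = g$nodes))
}

#' Recurrence counts: repeated and parallel edges
#'
#' `RE` counts excess traversals: for every distinct ordered word pair
#' (self-pairs included) multiplicity minus one, summed — so text without
#' repeated transitions has RE = 0. `PE` counts unordered pairs of distinct
#' words linked in both directions. `re_mode = "all"` instead counts every
#' occurrence of a repeated pair (multiplicity m contributes m, not m - 1).
#'
#' @param g A `speech_graph`.
#' @param re_mode "excess" (default) or "all".
#' @return Named numeric vector `c(RE =, PE =)`.
#' @export
recurrence_counts <- function(g, re_mode = c("excess", "all")) {
  stopifnot(inherits(g, "speech_graph"))
  re_mode <- match.arg(re_mode)
  m <- g$edges$count
  RE <- if (re_mode == "excess") sum(m - 1L) else sum(m[m >= 2L])
  e <- g$edges[g$edges$from != g$edges$to, , drop = FALSE]
  fwd <- paste(e$from, e$to, sep = "\r")
  rev <- paste(e$to, e$from, sep = "\r")
  PE <- sum(fwd %in% rev) / 2
  c(RE = RE, PE = PE)
}

#' Loop counts: self-loops, reciprocal pairs and directed triangles
#'
#' `L1` is the number of self-loop edge occurrences (with multiplicity);
#' `L2` the number of unordered node pairs with edges in both directions;
#' `L3` the number of directed 3-cycles over distinct node triples, each
#' cyclic class counted once (multiplicities ignored).
#'
#' @param g A `speech_graph`.
#' @return Named numeric vector `c(L1 =, L2 =, L3 =)`.
#' @export
loop_counts <- function(g) {
  stopifnot(inherits(g, "speech_graph"))
  L1 <- sum(g$edges$count[g$edges$from == g$edges$to])
  e <- g$edges[g$edges$from != g$edges$to, , drop = FALSE]
  fwd <- paste(e$from, e$to, sep = "\r")
  rev <- paste(e$to, e$from, sep = "\r")
  L2 <- sum(fwd %in% rev) / 2
  # directed 3-cycles once per cyclic class: trace(A^3)/3 on the binary
  # zero-diagonal adjacency matrix (no self-loops => every closed 3-walk is a
  # triangle over distinct nodes)
  n <- length(g$nodes)
  if (n >= 3L && nrow(e) >= 3L) {
    A <- matrix(0L, n, n, dimnames = list(g$nodes, g$nodes))
    A[cbind(match(e$from, g$nodes), match(e$to, g$nodes))] <- 1L
    L3 <- sum(diag(A %*% A %*% A)) / 3
  } else {
    L3 <- 0
  }
  c(L1 = L1, L2 = L2, L3 = L3)
}

#' Largest weakly connected component size
#'
#' Number of nodes in the largest component when edge direction is ignored.
#' Graphs built from a single token sequence are always weakly connected, so
#' for pipeline graphs LCC equals N; the general computation is kept for
#' hand-built graphs.
#'
#' @param g A `speech_graph`.
#' @return Integer component size.
#' @export
largest_weakly_connected <- function(g) {
  stopifnot(inherits(g, "speech_graph"))
  comp <- igraph::components(as_igraph_simple(g), mode = "weak")
  max(comp$csize)
}

#' Largest strongly connected component size
#'
#' Number of nodes in the largest set in which every node reaches every other
#' along directed paths — the long-range recurrence measure: returning to an
#' earlier word closes a directed cycle and enlarges the strongly connected
#' core.
#'
#' @param g A `speech_graph`.
#' @return Integer component size (1 for cycle-free graphs).
#' @export
largest_strongly_connected <- function(g) {
  stopifnot(inherits(g, "speech_graph"))
  comp <- igraph::components(as_igraph_simple(g), mode = "strong")
  max(comp$csize)
}

#' Global measures: degree, density, diameter, path length, clustering
#'
#' `ATD` is the average total degree, 2E/N with E counted with multiplicity
#' (a self-loop adds 2 to its node's degree). `D` is the number of distinct
#' directed non-self edges over N(N-1), 0 for a single node. `DI` (diameter)
#' and `ASP` (average shortest path) are unweighted shortest-path statistics
#' in edge counts; by default they are computed on the undirected simple
#' projection of the graph, restricted to the largest weak component, over
#' unordered node pairs. `CC` is the mean local clustering coefficient over
#' all nodes of the undirected simple projection (self-loops excluded;
#' nodes of degree < 2 contribute 0).
#'
#' Directed word graphs are usually not strongly connected, which would leave
#' directed all-pairs distances undefined; the undirected convention keeps DI
#' and ASP total. `distances = "directed_lsc"` instead computes them with
#' edge direction respected, inside the largest strongly connected component.
#'
#' @param g A `speech_graph`.
#' @param distances "undirected" (default) or "directed_lsc".
#' @return Named numeric vector `c(ATD =, D =, DI =, ASP =, CC =)`. A
#'   single-node graph yields DI = ASP = 0 by convention.
#' @export
global_measures <- function(g, distances = c("undirected", "directed_lsc")) {
  stopifnot(inherits(g, "speech_graph"))
  distances <- match.arg(distances)
  n <- length(g$nodes)
  E_mult <- sum(g$edges$count)
  ATD <- 2 * E_mult / n
  nonself <- g$edges$from != g$edges$to
  D <- if (n >= 2L) sum(nonself) / (n * (n - 1)) else 0

  gi <- as_igraph_simple(g, drop_loops = TRUE)
  gu <- igraph::as_undirected(gi, mode = "collapse")

  # clustering over ALL nodes of the projection
  cc_local <- igraph::transitivity(gu, type = "local", isolates = "zero")
  CC <- if (n >= 1L) mean(cc_local) else 0

  if (distances == "undirected") {
    comp <- igraph::components(gu)
    members <- which(comp$membership == which.max(comp$csize))
    sub <- igraph::induced_subgraph(gu, members)
    dm <- igraph::distances(sub)
  } else {
    comp <- igraph::components(gi, mode = "strong")
    members <- which(comp$membership == which.max(comp$csize))
    sub <- igraph::induced_subgraph(gi, members)
    dm <- igraph::distances(sub, mode = "out")
  }
  if (nrow(dm) >= 2L) {
    vals <- dm[upper.tri(dm)]
    if (distances == "directed_lsc") {
      vals <- c(vals, t(dm)[upper.tri(dm)])  # ordered pairs when directed
    }
    DI <- max(vals)
    ASP <- mean(vals)
  } else {
    DI <- 0
    ASP <- 0
  }
  c(ATD = ATD, D = D, DI = DI, ASP = ASP, CC = CC)
}

# boolean transitive closure (paths of length >= 0) by repeated squaring
bool_closure <- function(M) {
  R <- M
  diag(R) <- 1
  repeat {
    R2 <- (R %*% R) > 0
    storage.mode(R2) <- "double"
    if (all(R2 == R)) return(R2)
    R <- R2
  }
}

# all-pairs unweighted distances within one connected undirected graph,
# by breadth-first wavefronts of matrix products
bfs_distances <- function(U) {
  m <- nrow(U)
  Dist <- matrix(0, m, m)
  reached <- diag(1, m)
  front <- reached
  d <- 0
  while (any(reached == 0) && d < m) {
    d <- d + 1
    front <- (front %*% U) > 0
    storage.mode(front) <- "double"
    newly <- front * (1 - reached)
    Dist[newly > 0] <- d
    reached <- pmin(reached + newly, 1)
  }
  Dist
}

#' Compute the full speech-graph attribute vector
#'
#' Computes the 15 attributes of a token window: general characteristics N
#' (nodes), E (edge occurrences, with multiplicity) and WC (token count of
#' the window); recurrence characteristics RE, PE, L1, L2, L3; connectivity
#' characteristics LCC, LSC, ATD; and the global measures D, DI, ASP, CC.
#'
#' This is a self-contained dense-matrix implementation tuned for the small
#' (window-sized) graphs the pipeline produces; the per-operation functions
#' ([recurrence_counts()], [largest_strongly_connected()],
#' [global_measures()], ...) form an independent igraph-backed route that
#' must agree with it, and the test suite checks that they do.
#'
#' @param tokens Character vector of tokens, a `token_sequence`, or a
#'   `speech_graph`.
#' @param re_mode "excess" (default: multiplicity minus one per distinct
#'   pair) or "all"; see [recurrence_counts()].
#' @param distances "undirected" (default) or "directed_lsc"; see
#'   [global_measures()].
#' @return Named numeric vector of length 15 (class `graph_attributes`).
#' @examples
#' compute_attributes(c("a", "b", "c", "a", "b", "d"))
#' @export
compute_attributes <- function(tokens, re_mode = c("excess", "all"),
                               distances = c("undirected", "directed_lsc")) {
  re_mode <- match.arg(re_mode)
  distances <- match.arg(distances)
  if (inherits(tokens, "token_sequence")) tokens <- tokens$tokens
  if (inherits(tokens, "speech_graph")) {
    g <- tokens
    nodes <- g$nodes
    n <- length(nodes)
    k <- g$token_count
    Cnt <- matrix(0, n, n)
    Cnt[cbind(match(g$edges$from, nodes), match(g$edges$to, nodes))] <-
      g$edges$count
  } else {
    stopifnot(is.character(tokens))
    if (length(tokens) == 0L) stop("empty token window: cannot build a graph")
    k <- length(tokens)
    f <- factor(tokens, levels = sort(unique(tokens), method = "radix"))
    n <- nlevels(f)
    code <- as.integer(f)
    Cnt <- matrix(0, n, n)
    if (k >= 2L) {
      idx <- (code[-k] - 1L) * n + code[-1L]
      tab <- tabulate(idx, nbins = n * n)
      Cnt[] <- tab[matrix(seq_len(n * n), n, n, byrow = TRUE)]
    }
  }
  E <- sum(Cnt)
  Adj <- (Cnt > 0) * 1
  A0 <- Adj
  diag(A0) <- 0
  RE <- if (re_mode == "excess") E - sum(Adj) else sum(Cnt[Cnt >= 2])
  L1 <- sum(diag(Cnt))
  mutual <- A0 * t(A0)
  PE <- L2 <- sum(mutual) / 2
  L3 <- if (n >= 3L) sum(diag(A0 %*% A0 %*% A0)) / 3 else 0
  D <- if (n >= 2L) sum(A0) / (n * (n - 1)) else 0
  ATD <- 2 * E / n

  U <- ((A0 + t(A0)) > 0) * 1
  Wreach <- bool_closure(U)
  LCC <- max(rowSums(Wreach))
  Sreach <- bool_closure(Adj)
  LSC <- max(rowSums(Sreach * t(Sreach)))

  # clustering over all nodes of the undirected simple projection
  if (n >= 2L) {
    deg <- rowSums(U)
    tri <- diag(U %*% U %*% U) / 2
    cc_local <- ifelse(deg >= 2, tri / (deg * (deg - 1) / 2), 0)
    CC <- mean(cc_local)
  } else {
    CC <- 0
  }

  if (distances == "undirected") {
    members <- which(Wreach[which.max(rowSums(Wreach)), ] > 0)
    if (length(members) >= 2L) {
      Dm <- bfs_distances(U[members, members, drop = FALSE])
      vals <- Dm[upper.tri(Dm)]
      DI <- max(vals); ASP <- mean(vals)
    } else {
      DI <- 0; ASP <- 0
    }
  } else {
    mutual_reach <- Sreach * t(Sreach)
    members <- which(mutual_reach[which.max(rowSums(mutual_reach)), ] > 0)
    if (length(members) >= 2L) {
      glob <- global_measures(speech_graph_from_counts(Cnt, k),
                              distances = "directed_lsc")
      DI <- glob[["DI"]]; ASP <- glob[["ASP"]]
    } else {
      DI <- 0; ASP <- 0
    }
  }

  out <- c(N = n, E = E, WC = k, RE = RE, PE = PE, L1 = L1, L2 = L2,
           L3 = L3, LCC = LCC, LSC = LSC, ATD = ATD, D = D, DI = DI,
           ASP = ASP, CC = CC)
  structure(out[ATTRIBUTE_NAMES], class = "graph_attributes")
}

# rebuild a speech_graph from a multiplicity matrix (anonymous node labels)
speech_graph_from_counts <- function(Cnt, token_count) {
  n <- nrow(Cnt)
  labels <- sprintf("n%03d", seq_len(n))
  idx <- which(Cnt > 0, arr.ind = TRUE)
  edges <- data.frame(from = labels[idx[, 1]], to = labels[idx[, 2]],
                      count = as.integer(Cnt[idx]),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to, method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = labels, edges = edges, token_count = token_count),
            class = "speech_graph")
}

#' @export
print.graph_attributes <- function(x, ...) {
  print(round(unclass(x), 4))
  invisible(x)
}
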