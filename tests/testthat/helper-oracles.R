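# Independent brute-force oracles, deliberately naive: these validate the
# package's graph and statistics code paths and never share code with them.

# random token sequence over a small alphabet
random_tokens <- function(k, vocab = letters[1:5]) {
  sample(vocab, k, replace = TRUE)
}

# binary adjacency matrix (distinct directed edges, self-loops kept)
adjacency_from_tokens <- function(tokens) {
  nodes <- sort(unique(tokens))
  A <- matrix(FALSE, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  k <- length(tokens)
  if (k >= 2) {
    for (i in 1:(k - 1)) A[tokens[i], tokens[i + 1]] <- TRUE
  }
  A
}

# largest SCC size by Warshall transitive closure: i,j strongly connected
# iff i reaches j and j reaches i (path of length >= 0)
oracle_lsc <- function(tokens) {
  A <- adjacency_from_tokens(tokens)
  n <- nrow(A)
  R <- A | diag(TRUE, n)
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    R[i, j] <- R[i, j] || (R[i, k] && R[k, j])
  }
  mutual <- R & t(R)
  max(rowSums(mutual))
}

# largest weak component size by label propagation on the symmetrized matrix
oracle_lcc <- function(tokens) {
  A <- adjacency_from_tokens(tokens)
  M <- A | t(A) | diag(TRUE, nrow(A))
  lab <- seq_len(nrow(M))
  repeat {
    new <- vapply(seq_along(lab), function(i) min(lab[M[i, ]]), integer(1))
    if (identical(new, lab)) break
    lab <- new
  }
  max(table(lab))
}

# Floyd-Warshall diameter and average shortest path on the undirected simple
# projection (self-loops dropped), restricted to the largest weak component
oracle_di_asp <- function(tokens) {
  A <- adjacency_from_tokens(tokens)
  diag(A) <- FALSE
  U <- A | t(A)
  n <- nrow(U)
  D <- matrix(Inf, n, n)
  D[U] <- 1
  diag(D) <- 0
  if (n >= 1) for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    D[i, j] <- min(D[i, j], D[i, k] + D[k, j])
  }
  comp_sizes <- rowSums(is.finite(D))
  members <- which(comp_sizes == max(comp_sizes))
  # members of the largest component all see the same finite set; restrict
  Dc <- D[members, members, drop = FALSE]
  if (length(members) < 2) return(c(DI = 0, ASP = 0))
  vals <- Dc[upper.tri(Dc)]
  c(DI = max(vals), ASP = mean(vals))
}

# partial correlation of x and y given Z from the inverse of the Spearman
# correlation matrix of (x, y, Z)
oracle_partial_spearman_r <- function(x, y, Z) {
  M <- cbind(x, y, Z)
  R <- stats::cor(apply(M, 2, rank))
  P <- solve(R)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# disjoint union of two token-built graphs over disjoint alphabets
# (test-only construction; the pipeline never produces disconnected graphs)
union_speech_graph <- function(tokens1, tokens2) {
  stopifnot(length(intersect(tokens1, tokens2)) == 0)
  g1 <- speech_graph(tokens1)
  g2 <- speech_graph(tokens2)
  structure(list(nodes = sort(c(g1$nodes, g2$nodes)),
                 edges = rbind(g1$edges, g2$edges),
                 token_count = g1$token_count + g2$token_count),
            class = "speech_graph")
}
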