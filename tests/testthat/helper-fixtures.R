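# Shared fixtures and independent oracles, all built in code.

# Independent DTW reference: shortest path on the (i,j) lattice DAG with
# steps right/down/diagonal and node-entry costs |q_i - c_j|, solved by a
# generic graph shortest-path algorithm (igraph), entirely independent of
# the package's dynamic-programming implementation.
dtwRefShortestPath <- function(q, c) {
  n <- length(q); m <- length(c)
  cost <- outer(q, c, function(a, b) abs(a - b))
  id <- function(i, j) (i - 1L) * m + j
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (i in 1:n) for (j in 1:m) {
    if (i < n) { from <- c(from, id(i, j)); to <- c(to, id(i + 1, j))
                 w <- c(w, cost[i + 1, j]) }
    if (j < m) { from <- c(from, id(i, j)); to <- c(to, id(i, j + 1))
                 w <- c(w, cost[i, j + 1]) }
    if (i < n && j < m) { from <- c(from, id(i, j))
                          to <- c(to, id(i + 1, j + 1))
                          w <- c(w, cost[i + 1, j + 1]) }
  }
  g <- igraph::make_directed_graph(rbind(from, to), n * m)
  cost[1, 1] + igraph::distances(g, v = id(1, 1), to = id(n, m),
                                 mode = "out", weights = w)[1, 1]
}

# Adjusted Rand index between two labelings.
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# Small normal-template fixture shared across segmentation tests.
testTemplate <- function(dim = c(32, 32, 32), n = 41, seed = 11) {
  buildTemplate(simulateNormalStatics(n = n, dim = dim, seed = seed))
}

diceOverlap <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# z-normalize the rows of a matrix (population SD), for tests that start
# from plain matrices.
znormRows <- function(X) t(apply(X, 1, znormalize))
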