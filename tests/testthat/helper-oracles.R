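# Independent brute-force oracles used across the suite.  These are written
# against first principles (BFS, full enumeration) and never call the
# package's own implementations.

# All-pairs shortest-path distances by breadth-first search on an adjacency
# matrix (directed).
bfsDistances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- integer()
      for (v in frontier) nxt <- union(nxt, which(adj[v, ] == 1))
      nxt <- nxt[d[s, nxt] == Inf]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

# Betweenness centrality by explicit enumeration of all shortest paths
# (counts via dynamic programming on the BFS DAG).
enumBetweenness <- function(adj) {
  n <- nrow(adj)
  d <- bfsDistances(adj)
  # number of shortest paths between every ordered pair
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (dep in seq_len(n)) {
      layer <- which(d[s, ] == dep)
      for (v in layer) {
        preds <- which(adj[, v] == 1 & d[s, ] == dep - 1)
        sigma[s, v] <- sum(sigma[s, preds])
      }
    }
  }
  btw <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || !is.finite(d[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t]) {
        btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  btw
}

# Watts-Strogatz local clustering on the undirected projection of a
# directed adjacency matrix, by direct neighbour-pair counting.
enumClustering <- function(adj) {
  und <- (adj + t(adj)) > 0
  diag(und) <- FALSE
  n <- nrow(und)
  vapply(seq_len(n), function(v) {
    nb <- which(und[v, ])
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(und[nb, nb]) / 2
    links / choose(k, 2)
  }, 0)
}

# Exhaustive Barber-Q maximum over all joint row/column partitions into at
# most maxc modules (restricted growth strings avoid relabelings).
setPartitions <- function(n, maxc) {
  out <- list()
  rec <- function(prefix, used) {
    i <- length(prefix) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (b in seq_len(min(used + 1L, maxc)))
      rec(c(prefix, b), max(used, b))
  }
  rec(integer(), 0L)
  out
}

exhaustiveBarberMax <- function(A, maxc = NULL) {
  p <- nrow(A); q <- ncol(A); m <- sum(A)
  if (is.null(maxc)) maxc <- min(p, q)
  B <- A - outer(rowSums(A), colSums(A)) / m
  parts <- setPartitions(p + q, maxc)
  best <- -Inf
  for (pt in parts) {
    g <- pt[seq_len(p)]; h <- pt[p + seq_len(q)]
    Q <- sum(B[outer(g, h, "==")]) / m
    if (Q > best) best <- Q
  }
  best
}

# Hand log-rank: O-E and hypergeometric variance sums over distinct death
# times (two groups, right censoring).
handLogrank <- function(time, event, group) {
  dt <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in dt) {
    at1 <- sum(time >= t & group == "mutant")
    at0 <- sum(time >= t & group == "control")
    d1 <- sum(time == t & event == 1 & group == "mutant")
    d0 <- sum(time == t & event == 1 & group == "control")
    N <- at0 + at1; D <- d0 + d1
    O <- O + d1
    E <- E + D * at1 / N
    if (N > 1) V <- V + D * (at1 / N) * (at0 / N) * (N - D) / (N - 1)
  }
  list(chisq = (O - E)^2 / V, OminusE = O - E, V = V)
}

# internal constructor, convenient for building per-trial fixtures
trialTestResult <- ilpnet:::trialTestResult
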