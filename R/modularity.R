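# Barber bipartite modularity and the adaptive BRIM heuristic.
#
# For a binary incidence matrix A (p rows x q columns, m = sum(A)), a joint
# assignment of rows (g) and columns (h) to modules scores
#     Q = (1/m) * sum_ij (A_ij - k_i d_j / m) * delta(g_i, h_j)
# with k, d the row/column degrees.  BRIM alternates: holding column
# assignments fixed, each row moves to the module maximizing its summed
# contribution, then symmetrically for columns; Q never decreases, so the
# alternation reaches a fixed point.  The adaptive wrapper searches the
# module count and averages Q over random restarts.

# Null-adjusted incidence B = A - k d'/m, precomputed once per matrix.
barberB <- function(A) {
  m <- sum(A)
  if (m == 0) stop("modularity undefined: matrix has no interactions",
                   call. = FALSE)
  A - outer(rowSums(A), colSums(A)) / m
}

#' Barber bipartite modularity Q of a given partition
#'
#' @param A binary incidence matrix (rows and columns are the two node
#'   classes).
#' @param rowModules,colModules integer module assignments for rows and
#'   columns (shared label space).
#' @return Q (numeric scalar, <= 1).
#' @examples
#' barberQ(diag(2), 1:2, 1:2)        # 0.5
#' barberQ(diag(2), c(1, 1), c(1, 1))  # one module: 0
#' @export
barberQ <- function(A, rowModules, colModules) {
  stopifnot(length(rowModules) == nrow(A), length(colModules) == ncol(A))
  B <- barberB(A)
  delta <- outer(rowModules, colModules, "==")
  sum(B[delta]) / sum(A)
}

# One BRIM half-sweep pair.  G/H are one-hot assignment matrices
# (p x c, q x c).  Ties keep the current module when it attains the max,
# otherwise the lowest module index (deterministic).
brimSweep <- function(B, G, H) {
  TT <- B %*% H                     # p x c row contributions
  G <- reassign(TT, G)
  S <- crossprod(B, G)              # q x c column contributions
  H <- reassign(S, H)
  list(G = G, H = H)
}

reassign <- function(score, current) {
  c_ <- ncol(score)
  best <- max.col(score, ties.method = "first")
  cur <- max.col(current, ties.method = "first")
  keep <- score[cbind(seq_len(nrow(score)), cur)] >=
    score[cbind(seq_len(nrow(score)), best)] - 1e-12
  best[keep] <- cur[keep]
  out <- matrix(0, nrow(score), c_)
  out[cbind(seq_len(nrow(score)), best)] <- 1
  out
}

partitionQ <- function(B, m, G, H) sum((B %*% H) * G) / m

#' One BRIM improvement step
#'
#' Holding column assignments fixed, moves every row to its best module,
#' then symmetrically updates the columns.  Q never decreases.
#'
#' @param A binary incidence matrix.
#' @param rowModules,colModules current assignments.
#' @param n_modules module count c (default: the largest label present).
#' @return list with updated \code{rowModules}, \code{colModules},
#'   \code{Q}.
#' @export
brimStep <- function(A, rowModules, colModules, n_modules = NULL) {
  if (is.null(n_modules))
    n_modules <- max(rowModules, colModules)
  B <- barberB(A); m <- sum(A)
  G <- matrix(0, nrow(A), n_modules)
  G[cbind(seq_len(nrow(A)), rowModules)] <- 1
  H <- matrix(0, ncol(A), n_modules)
  H[cbind(seq_len(ncol(A)), colModules)] <- 1
  sw <- brimSweep(B, G, H)
  list(rowModules = max.col(sw$G, ties.method = "first"),
       colModules = max.col(sw$H, ties.method = "first"),
       Q = partitionQ(B, m, sw$G, sw$H))
}

# Iterate BRIM sweeps from a random c-module start to a fixed point.
brimToFixedPoint <- function(B, m, c_, max_iter = 200L) {
  p <- nrow(B); q <- ncol(B)
  G <- matrix(0, p, c_); H <- matrix(0, q, c_)
  G[cbind(seq_len(p), sample.int(c_, p, replace = TRUE))] <- 1
  H[cbind(seq_len(q), sample.int(c_, q, replace = TRUE))] <- 1
  Q <- partitionQ(B, m, G, H)
  for (i in seq_len(max_iter)) {
    sw <- brimSweep(B, G, H)
    Qnew <- partitionQ(B, m, sw$G, sw$H)
    G <- sw$G; H <- sw$H
    if (Qnew <= Q + 1e-12) { Q <- max(Q, Qnew); break }
    Q <- Qnew
  }
  list(G = G, H = H, Q = Q)
}

# One adaptive run: geometric expansion of the module count while Q
# improves, then +/-1 refinement around the best c.  Each module count is
# tried from a few random initializations (alternating reassignment has
# degenerate fixed points, e.g. all nodes in one module, that a single
# unlucky start can hit even on noiseless block matrices).
adaptiveRun <- function(B, m, cmax, inits = 3L) {
  tryC <- function(c_) {
    best <- brimToFixedPoint(B, m, c_)
    for (i in seq_len(inits - 1L)) {
      cand <- brimToFixedPoint(B, m, c_)
      if (cand$Q > best$Q) best <- cand
    }
    best
  }
  best <- tryC(min(2L, cmax)); bestc <- min(2L, cmax)
  c_ <- bestc * 2L
  while (c_ <= cmax) {
    cand <- tryC(c_)
    if (cand$Q > best$Q + 1e-9) { best <- cand; bestc <- c_; c_ <- c_ * 2L }
    else break
  }
  for (c_ in unique(pmin(pmax(c(bestc - 1L, bestc + 1L), 1L), cmax))) {
    cand <- tryC(c_)
    if (cand$Q > best$Q + 1e-9) best <- cand
  }
  best
}

#' Adaptive BRIM modularity maximization
#'
#' Runs BRIM from \code{n_runs} random initial assignments, adapting the
#' module count per run (geometric expansion while the fixed-point Q
#' improves, then local refinement).  Because the heuristic is stochastic,
#' the headline value is the \emph{mean} Q across runs; the best single-run
#' partition is returned alongside.
#'
#' @param A binary incidence matrix.
#' @param n_runs number of random restarts averaged over (default 30).
#' @param seed integer seed.
#' @param c_max largest module count tried (default
#'   \code{min(nrow, ncol)}; more modules can never raise Q because every
#'   module contributing to Q needs at least one row and one column).
#' @return list with \code{Q_runs}, \code{mean_Q}, \code{best_Q},
#'   \code{rowModules}, \code{colModules}, \code{n_runs}, \code{seed}.
#' @examples
#' ab <- adaptiveBrim(diag(4), n_runs = 5, seed = 1)
#' ab$mean_Q   # 0.75 for the 4-block identity
#' @export
adaptiveBrim <- function(A, n_runs = 30L, seed = 1L, c_max = NULL) {
  n_runs <- assertCount(n_runs)
  A <- as.matrix(A)
  B <- barberB(A); m <- sum(A)
  if (is.null(c_max)) c_max <- max(1L, min(nrow(A), ncol(A)))
  withSeed(deriveSeed(seed, "adaptive_brim"), {
    runs <- lapply(seq_len(n_runs), function(i) adaptiveRun(B, m, c_max))
    Qs <- vapply(runs, `[[`, 0, "Q")
    best <- runs[[which.max(Qs)]]
    list(Q_runs = Qs, mean_Q = mean(Qs), best_Q = max(Qs),
         rowModules = max.col(best$G, ties.method = "first"),
         colModules = max.col(best$H, ties.method = "first"),
         n_runs = n_runs, seed = seed)
  })
}

# The two null-matrix families used for significance testing.
nullMatrix <- function(A, model) {
  p <- nrow(A); q <- ncol(A); m <- sum(A)
  if (model == "bernoulli") {
    # same total number of interactions, uniformly re-positioned
    out <- matrix(0L, p, q)
    out[sample.int(p * q, m)] <- 1L
    out
  } else {
    # probabilistic degree null: cell (i,j) filled with probability
    # (k_i/q + d_j/p)/2, preserving expected margins
    prob <- (outer(rowSums(A) / q, rep(1, q)) +
             outer(rep(1, p), colSums(A) / p)) / 2
    matrix(rbinom(p * q, 1L, pmin(1, as.vector(prob))), p, q)
  }
}

#' Null-model significance test for bipartite modularity
#'
#' Scores \code{n_null} null matrices with adaptive BRIM and reports the
#' empirical p-value \code{(1 + #\{Q_null >= Q_obs\}) / (1 + n_null)}.
#' Null families: \code{"bernoulli"} (same number of interactions,
#' uniformly re-positioned) and \code{"probabilistic_degree"} (cell
#' (i, j) filled with probability \code{(k_i/q + d_j/p)/2}, preserving
#' expected margins - the stronger test).
#'
#' @param A binary incidence matrix.
#' @param model \code{"bernoulli"} or \code{"probabilistic_degree"}.
#' @param n_null number of null matrices.
#' @param runs_per_null BRIM restarts used to score each null (fewer than
#'   the observed matrix's 30 keeps the test tractable).
#' @param n_runs restarts for the observed matrix.
#' @param seed integer seed.
#' @return list with \code{model}, \code{Q_obs} (mean Q of the observed
#'   matrix), \code{null_Q} (vector of null mean Qs), \code{p}.
#' @export
modularityNullTest <- function(A, model = c("bernoulli",
                                            "probabilistic_degree"),
                               n_null = 100L, runs_per_null = 5L,
                               n_runs = 30L, seed = 1L) {
  model <- match.arg(model)
  A <- as.matrix(A)
  Q_obs <- adaptiveBrim(A, n_runs = n_runs, seed = seed)$mean_Q
  null_Q <- withSeed(deriveSeed(seed, paste0("modularity_null_", model)), {
    vapply(seq_len(n_null), function(i) {
      Ai <- nullMatrix(A, model)
      while (sum(Ai) == 0) Ai <- nullMatrix(A, model)
      # inner seed drawn from the outer stream keeps runs reproducible
      adaptiveBrim(Ai, n_runs = runs_per_null,
                   seed = sample.int(2147483646L, 1L))$mean_Q
    }, 0)
  })
  list(model = model, Q_obs = Q_obs, null_Q = null_Q,
       p = (1 + sum(null_Q >= Q_obs)) / (1 + n_null))
}

#' Incidence matrices for modularity analysis
#'
#' Helpers to build the two matrices the pipeline scores: the unsigned
#' regulator x target incidence of a regulatory network, and the binary
#' ILP x process phenotype matrix (see
#' \code{\link{buildPhenotypeMatrix}}).
#'
#' @param network a \linkS4class{RegulatoryNetwork}.
#' @return binary incidence matrix with regulators as rows (only genes
#'   with at least one interaction on the respective side are kept).
#' @export
incidenceMatrix <- function(network) {
  e <- networkEdges(network)
  if (nrow(e) == 0L) stop("network has no edges", call. = FALSE)
  regs <- sort(unique(e$regulator)); tgts <- sort(unique(e$target))
  m <- matrix(0L, length(regs), length(tgts),
              dimnames = list(regs, tgts))
  m[cbind(match(e$regulator, regs), match(e$target, tgts))] <- 1L
  m
}
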