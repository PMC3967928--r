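# qPCR normalization, differential testing and q-value machinery: the steps
# that turn copy-number tables into the DiffExprTable feeding edge calling.

copiesAssay <- function(x) SummarizedExperiment::assay(x, "copies")

#' geNorm reference-gene stability
#'
#' For each candidate reference gene j, the stability value M_j is the mean,
#' over the other candidates k, of the standard deviation across samples of
#' log2(x_j / x_k).  A perfectly stable pair has constant ratio in every
#' sample and M = 0.  Candidates are eliminated one at a time (highest M
#' first, recomputing M among the remainder) until two genes remain.
#'
#' @param x a \linkS4class{QPCRExperiment} (raw copies).
#' @param candidates character vector of candidate reference genes (>= 2),
#'   all above the detection floor in every sample.
#' @return list with \code{M} (initial stability values),
#'   \code{elimination} (genes in elimination order, least stable first),
#'   \code{selected} (the two most stable genes) and \code{trace}
#'   (data.frame of the M value of each gene at its elimination round).
#' @examples
#' qe <- simulateQPCRDataset(n_genes = 4, n_mutants = 2, n_reference = 3,
#'                           seed = 1)
#' genormStability(qe, referenceGenes(qe))$selected
#' @export
genormStability <- function(x, candidates) {
  stopifnot(is(x, "QPCRExperiment"))
  if (length(candidates) < 2L)
    stop("need >= 2 candidate reference genes", call. = FALSE)
  a <- copiesAssay(x)[candidates, , drop = FALSE]
  if (any(a < detectionFloor(x)))
    stop("candidate reference below the detection floor", call. = FALSE)
  la <- log2(a)
  mValues <- function(genes) {
    vapply(genes, function(j) {
      mean(vapply(setdiff(genes, j),
                  function(k) sd(la[j, ] - la[k, ]), 0))
    }, 0)
  }
  M0 <- mValues(candidates)
  remaining <- candidates
  elim <- character()
  trace <- data.frame(gene = character(), M = numeric(), round = integer())
  round <- 0L
  while (length(remaining) > 2L) {
    round <- round + 1L
    M <- mValues(remaining)
    worst <- names(which.max(M))
    trace <- rbind(trace, data.frame(gene = worst, M = unname(M[worst]),
                                     round = round))
    elim <- c(elim, worst)
    remaining <- setdiff(remaining, worst)
  }
  list(M = M0, elimination = elim, selected = remaining, trace = trace)
}

#' Normalize copy numbers by the geometric mean of two reference genes
#'
#' Adds a \code{"normalized"} assay: each gene's copies in a sample divided
#' by the geometric mean of the reference genes' copies in that sample.
#' Normalized values are scale-free: multiplying every gene of a sample by
#' a constant leaves them unchanged.
#'
#' @param x a \linkS4class{QPCRExperiment}.
#' @param references the reference genes (default: the two stored in the
#'   object).
#' @return \code{x} with the \code{"normalized"} assay added and
#'   \code{referenceGenes} set to \code{references}.
#' @export
normalizeExpression <- function(x, references = referenceGenes(x)) {
  stopifnot(is(x, "QPCRExperiment"), length(references) >= 2L,
            all(references %in% rownames(x)))
  a <- copiesAssay(x)
  divisor <- exp(colMeans(log(a[references, , drop = FALSE])))
  norm <- sweep(a, 2L, divisor, "/")
  SummarizedExperiment::assay(x, "normalized", withDimnames = FALSE) <- norm
  x@referenceGenes <- references
  validObject(x)
  x
}

normalizedAssay <- function(x) {
  if (!"normalized" %in% SummarizedExperiment::assayNames(x))
    stop("run normalizeExpression() first", call. = FALSE)
  SummarizedExperiment::assay(x, "normalized")
}

#' Differential expression of one target gene in one mutant
#'
#' Two-sided p for the genotype coefficient in a linear model of log2
#' normalized expression on genotype (wild type vs the mutant); with two
#' groups this equals the pooled-variance two-sample t test with
#' df = n1 + n2 - 2.
#'
#' @param x a normalized \linkS4class{QPCRExperiment}.
#' @param mutant mutant genotype label (as in \code{colData()$genotype}).
#' @param target target gene (row name), above the detection floor.
#' @return list with \code{t}, \code{df}, \code{p} and \code{log2fc}
#'   (mutant minus wild type, log2 scale).
#' @export
differentialTest <- function(x, mutant, target) {
  stopifnot(is(x, "QPCRExperiment"))
  gt <- SummarizedExperiment::colData(x)$genotype
  sel <- gt %in% c("wild_type", mutant)
  if (sum(gt == mutant) < 2L || sum(gt == "wild_type") < 2L)
    stop("need >= 2 replicates per genotype", call. = FALSE)
  y <- log2(normalizedAssay(x)[target, sel])
  g <- factor(gt[sel], levels = c("wild_type", mutant))
  df <- length(y) - 2L
  lfc <- mean(y[g == mutant]) - mean(y[g == "wild_type"])
  eps <- sqrt(.Machine$double.eps)
  if (max(var(y[g == mutant]), var(y[g == "wild_type"])) < eps^2) {
    # degenerate: zero residual variance in both groups
    if (abs(lfc) < eps) {
      t <- 0; p <- 1
    } else {
      warning("zero within-group variance with unequal means; p -> 0")
      t <- sign(lfc) * Inf; p <- 0
    }
  } else {
    fit <- lm(y ~ g)
    sm <- summary(fit)$coefficients
    t <- sm[2, 3]; p <- sm[2, 4]
  }
  list(t = unname(t), df = df, p = unname(p), log2fc = unname(lfc))
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 from the p-value histogram over the
#' lambda grid 0.05, 0.10, ..., 0.90 with a cubic smoothing spline
#' (\code{pi0_mode = "smoother"}), or fixes pi0 = 1, in which case the
#' q-values reduce exactly to Benjamini-Hochberg step-up values.  q-values
#' are monotone in p and capped at 1.
#'
#' @param p vector of p-values in [0, 1].
#' @param pi0_mode \code{"smoother"} or \code{"fixed_1"}.
#' @return list with \code{q} (same order as \code{p}) and \code{pi0}.
#' @examples
#' storeyQvalues(c(0.01, 0.02, 0.03, 0.04), pi0_mode = "fixed_1")$q
#' @export
storeyQvalues <- function(p, pi0_mode = c("smoother", "fixed_1")) {
  pi0_mode <- match.arg(pi0_mode)
  if (length(p) == 0L) stop("empty p-value vector", call. = FALSE)
  assertProbability(p, "p")
  m <- length(p)
  pi0 <- if (pi0_mode == "fixed_1" || m < 2L) 1 else {
    lambda <- seq(0.05, 0.90, by = 0.05)
    pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
    fit <- smooth.spline(lambda, pi0l, df = 3)
    min(1, max(predict(fit, x = max(lambda))$y, .Machine$double.eps))
  }
  o <- order(p)
  ro <- order(o)
  q <- pi0 * m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))            # q(p_(i)) = min over t >= i
  q <- pmin(q, 1)[ro]
  list(q = q, pi0 = pi0)
}

# Vectorized pooled-t differential table over the full mutant x target
# matrix.  Equivalent to differentialTest() cell by cell (asserted in the
# test suite) but runs in milliseconds at screen scale.
#' Differential-expression table across all mutants and targets
#'
#' Computes, for every (mutant, target gene) cell, the pooled-variance
#' t-statistic, p-value and log2 fold change of normalized expression in
#' the mutant versus wild type, assigns cell status, and corrects the
#' tested cells for multiple testing with Storey q-values as one family.
#' Statuses: \code{"tested"}; \code{"self_deletion"} (the mutant's own
#' transcript, excluded because the change is not regulatory);
#' \code{"low_expression"} (target below the detection floor in wild
#' type).  Reference genes are not treated as targets.
#'
#' @param x a normalized \linkS4class{QPCRExperiment}.
#' @param mutants genotype labels to profile (default: all non-wild-type
#'   genotypes).
#' @param mutant_genes named character vector mapping genotype label to
#'   the deleted/affected gene (default: labels are gene names).
#' @param pi0_mode passed to \code{\link{storeyQvalues}}.
#' @param pooling \code{"global"} (default) fits one linear model per
#'   transcript across all genotypes, so the residual variance is pooled
#'   over the whole design (df = N - G) - the efficient choice when every
#'   genotype shares the assay noise; \code{"pairwise"} uses the
#'   two-group pooled t of \code{\link{differentialTest}}
#'   (df = n1 + n2 - 2) cell by cell.
#' @return data.frame (one row per cell): \code{mutant}, \code{gene}
#'   (regulator gene), \code{target}, \code{t}, \code{p}, \code{q},
#'   \code{log2fc}, \code{status}.  q is NA for untested cells.
#' @export
differentialTable <- function(x, mutants = NULL, mutant_genes = NULL,
                              pi0_mode = "smoother",
                              pooling = c("global", "pairwise")) {
  stopifnot(is(x, "QPCRExperiment"))
  pooling <- match.arg(pooling)
  gt <- SummarizedExperiment::colData(x)$genotype
  if (is.null(mutants)) mutants <- setdiff(unique(gt), "wild_type")
  if (is.null(mutant_genes))
    mutant_genes <- setNames(mutants, mutants)
  targets <- setdiff(rownames(x), referenceGenes(x))
  ln <- log2(normalizedAssay(x))
  raw <- copiesAssay(x)

  wt <- gt == "wild_type"
  low <- rowMeans(raw[targets, wt, drop = FALSE]) < detectionFloor(x)
  nw <- sum(wt)
  mw <- rowMeans(ln[targets, wt, drop = FALSE])
  vw <- apply(ln[targets, wt, drop = FALSE], 1L, var)

  # global pooling: residual variance of the one-way genotype model,
  # excluding the self-deletion cell of each genotype (its variance is
  # assay noise at the detection floor, not regulatory signal)
  if (pooling == "global") {
    glevels <- c("wild_type", mutants)
    gvar <- matrix(0, length(targets), length(glevels),
                   dimnames = list(targets, glevels))
    gn <- integer(length(glevels)); names(gn) <- glevels
    for (gl in glevels) {
      sel <- gt == gl
      gn[gl] <- sum(sel)
      gvar[, gl] <- apply(ln[targets, sel, drop = FALSE], 1L, var)
    }
    for (mu in mutants)                      # drop self cells from pooling
      if (mutant_genes[[mu]] %in% targets) gvar[mutant_genes[[mu]], mu] <- NA
    dfg <- rowSums((!is.na(gvar)) * rep(gn - 1L, each = length(targets)))
    sp2g <- rowSums(sweep(gvar, 2L, gn - 1L, "*"), na.rm = TRUE) / dfg
  }

  rows <- lapply(mutants, function(mu) {
    sel <- gt == mu
    nm <- sum(sel)
    mm <- rowMeans(ln[targets, sel, drop = FALSE])
    vm <- apply(ln[targets, sel, drop = FALSE], 1L, var)
    if (pooling == "global") {
      df <- dfg
      sp2 <- sp2g
    } else {
      df <- nw + nm - 2L
      sp2 <- ((nw - 1) * vw + (nm - 1) * vm) / df
    }
    se <- sqrt(sp2 * (1 / nw + 1 / nm))
    lfc <- mm - mw
    t <- lfc / se
    t[se == 0 & abs(lfc) < sqrt(.Machine$double.eps)] <- 0
    p <- 2 * pt(abs(t), df, lower.tail = FALSE)
    p[is.nan(p)] <- 1
    status <- rep("tested", length(targets))
    status[targets == mutant_genes[[mu]]] <- "self_deletion"
    status[low] <- "low_expression"   # unanalyzable for every mutant
    data.frame(mutant = mu, gene = unname(mutant_genes[[mu]]),
               target = targets, t = t, p = p, log2fc = lfc,
               status = status, stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  tested <- out$status == "tested"
  if (any(tested))
    out$q[tested] <- storeyQvalues(out$p[tested], pi0_mode = pi0_mode)$q
  out
}

#' Call signed regulatory edges from a differential-expression table
#'
#' An edge regulator -> target is called for every tested cell with
#' q below the threshold.  The sign states the direction of regulation by
#' the \emph{normal} gene product: in a null mutant, a target going up
#' means the gene normally represses it (sign -1), a target going down
#' means the gene normally activates it (sign +1).  For a
#' gain-of-function (overexpressing) allele the inference flips.  When a
#' gene has several alleles, only interactions significant with the same
#' inferred sign in all alleles are kept (reported q is the worst allele's
#' q).
#'
#' @param diff table from \code{\link{differentialTable}}.
#' @param allele_classes named character vector mapping mutant genotype
#'   label to \code{"null"} or \code{"gain_of_function"}; unlisted mutants
#'   are null alleles.
#' @param q_threshold q-value cutoff (0.05).
#' @param genes gene universe for the network (default: regulator genes
#'   and targets present in \code{diff}).
#' @return A \linkS4class{RegulatoryNetwork}.
#' @export
callEdges <- function(diff, allele_classes = NULL, q_threshold = 0.05,
                      genes = NULL) {
  need <- c("mutant", "gene", "target", "q", "log2fc", "status")
  stopifnot(all(need %in% names(diff)))
  cls <- setNames(rep("null", length(unique(diff$mutant))),
                  unique(diff$mutant))
  if (!is.null(allele_classes)) {
    bad <- setdiff(allele_classes, c("null", "gain_of_function"))
    if (length(bad))
      stop("unknown allele class: ", paste(bad, collapse = ", "),
           call. = FALSE)
    cls[names(allele_classes)] <- allele_classes
  }
  sig <- diff[diff$status == "tested" & !is.na(diff$q) &
                diff$q < q_threshold & diff$gene != diff$target, ,
              drop = FALSE]
  if (nrow(sig)) {
    flip <- ifelse(cls[sig$mutant] == "gain_of_function", 1, -1)
    sig$sign <- flip * sign(sig$log2fc)
  }
  # allele merging: a (gene, target) pair profiled through several mutant
  # alleles must be significant with the same sign in all of them
  nAlleles <- tapply(diff$mutant, diff$gene,
                     function(m) length(unique(m)))
  edges <- if (nrow(sig)) {
    key <- paste(sig$gene, sig$target, sep = "\r")
    pieces <- lapply(split(sig, key), function(d) {
      gene <- d$gene[1]
      if (nrow(d) < nAlleles[[gene]]) return(NULL)   # missing in an allele
      if (length(unique(d$sign)) > 1L) return(NULL)  # discordant sign
      data.frame(regulator = gene, target = d$target[1], sign = d$sign[1],
                 q = max(d$q), alleles = paste(sort(d$mutant),
                                               collapse = ","),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, pieces)
  } else NULL
  if (is.null(genes))
    genes <- sort(unique(c(diff$gene, diff$target)))
  if (is.null(edges))
    edges <- data.frame(regulator = character(), target = character(),
                        sign = numeric(), q = numeric(),
                        alleles = character())
  rownames(edges) <- NULL
  RegulatoryNetwork(edges, genes = genes)
}

#' Census of a differential-expression table
#'
#' Counts candidate interaction cells both ways the denominator can be
#' defined: \code{cells_possible} counts every mutant x analyzable-transcript
#' cell (low/undetectable transcripts removed, self-deletion cells still
#' counted), \code{cells_tested} additionally removes the self-deletion
#' cells actually excluded from testing.
#'
#' @param diff table from \code{\link{differentialTable}}.
#' @return list with \code{cells_all}, \code{cells_possible},
#'   \code{cells_tested}, \code{cells_self_deletion},
#'   \code{cells_low_expression}.
#' @export
expressionCensus <- function(diff) {
  list(cells_all = nrow(diff),
       cells_possible = sum(diff$status != "low_expression"),
       cells_tested = sum(diff$status == "tested"),
       cells_self_deletion = sum(diff$status == "self_deletion"),
       cells_low_expression = sum(diff$status == "low_expression"))
}
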