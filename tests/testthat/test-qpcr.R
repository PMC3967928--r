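makeQE <- function(copies, genotype, replicate = NULL, refs = character(),
                   floor = 10) {
  if (is.null(replicate))
    replicate <- stats::ave(seq_along(genotype), genotype, FUN = seq_along)
  QPCRExperiment(copies, genotype, replicate, referenceGenes = refs,
                 detectionFloor = floor)
}

test_that("QPCRExperiment validity catches malformed objects", {
  m <- matrix(c(100, 50), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_s4_class(makeQE(m, "wild_type"), "QPCRExperiment")
  expect_error(makeQE(-m, "wild_type"), "non-negative")
  expect_error(makeQE(m, "wild_type", refs = "missing_gene"), "reference")
})

test_that("geNorm stability is zero for constant-ratio pairs and penalizes noise", {
  # two candidates with x2 = 2 * x1 in every sample: both M = 0
  cp <- rbind(r1 = c(100, 200, 150), r2 = c(200, 400, 300),
              g = c(50, 60, 70))
  qe <- makeQE(cp, rep("wild_type", 3))
  st <- genormStability(qe, c("r1", "r2"))
  expect_equal(unname(st$M), c(0, 0))
  # perturbing one sample of r2 strictly increases its M; hand SD oracle
  cp2 <- cp; cp2["r2", 2] <- 500
  st2 <- genormStability(makeQE(cp2, rep("wild_type", 3)), c("r1", "r2"))
  expect_equal(unname(st2$M["r2"]), sd(log2(cp2["r2", ] / cp2["r1", ])))
  expect_gt(st2$M[["r2"]], 0)
  # three candidates, one scrambled: the scrambled one goes first
  set.seed(1)
  cp3 <- rbind(r1 = 100 * 2^rnorm(6, 0, 0.01),
               r2 = 200 * 2^rnorm(6, 0, 0.01),
               bad = 150 * 2^rnorm(6, 0, 1))
  st3 <- genormStability(makeQE(cp3, rep("wild_type", 6)),
                         c("r1", "r2", "bad"))
  expect_equal(st3$elimination, "bad")
  expect_equal(sort(st3$selected), c("r1", "r2"))
  expect_error(genormStability(makeQE(cp, rep("wild_type", 3), floor = 80),
                               c("r1", "g")), "floor")
})

test_that("normalization divides by the geometric mean of the references", {
  cp <- rbind(g = c(12, 24), r1 = c(4, 8), r2 = c(9, 18))
  qe <- makeQE(cp, c("wild_type", "wild_type"), refs = c("r1", "r2"),
               floor = 1)
  nn <- SummarizedExperiment::assay(normalizeExpression(qe), "normalized")
  expect_equal(nn["g", 1], 12 / 6)         # geomean(4, 9) = 6
  expect_equal(nn["g", 2], 24 / 12)
  # doubling every gene in a sample leaves normalized values unchanged
  cp2 <- cp; cp2[, 2] <- cp[, 1] * 2
  n2 <- SummarizedExperiment::assay(normalizeExpression(
    makeQE(cp2, c("wild_type", "wild_type"), refs = c("r1", "r2"),
           floor = 1)), "normalized")
  expect_equal(n2[, 2], n2[, 1])
})

test_that("differential test equals the hand pooled-variance t", {
  cp <- rbind(t = 2^c(1, 1, 1, 1, 2, 2, 2, 2.1),
              r1 = rep(100, 8), r2 = rep(50, 8))
  qe <- normalizeExpression(makeQE(cp, rep(c("wild_type", "mut"), each = 4),
                                   refs = c("r1", "r2")))
  res <- differentialTest(qe, "mut", "t")
  # hand pooled t on the log2 values (references constant, so unaffected)
  y1 <- c(1, 1, 1, 1) - log2(sqrt(100 * 50))
  y2 <- c(2, 2, 2, 2.1) - log2(sqrt(100 * 50))
  sp <- sqrt((3 * var(y1) + 3 * var(y2)) / 6)
  tref <- (mean(y2) - mean(y1)) / (sp * sqrt(1 / 4 + 1 / 4))
  expect_equal(res$t, tref, tolerance = 1e-10)
  expect_equal(res$df, 6)
  expect_equal(res$p, 2 * pt(abs(tref), 6, lower.tail = FALSE))
  # identical replicate sets: t = 0, p = 1
  cp0 <- rbind(t = rep(8, 6), r1 = rep(100, 6), r2 = rep(50, 6))
  qe0 <- normalizeExpression(makeQE(cp0, rep(c("wild_type", "mut"), each = 3),
                                    refs = c("r1", "r2")))
  r0 <- differentialTest(qe0, "mut", "t")
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # zero variance with unequal means: limiting p = 0 with a warning
  cpz <- rbind(t = rep(c(8, 16), each = 3), r1 = rep(100, 6), r2 = rep(50, 6))
  qez <- normalizeExpression(makeQE(cpz, rep(c("wild_type", "mut"), each = 3),
                                    refs = c("r1", "r2")))
  expect_warning(rz <- differentialTest(qez, "mut", "t"), "zero")
  expect_equal(rz$p, 0)
})

test_that("differentialTable matches cell-wise differentialTest and flags statuses", {
  qe <- normalizeExpression(simulateQPCRDataset(
    n_genes = 6, n_mutants = 3, n_replicates = 3, noise_cv = 0.15,
    low_genes = "g6", seed = 21))
  d <- differentialTable(qe, pooling = "pairwise")
  for (i in sample(which(d$status == "tested"), 5)) {
    single <- differentialTest(qe, d$mutant[i], d$target[i])
    expect_equal(d$t[i], single$t, tolerance = 1e-9)
    expect_equal(d$p[i], single$p, tolerance = 1e-9)
    expect_equal(d$log2fc[i], single$log2fc, tolerance = 1e-9)
  }
  # globally pooled variant keeps the same fold changes and flags, with
  # wider residual degrees of freedom
  dg <- differentialTable(qe)
  expect_equal(dg$log2fc, d$log2fc, tolerance = 1e-12)
  expect_identical(dg$status, d$status)
  expect_equal(sum(d$status == "self_deletion"), 3)
  expect_equal(sum(d$status == "low_expression"), 3)
  expect_true(all(is.na(d$q[d$status != "tested"])))
  # q monotone non-decreasing in p within the tested family
  td <- d[d$status == "tested", ]
  expect_true(all(diff(td$q[order(td$p)]) >= -1e-12))
})

test_that("Storey q-values with pi0 = 1 reduce exactly to Benjamini-Hochberg", {
  expect_equal(storeyQvalues(c(0.01, 0.02, 0.03, 0.04), "fixed_1")$q,
               rep(0.04, 4))
  set.seed(31)
  for (i in 1:10) {
    p <- runif(200)^sample(1:3, 1)
    expect_equal(storeyQvalues(p, "fixed_1")$q, p.adjust(p, "BH"),
                 tolerance = 1e-12)
  }
  expect_equal(storeyQvalues(rep(1, 5))$q, rep(1, 5))
  # uniform p: the smoother estimates pi0 near 1
  set.seed(7)
  pi0 <- storeyQvalues(runif(1000))$pi0
  expect_gt(pi0, 0.9)
  expect_error(storeyQvalues(numeric()), "empty")
  expect_error(storeyQvalues(c(0.5, 1.2)), "probability")
})

test_that("edge calling applies the sign convention, threshold and allele rules", {
  diff <- data.frame(
    mutant = c("m1", "m1", "m2"),
    gene = c("g1", "g1", "g2"),
    target = c("g2", "g3", "g3"),
    t = c(-3, 4, 2), p = c(0.001, 0.001, 0.04),
    log2fc = c(-1, 1, 0.5),
    status = "tested",
    q = c(0.049, 0.02, 0.051))
  net <- callEdges(diff)
  e <- networkEdges(net)
  # q = 0.049, target down in the null mutant: activating edge (+1)
  expect_equal(e$sign[e$regulator == "g1" & e$target == "g2"], 1)
  # target up in the null mutant: the gene normally represses it (-1)
  expect_equal(e$sign[e$regulator == "g1" & e$target == "g3"], -1)
  # q = 0.051: no edge
  expect_false(any(e$regulator == "g2"))
  # gain-of-function allele flips the inference
  gof <- callEdges(diff, allele_classes = c(m1 = "gain_of_function"))
  eg <- networkEdges(gof)
  expect_equal(eg$sign[eg$regulator == "g1" & eg$target == "g2"], -1)
  expect_error(callEdges(diff, allele_classes = c(m1 = "odd")), "allele class")
  # two alleles of one gene: interaction must be shared with the same sign
  di2 <- data.frame(
    mutant = c("a1", "a2", "a1", "a2", "a1", "a2"),
    gene = "g1",
    target = c("g2", "g2", "g3", "g3", "g4", "g4"),
    t = 0, p = 0.01,
    log2fc = c(-1, -1, -1, 1, -1, -0.5),
    status = "tested",
    q = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.2))
  e2 <- networkEdges(callEdges(di2))
  expect_equal(e2$target, "g2")             # g3 discordant, g4 not shared
  expect_equal(e2$alleles, "a1,a2")
  expect_equal(e2$q, 0.01)
})

test_that("edge calling is invariant to uniform rescaling of a sample", {
  qe <- simulateQPCRDataset(
    n_genes = 8, n_mutants = 4, n_replicates = 4, noise_cv = 0.1,
    planted_edges = data.frame(regulator = c("g1", "g2"),
                               target = c("g5", "g6"), sign = c(1, -1)),
    seed = 13)
  a <- SummarizedExperiment::assay(qe, "copies")
  a2 <- a; a2[, 3] <- a2[, 3] * 7.5         # pipetting-scale distortion
  cd <- SummarizedExperiment::colData(qe)
  qe2 <- QPCRExperiment(a2, cd$genotype, cd$replicate,
                        referenceGenes = referenceGenes(qe))
  d1 <- differentialTable(normalizeExpression(qe))
  d2 <- differentialTable(normalizeExpression(qe2))
  expect_equal(d1$p, d2$p, tolerance = 1e-9)
  e1 <- networkEdges(callEdges(d1)); e2 <- networkEdges(callEdges(d2))
  expect_identical(e1[c("regulator", "target", "sign")],
                   e2[c("regulator", "target", "sign")])
  expect_equal(e1$q, e2$q, tolerance = 1e-9)
})

test_that("RegulatoryNetwork validity enforces the edge contract", {
  expect_error(RegulatoryNetwork(data.frame(regulator = "a", target = "a",
                                            sign = 1, q = 0.01)), "self")
  expect_error(RegulatoryNetwork(data.frame(regulator = c("a", "a"),
                                            target = c("b", "b"),
                                            sign = 1, q = 0.01)), "one edge")
  expect_error(RegulatoryNetwork(data.frame(regulator = "a", target = "b",
                                            sign = 2, q = 0.01)), "sign")
  net <- RegulatoryNetwork(data.frame(regulator = "a", target = "b",
                                      sign = -1, q = 0.01),
                           genes = c("a", "b", "c"))
  expect_equal(edgeCount(net), 1)
  expect_equal(unname(signSplit(net)), c(1, 0))
  g <- asIgraph(net)
  expect_equal(igraph::vcount(g), 3)
})
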