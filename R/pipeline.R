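# Orchestration and file I/O: every stage writes plain-text artifacts
# (TSV/JSON/GraphML) and later stages read only those artifacts, so the
# pipeline can be restarted at any stage.

writeTSV <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTSV <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' Export a regulatory network
#'
#' Writes a plain edge-list TSV (regulator, target, sign, q) and, if
#' \code{graphml} is given, a GraphML file for visualization tools.
#'
#' @param network a \linkS4class{RegulatoryNetwork}.
#' @param edge_tsv path for the edge list.
#' @param graphml optional path for GraphML export.
#' @return invisibly, the paths written.
#' @export
exportNetwork <- function(network, edge_tsv, graphml = NULL) {
  writeTSV(networkEdges(network), edge_tsv)
  if (!is.null(graphml))
    igraph::write_graph(asIgraph(network), graphml, format = "graphml")
  invisible(c(edge_tsv, graphml))
}

#' Default pipeline configuration
#'
#' Study-design defaults: a 40-gene ILP panel profiled in 35 null mutants
#' with 2 stable reference genes, 4 qPCR replicates, CV 10% noise and 6
#' low-expression transcripts; dauer screens at 50 eggs x 3 trials; 12
#' planted regulatory edges of |log2fc| = 1; modularity averaged over 30
#' BRIM runs.
#'
#' @param seed master seed; every stage derives its own substream.
#' @param outdir output directory.
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function(seed = 1L, outdir = tempfile("ilpnet_")) {
  list(
    seed = seed,
    outdir = outdir,
    screen = list(n_mutants = 6L, n_trials = 3L, n_per_group = 50L,
                  hazard_ratio = 0.7, p_control = 0.05, p_mutant = 0.35,
                  n_eggs = 50L),
    qpcr = list(n_genes = 40L, n_mutants = 35L, n_replicates = 4L,
                noise_cv = 0.10, n_reference = 2L, n_low_expression = 6L,
                n_planted_edges = 12L, log2fc = 1, frac_negative = 0.5),
    network = list(q_threshold = 0.05, pi0_mode = "smoother"),
    modularity = list(n_runs = 30L),
    interactions = list(classes = c("additive", "synergistic",
                                    "non_additive", "suppression",
                                    "no_effect", "no_interaction"),
                        n_eggs = 50L, n_trials = 3L)
  )
}

# Random planted edge set among the analyzable (non-reference, non-low)
# targets.
plantEdges <- function(n_genes, n_mutants, n_edges, frac_negative, log2fc,
                       seed, exclude_targets = character()) {
  genes <- paste0("g", seq_len(n_genes))
  mutants <- genes[seq_len(n_mutants)]
  withSeed(deriveSeed(seed, "plant_edges"), {
    cells <- expand.grid(regulator = mutants,
                         target = setdiff(genes, exclude_targets),
                         stringsAsFactors = FALSE)
    cells <- cells[cells$regulator != cells$target, ]
    pick <- cells[sample.int(nrow(cells), n_edges), ]
    nneg <- round(frac_negative * n_edges)
    pick$sign <- rep(1, n_edges)
    pick$sign[seq_len(nneg)] <- -1
    pick$log2fc <- log2fc
    rownames(pick) <- NULL
    pick
  })
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> screen -> qpcr -> network -> graph -> modularity ->
#' interactions on synthetic data with known ground truth, writing all
#' tables, graph exports and a JSON summary into \code{config$outdir}.
#'
#' @param config configuration list from
#'   \code{\link{defaultPipelineConfig}}, or a path to a YAML file with
#'   the same structure.
#' @return the summary list (also written as \code{summary.json}).
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- defaultPipelineConfig(seed = config$seed %||% 1L)
  config <- utils::modifyList(base, config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outdir, ...)
  seed <- config$seed

  ## screen stage: survival + dauer trials for a small mutant panel
  sc <- config$screen
  screen_calls <- lapply(seq_len(sc$n_mutants), function(i) {
    surv <- simulateSurvivalTrials(sc$hazard_ratio,
                                   n_per_group = sc$n_per_group,
                                   n_trials = sc$n_trials,
                                   seed = deriveSeed(seed, paste0("surv", i)))
    res <- lapply(split(surv, surv$trial), logrankRightCensored)
    cp <- combineTrials(res)
    classifyConfidence(res, cp, lab_ids = rep("lab1", length(res)))
  })
  screen_tab <- data.frame(
    mutant = paste0("m", seq_len(sc$n_mutants)),
    level = vapply(screen_calls, `[[`, "", "level"),
    direction = vapply(screen_calls, function(x) x$direction, 0L),
    combined_p = vapply(screen_calls, `[[`, 0, "combined_p"))
  writeTSV(screen_tab, out("screen_calls.tsv"))

  ## qpcr stage
  qc <- config$qpcr
  genes <- paste0("g", seq_len(qc$n_genes))
  low <- if (qc$n_low_expression > 0)
    utils::tail(genes, qc$n_low_expression) else character()
  planted <- plantEdges(qc$n_genes, qc$n_mutants, qc$n_planted_edges,
                        qc$frac_negative, qc$log2fc, seed,
                        exclude_targets = low)
  qe <- simulateQPCRDataset(n_genes = qc$n_genes, n_mutants = qc$n_mutants,
                            planted_edges = planted,
                            n_replicates = qc$n_replicates,
                            noise_cv = qc$noise_cv,
                            n_reference = qc$n_reference,
                            low_genes = low,
                            seed = seed)
  qe <- normalizeExpression(qe)
  diff <- differentialTable(qe, pi0_mode = config$network$pi0_mode)
  writeTSV(diff, out("diffexpr.tsv"))
  writeTSV(planted, out("planted_edges.tsv"))

  ## network stage (reads the written diff table)
  diff2 <- readTSV(out("diffexpr.tsv"))
  net <- callEdges(diff2, q_threshold = config$network$q_threshold)
  exportNetwork(net, out("edges.tsv"), out("network.graphml"))
  census <- expressionCensus(diff2)

  ## graph stage
  view <- buildGraphView(net)
  gm <- list(
    L_directed = characteristicPathLength(view, "directed_reachable"),
    L_undirected = characteristicPathLength(view, "undirected"),
    C = clusteringCoefficients(view)$average,
    T = clusteringCoefficients(view)$transitivity)
  sw <- smallWorldness(view, n_null = 100L,
                       seed = deriveSeed(seed, "sw"))
  writeTSV(nodeCentralities(view), out("centralities.tsv"))

  ## modularity stage (reads the written edge list)
  edges <- readTSV(out("edges.tsv"))
  A <- incidenceMatrix(RegulatoryNetwork(edges))
  mod <- adaptiveBrim(A, n_runs = config$modularity$n_runs,
                      seed = deriveSeed(seed, "brim"))

  ## interactions stage
  ic <- config$interactions
  inter <- vapply(seq_along(ic$classes), function(i) {
    counts <- simulateDoubleMutantCounts(
      ic$classes[i], n_eggs = ic$n_eggs, n_trials = ic$n_trials,
      seed = deriveSeed(seed, paste0("dm", i)))
    classifyInteraction(counts)$class
  }, "")
  inter_tab <- data.frame(planted = ic$classes, called = inter)
  writeTSV(inter_tab, out("interactions.tsv"))

  summary <- list(
    seed = seed,
    screen = list(n_high = sum(screen_tab$level == "high")),
    network = c(census, list(
      edges = edgeCount(net),
      sign_split = as.list(signSplit(net)))),
    graph = c(gm, list(small_worldness = sw$S)),
    modularity = list(mean_Q = mod$mean_Q, n_runs = mod$n_runs),
    interactions = list(
      planted = as.list(setNames(inter_tab$called, inter_tab$planted)),
      accuracy = mean(inter_tab$called == inter_tab$planted))
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
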