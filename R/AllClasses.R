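#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' QPCRExperiment: copy-number qPCR data for a panel of genes
#'
#' A \linkS4class{SummarizedExperiment} holding one assay, \code{"copies"}
#' (copies per reaction, gene x sample), with per-sample \code{genotype}
#' (\code{"wild_type"} or a mutant identifier) and \code{replicate} columns.
#' Metadata carries the designated reference genes, the assay detection floor
#' (copies/reaction below which a transcript is considered not robustly
#' detected), and - for synthetic data - the planted ground truth.
#'
#' @slot referenceGenes character vector of stable reference gene names.
#' @slot detectionFloor numeric scalar, copies/reaction.
#'
#' @export
setClass("QPCRExperiment",
  contains = "SummarizedExperiment",
  slots = c(referenceGenes = "character", detectionFloor = "numeric")
)

setValidity("QPCRExperiment", function(object) {
  msg <- character()
  if (!"copies" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'copies' is required")
  else if (any(SummarizedExperiment::assay(object, "copies") < 0))
    msg <- c(msg, "copy numbers must be non-negative")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("genotype", "replicate") %in% colnames(cd)))
    msg <- c(msg, "colData must have 'genotype' and 'replicate' columns")
  if (length(object@detectionFloor) != 1L || object@detectionFloor < 0)
    msg <- c(msg, "detectionFloor must be a single non-negative number")
  if (!all(object@referenceGenes %in% rownames(object)))
    msg <- c(msg, "all reference genes must be rows of the assay")
  if (length(msg)) msg else TRUE
})

#' Construct a QPCRExperiment
#'
#' @param copies numeric matrix of copies per reaction, genes in rows and
#'   samples in columns.
#' @param genotype character vector, one entry per sample; wild-type samples
#'   must be labelled \code{"wild_type"}.
#' @param replicate integer vector of replicate indices within genotype.
#' @param referenceGenes character vector naming the candidate/selected
#'   reference genes (rows of \code{copies}).
#' @param detectionFloor copies/reaction below which a transcript is treated
#'   as not robustly detected (default 10, the sensitivity of a good
#'   SYBR-green assay).
#' @param metadata optional list of extra metadata (e.g. planted ground
#'   truth).
#' @return A \linkS4class{QPCRExperiment}.
#' @examples
#' m <- matrix(c(100, 50, 110, 55), 2, dimnames = list(c("g1", "ref"), NULL))
#' qe <- QPCRExperiment(m, genotype = c("wild_type", "wild_type"),
#'                      replicate = 1:2, referenceGenes = "ref")
#' detectionFloor(qe)
#' @export
QPCRExperiment <- function(copies, genotype, replicate,
                           referenceGenes = character(),
                           detectionFloor = 10,
                           metadata = list()) {
  stopifnot(is.matrix(copies), ncol(copies) == length(genotype),
            length(replicate) == length(genotype))
  if (is.null(colnames(copies)))
    colnames(copies) <- paste(genotype, replicate, sep = ".")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(copies = copies),
    colData = S4Vectors::DataFrame(genotype = as.character(genotype),
                                   replicate = as.integer(replicate),
                                   row.names = colnames(copies)),
    metadata = metadata
  )
  new("QPCRExperiment", se, referenceGenes = as.character(referenceGenes),
      detectionFloor = as.numeric(detectionFloor))
}

#' @describeIn QPCRExperiment accessor for the reference genes.
#' @param x a QPCRExperiment.
#' @export
referenceGenes <- function(x) {
  stopifnot(is(x, "QPCRExperiment"))
  x@referenceGenes
}

#' @describeIn QPCRExperiment accessor for the detection floor.
#' @export
detectionFloor <- function(x) {
  stopifnot(is(x, "QPCRExperiment"))
  x@detectionFloor
}

setMethod("show", "QPCRExperiment", function(object) {
  callNextMethod()
  cat("reference genes:", paste(object@referenceGenes, collapse = ", "),
      "\ndetection floor:", object@detectionFloor, "copies/reaction\n")
})

#' RegulatoryNetwork: a directed signed gene-to-gene network
#'
#' Edges state that the normal activity of \code{regulator} raises
#' (\code{sign = +1}) or lowers (\code{sign = -1}) the transcript of
#' \code{target}, as inferred from expression changes in the regulator's
#' mutant.
#'
#' @slot edges data.frame with columns \code{regulator}, \code{target},
#'   \code{sign}, \code{q}, and \code{alleles}.
#' @slot genes character vector: the full gene universe the network was
#'   inferred over (including unconnected genes).
#' @export
setClass("RegulatoryNetwork",
  slots = c(edges = "data.frame", genes = "character")
)

setValidity("RegulatoryNetwork", function(object) {
  e <- object@edges
  msg <- character()
  need <- c("regulator", "target", "sign", "q")
  if (!all(need %in% colnames(e)))
    msg <- c(msg, paste("edges need columns:", paste(need, collapse = ", ")))
  else {
    if (any(e$regulator == e$target)) msg <- c(msg, "self-edges not allowed")
    if (!all(e$sign %in% c(-1, 1))) msg <- c(msg, "sign must be +1 or -1")
    if (anyDuplicated(e[c("regulator", "target")]))
      msg <- c(msg, "at most one edge per (regulator, target)")
    if (!all(c(e$regulator, e$target) %in% object@genes))
      msg <- c(msg, "edge endpoints must belong to the gene universe")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RegulatoryNetwork
#'
#' @param edges data.frame with columns \code{regulator}, \code{target},
#'   \code{sign} (+1/-1), \code{q}; an \code{alleles} column is added if
#'   missing.
#' @param genes gene universe (defaults to the genes appearing in edges).
#' @return A \linkS4class{RegulatoryNetwork}.
#' @export
RegulatoryNetwork <- function(edges, genes = NULL) {
  edges <- as.data.frame(edges)
  if (nrow(edges) == 0L) {
    edges <- data.frame(regulator = character(), target = character(),
                        sign = numeric(), q = numeric(),
                        alleles = character())
  }
  if (is.null(edges$alleles)) edges$alleles <- NA_character_
  if (is.null(genes)) genes <- sort(unique(c(edges$regulator, edges$target)))
  new("RegulatoryNetwork", edges = edges, genes = as.character(genes))
}

#' @describeIn RegulatoryNetwork the edge table.
#' @param x a RegulatoryNetwork.
#' @export
networkEdges <- function(x) {
  stopifnot(is(x, "RegulatoryNetwork"))
  x@edges
}

#' @describeIn RegulatoryNetwork the gene universe.
#' @export
networkGenes <- function(x) {
  stopifnot(is(x, "RegulatoryNetwork"))
  x@genes
}

#' @describeIn RegulatoryNetwork number of edges.
#' @export
edgeCount <- function(x) nrow(networkEdges(x))

#' @describeIn RegulatoryNetwork fraction of negative and positive edges.
#' @export
signSplit <- function(x) {
  e <- networkEdges(x)
  if (nrow(e) == 0L) return(c(negative = NA_real_, positive = NA_real_))
  c(negative = mean(e$sign < 0), positive = mean(e$sign > 0))
}

setMethod("show", "RegulatoryNetwork", function(object) {
  e <- object@edges
  cat(sprintf("RegulatoryNetwork: %d genes, %d signed directed edges\n",
              length(object@genes), nrow(e)))
  if (nrow(e)) {
    sp <- signSplit(object)
    cat(sprintf("  %.0f%% inhibiting / %.0f%% activating\n",
                100 * sp["negative"], 100 * sp["positive"]))
  }
})

#' Convert a RegulatoryNetwork to an igraph graph
#'
#' Vertices are the full gene universe; the edge attribute \code{sign}
#' carries the regulation sign.
#' @param network a \linkS4class{RegulatoryNetwork}.
#' @return An \code{igraph} directed graph.
#' @export
asIgraph <- function(network) {
  e <- networkEdges(network)
  igraph::graph_from_data_frame(
    e[c("regulator", "target", "sign", "q")],
    directed = TRUE,
    vertices = data.frame(name = networkGenes(network))
  )
}
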