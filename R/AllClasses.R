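#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges GRangesList reduce start end width seqnames strand
#' @importFrom IRanges IRanges
NULL

#' TranscriptCatalog: merged exon models for a set of genes
#'
#' One entry per gene: the union of its exons (per-gene `reduce()`d
#' \linkS4class{GRanges}), plus per-gene metadata columns (`gene_id`, `chrom`,
#' `strand`, `exonic_length`, and, after classification, `class` and
#' `best_overlap`). The catalog is the unit on which annotation-overlap
#' classification and the lncRNA length rule operate.
#'
#' @slot exons a named \code{GRangesList}, one element per gene, exons merged
#'   and sorted.
#' @slot geneData a \code{DataFrame} parallel to \code{exons}.
#' @exportClass TranscriptCatalog
setClass("TranscriptCatalog",
  representation(exons = "GRangesList", geneData = "DataFrame"))

setValidity("TranscriptCatalog", function(object) {
  msg <- character()
  if (length(object@exons) != nrow(object@geneData))
    msg <- c(msg, "exons and geneData must be parallel")
  if (length(object@exons)) {
    if (is.null(names(object@exons)) || anyDuplicated(names(object@exons)))
      msg <- c(msg, "gene ids must be unique and non-empty")
    if (any(object@geneData$exonic_length <= 0))
      msg <- c(msg, "every gene must have positive exonic length")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn TranscriptCatalog number of genes
#' @param x,object a TranscriptCatalog
#' @export
setMethod("length", "TranscriptCatalog", function(x) length(x@exons))

#' Gene identifiers of a catalog
#' @param x a TranscriptCatalog or RegulatoryNetwork
#' @return character vector of gene ids
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname geneIds
#' @export
setMethod("geneIds", "TranscriptCatalog", function(x) names(x@exons))

#' Merged exons per gene
#' @param x a TranscriptCatalog
#' @return a GRangesList named by gene id
#' @export
exonsByGene <- function(x) x@exons

#' Per-gene metadata of a catalog
#'
#' Columns: gene_id, chrom, strand, exonic_length, and when classified,
#' class and best_overlap.
#' @param x a TranscriptCatalog
#' @return a DataFrame with one row per gene
#' @export
geneData <- function(x) x@geneData

#' Merged exonic length per gene (bp)
#' @param x a TranscriptCatalog
#' @return named integer vector
#' @export
exonicLength <- function(x) {
  stats::setNames(x@geneData$exonic_length, x@geneData$gene_id)
}

#' Gene classes of a classified catalog
#' @param x a TranscriptCatalog produced by [classifyCatalog()]
#' @return named character vector with values among
#'   PSEUDOGENE, NCRNA, LINCRNA, CODING, UNANNOTATED
#' @export
geneClasses <- function(x) {
  if (is.null(x@geneData$class)) stop("catalog has not been classified")
  stats::setNames(x@geneData$class, x@geneData$gene_id)
}

setMethod("show", "TranscriptCatalog", function(object) {
  cat("TranscriptCatalog with", length(object), "genes\n")
  if (!is.null(object@geneData$class)) {
    tab <- table(object@geneData$class)
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

#' DiscreteDAG: a directed acyclic graph over discrete variables
#'
#' The structure component of a discrete Bayesian network: an ordered set of
#' variables and, for each, its parent set. Validity enforces acyclicity
#' (a topological order must exist) and the absence of self-edges.
#'
#' @slot nodes ordered character vector of variable ids.
#' @slot parents named list (one entry per node) of character vectors.
#' @exportClass DiscreteDAG
setClass("DiscreteDAG", representation(nodes = "character", parents = "list"))

setValidity("DiscreteDAG", function(object) {
  msg <- character()
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate node ids")
  if (!identical(sort(names(object@parents)), sort(object@nodes)))
    msg <- c(msg, "parents must be named by exactly the node set")
  for (v in object@nodes) {
    pa <- object@parents[[v]]
    if (v %in% pa) msg <- c(msg, paste0("self-edge at ", v))
    if (!all(pa %in% object@nodes)) msg <- c(msg, paste0("unknown parent of ", v))
    if (anyDuplicated(pa)) msg <- c(msg, paste0("duplicate parents of ", v))
  }
  if (!length(msg) && is.null(topologicalOrder(object)))
    msg <- c(msg, "graph contains a cycle")
  if (length(msg)) msg else TRUE
})

#' Construct a DiscreteDAG
#' @param nodes character vector of variable ids
#' @param parents named list of parent sets; missing nodes get empty sets
#' @return a \linkS4class{DiscreteDAG}
#' @export
DiscreteDAG <- function(nodes, parents = list()) {
  pa <- stats::setNames(rep(list(character()), length(nodes)), nodes)
  for (v in names(parents)) pa[[v]] <- as.character(parents[[v]])
  new("DiscreteDAG", nodes = as.character(nodes), parents = pa)
}

#' Parent sets of a DAG
#' @param dag a DiscreteDAG
#' @return named list of character vectors
#' @export
dagParents <- function(dag) dag@parents

#' Node set of a DAG
#' @param dag a DiscreteDAG
#' @export
dagNodes <- function(dag) dag@nodes

#' Edge list of a DAG
#' @param dag a DiscreteDAG
#' @return data.frame with columns `from`, `to`, one row per directed edge,
#'   ordered by child then parent
#' @export
dagEdges <- function(dag) {
  to <- rep(dag@nodes, lengths(dag@parents[dag@nodes]))
  from <- unlist(dag@parents[dag@nodes], use.names = FALSE)
  if (is.null(from)) from <- character()
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

#' Number of directed edges in a DAG
#' @param dag a DiscreteDAG
#' @export
numEdges <- function(dag) sum(lengths(dag@parents))

#' Topological order of a DAG, or NULL if cyclic
#' @param dag a DiscreteDAG
#' @return character vector of nodes, parents before children; NULL on a cycle
#' @export
topologicalOrder <- function(dag) {
  indeg <- lengths(dag@parents[dag@nodes])
  names(indeg) <- dag@nodes
  children <- stats::setNames(rep(list(character()), length(dag@nodes)), dag@nodes)
  for (v in dag@nodes) for (p in dag@parents[[v]])
    children[[p]] <- c(children[[p]], v)
  queue <- dag@nodes[indeg == 0]
  out <- character()
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) == length(dag@nodes)) out else NULL
}

setMethod("show", "DiscreteDAG", function(object) {
  cat("DiscreteDAG with", length(object@nodes), "nodes and",
      numEdges(object), "edges\n")
})

#' RegulatoryNetwork: lncRNA-incident edges of a learned DAG
#'
#' The subgraph of a learned Bayesian network restricted to directed edges
#' with at least one lncRNA endpoint. Linkage for function prediction is
#' direction-agnostic and coding-only: `linkedGenes()` returns the
#' protein-coding neighbors of a lncRNA in either direction.
#'
#' @slot edges data.frame with columns `from`, `to`.
#' @slot lncIds lncRNA variable ids (whole input set, not only connected ones).
#' @slot codingIds protein-coding variable ids.
#' @exportClass RegulatoryNetwork
setClass("RegulatoryNetwork",
  representation(edges = "data.frame", lncIds = "character",
                 codingIds = "character"))

setValidity("RegulatoryNetwork", function(object) {
  msg <- character()
  if (length(intersect(object@lncIds, object@codingIds)))
    msg <- c(msg, "lncRNA and coding id sets overlap")
  if (nrow(object@edges)) {
    touched <- object@edges$from %in% object@lncIds |
               object@edges$to %in% object@lncIds
    if (!all(touched)) msg <- c(msg, "every edge needs a lncRNA endpoint")
  }
  if (length(msg)) msg else TRUE
})

#' Edge list of a regulatory network
#' @param net a RegulatoryNetwork
#' @return data.frame with columns from, to, source_is_lnc
#' @export
networkEdges <- function(net) {
  data.frame(net@edges, source_is_lnc = net@edges$from %in% net@lncIds)
}

#' lncRNA ids of a regulatory network
#' @param net a RegulatoryNetwork
#' @export
lncIds <- function(net) net@lncIds

#' @rdname geneIds
#' @export
setMethod("geneIds", "RegulatoryNetwork", function(x) x@codingIds)

#' Protein-coding genes linked to a lncRNA
#'
#' Direction-agnostic neighbors restricted to coding genes; lncRNA-lncRNA
#' edges are retained in the network but never contribute linked genes.
#' @param net a RegulatoryNetwork
#' @param lnc a single lncRNA id
#' @return character vector of coding gene ids (possibly empty)
#' @export
linkedGenes <- function(net, lnc) {
  stopifnot(length(lnc) == 1L)
  nb <- c(net@edges$to[net@edges$from == lnc],
          net@edges$from[net@edges$to == lnc])
  sort(unique(nb[nb %in% net@codingIds]))
}

setMethod("show", "RegulatoryNetwork", function(object) {
  nodes <- unique(c(object@edges$from, object@edges$to))
  cat("RegulatoryNetwork:", nrow(object@edges), "edges over",
      length(nodes), "connected nodes (",
      sum(nodes %in% object@lncIds), "lncRNAs,",
      sum(nodes %in% object@codingIds), "coding genes )\n")
})

#' GOAnnotation: flat term-to-gene annotation over a background
#'
#' @slot termToGenes named list, term id -> character vector of gene ids.
#' @slot termNames named character vector of human-readable labels (may be
#'   empty).
#' @slot background character vector: the enrichment universe.
#' @exportClass GOAnnotation
setClass("GOAnnotation",
  representation(termToGenes = "list", termNames = "character",
                 background = "character"))

setValidity("GOAnnotation", function(object) {
  msg <- character()
  if (any(lengths(object@termToGenes) == 0L))
    msg <- c(msg, "empty terms are not allowed")
  genes <- unique(unlist(object@termToGenes, use.names = FALSE))
  if (!all(genes %in% object@background))
    msg <- c(msg, "annotated genes must belong to the background")
  if (length(msg)) msg else TRUE
})

#' Construct a GOAnnotation
#' @param termToGenes named list term -> gene ids
#' @param background enrichment universe (gene ids)
#' @param termNames optional named character vector of term labels
#' @return a \linkS4class{GOAnnotation}
#' @export
GOAnnotation <- function(termToGenes, background, termNames = character()) {
  termToGenes <- lapply(termToGenes, function(g)
    sort(unique(intersect(g, background))))
  termToGenes <- termToGenes[lengths(termToGenes) > 0L]
  new("GOAnnotation", termToGenes = termToGenes,
      termNames = termNames, background = unique(background))
}

#' Term-to-gene map
#' @param go a GOAnnotation
#' @export
termGenes <- function(go) go@termToGenes

#' Enrichment background (gene universe)
#' @param go a GOAnnotation
#' @export
goBackground <- function(go) go@background

#' Term labels
#' @param go a GOAnnotation
#' @export
termNames <- function(go) go@termNames

setMethod("show", "GOAnnotation", function(object) {
  cat("GOAnnotation:", length(object@termToGenes), "terms over",
      length(object@background), "background genes\n")
})
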