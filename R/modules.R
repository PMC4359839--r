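#' Shortest-path distance matrix between genes through a PPI network
#'
#' Unweighted breadth-first distances through the full interaction network:
#' paths may traverse proteins outside the query set. Queried genes absent
#' from the network are dropped with a warning. Restricting the network to
#' its maximum component beforehand (see [maxComponent()]) guarantees finite
#' entries.
#'
#' @param genes character vector of gene ids
#' @param ppi an undirected igraph graph
#' @return symmetric integer matrix of path lengths (zero diagonal), with
#'   attribute `reason = "no module possible"` when fewer than two genes map
#' @export
shortestPathDistances <- function(genes, ppi) {
  mapped <- intersect(unique(genes), igraph::V(ppi)$name)
  if (length(mapped) < length(unique(genes)))
    warning(length(unique(genes)) - length(mapped),
            " gene(s) absent from the PPI network dropped")
  if (length(mapped) < 2L) {
    d <- matrix(0, length(mapped), length(mapped),
                dimnames = list(mapped, mapped))
    attr(d, "reason") <- "no module possible"
    return(d)
  }
  mapped <- sort(mapped)
  igraph::distances(ppi, v = mapped, to = mapped)
}

#' Average-linkage (UPGMA) clustering of a distance matrix
#'
#' Agglomerates by mean inter-cluster distance; merge heights are
#' non-decreasing on metric input.
#'
#' @param dm symmetric distance matrix
#' @return an object of class `hclust` (merge list + heights)
#' @export
averageLinkage <- function(dm) {
  if (nrow(dm) < 2L) stop("need at least two genes to cluster")
  stats::hclust(stats::as.dist(dm), method = "average")
}

#' Extract minimum-size modules from a dendrogram
#'
#' The basic tree-cut variant: a static cut at `cutHeight` (by default 0.99
#' of the maximum merge height) defines candidate branches; branches with at
#' least `minSize` leaves become modules, smaller branches stay unassigned.
#' Modules are numbered by their lexicographically smallest member id.
#'
#' @param dend an `hclust` object from [averageLinkage()]
#' @param minSize minimum module size (>= 2)
#' @param cutHeight absolute cut height; `NULL` uses
#'   `cutHeightFrac * max(height)`
#' @param cutHeightFrac fraction of the maximum merge height to cut at
#' @return list with `assignment` (named integer vector, `NA` = unassigned),
#'   `modules` (list of gene-id vectors), `minSize`
#' @export
treeCutModules <- function(dend, minSize = 3L, cutHeight = NULL,
                           cutHeightFrac = 0.99) {
  if (minSize < 2L) stop("minSize must be >= 2")
  if (is.null(cutHeight)) cutHeight <- cutHeightFrac * max(dend$height)
  # a flat dendrogram (all merges at one height) has no internal structure
  # to cut: the whole leaf set is a single candidate branch
  flat <- diff(range(dend$height)) < sqrt(.Machine$double.eps)
  branch <- if (flat)
    stats::setNames(rep(1L, length(dend$labels)), dend$labels)
  else stats::cutree(dend, h = cutHeight)
  sizes <- table(branch)
  keep <- as.integer(names(sizes)[sizes >= minSize])
  modules <- lapply(keep, function(b) sort(names(branch)[branch == b]))
  modules <- modules[order(vapply(modules, `[[`, "", 1L))]
  assignment <- rep(NA_integer_, length(branch))
  names(assignment) <- names(branch)
  for (i in seq_along(modules)) assignment[modules[[i]]] <- i
  list(assignment = assignment, modules = modules, minSize = minSize)
}

#' Hypergeometric over-representation test of a gene module
#'
#' One-sided upper-tail test per term: with N background genes, K carrying
#' the term, and m module genes in the background of which k carry the term,
#' \deqn{p = \sum_{i=k}^{\min(m,K)} \binom{K}{i}\binom{N-K}{m-i} / \binom{N}{m}.}
#' Terms with p below `alpha` are returned, sorted by p. No multiple-testing
#' correction is applied by default; `adjust = "BH"` filters on
#' Benjamini-Hochberg adjusted values instead.
#'
#' @param moduleGenes character vector of module gene ids
#' @param go a \linkS4class{GOAnnotation}
#' @param alpha significance threshold (exclusive)
#' @param adjust `"none"` (default) or `"BH"`
#' @return data.frame (term, term_name, k, m, K, N, p_value), with attribute
#'   `reason` when the module does not intersect the background
#' @export
hypergeomEnrich <- function(moduleGenes, go, alpha = 0.05,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  bg <- go@background
  inBg <- intersect(unique(moduleGenes), bg)
  empty <- data.frame(term = character(), term_name = character(),
                      k = integer(), m = integer(), K = integer(),
                      N = integer(), p_value = numeric())
  if (!length(inBg)) {
    attr(empty, "reason") <- "module disjoint from background"
    return(empty)
  }
  N <- length(bg); m <- length(inBg)
  terms <- names(go@termToGenes)
  k <- vapply(go@termToGenes, function(g) length(intersect(g, inBg)),
              integer(1))
  K <- lengths(go@termToGenes)
  p <- stats::phyper(k - 1, K, N - K, m, lower.tail = FALSE)
  crit <- if (adjust == "BH") stats::p.adjust(p, method = "BH") else p
  sel <- crit < alpha
  if (!any(sel)) return(empty)
  nm <- go@termNames[terms[sel]]
  nm[is.na(nm)] <- ""
  out <- data.frame(term = terms[sel], term_name = unname(nm),
                    k = k[sel], m = m, K = K[sel], N = N,
                    p_value = p[sel], row.names = NULL)
  out[order(out$p_value, out$term), , drop = FALSE]
}

#' Assign GO functions to every lncRNA of a regulatory network
#'
#' The module-based guilt-by-association pipeline: for each lncRNA, its
#' directly linked protein-coding genes are mapped onto the PPI network
#' (restricted to its maximum component); pairwise shortest-path distances
#' feed average-linkage clustering; modules of at least `minModule` genes are
#' extracted by a static tree cut; each module is tested for GO term
#' over-representation; and the lncRNA inherits the union of significant
#' terms over its modules. lncRNAs whose genes cannot form a module, or whose
#' modules hit no term, are reported unannotated with the reason.
#'
#' @param net a \linkS4class{RegulatoryNetwork}
#' @param ppi undirected igraph PPI network
#' @param go a \linkS4class{GOAnnotation}
#' @param minModule minimum module size
#' @param alpha enrichment threshold (exclusive)
#' @param cutHeightFrac static-cut height as a fraction of the maximum merge
#'   height
#' @param adjust multiple-testing mode passed to [hypergeomEnrich()]
#' @return list with `assignments` (data.frame: lnc, term, term_name,
#'   p_value, module_id, module_genes) and `unannotated` (data.frame: lnc,
#'   reason)
#' @export
assignFunctions <- function(net, ppi, go, minModule = 3L, alpha = 0.05,
                            cutHeightFrac = 0.99, adjust = "none") {
  ppi <- maxComponent(ppi)
  lncs <- sort(intersect(net@lncIds,
                         unique(c(net@edges$from, net@edges$to))))
  hits <- list(); misses <- list()
  for (l in lncs) {
    genes <- linkedGenes(net, l)
    d <- suppressWarnings(shortestPathDistances(genes, ppi))
    if (nrow(d) < 2L || nrow(d) < minModule) {
      misses[[l]] <- data.frame(lnc = l, reason = "no module")
      next
    }
    cut <- treeCutModules(averageLinkage(d), minSize = minModule,
                          cutHeightFrac = cutHeightFrac)
    if (!length(cut$modules)) {
      misses[[l]] <- data.frame(lnc = l, reason = "no module")
      next
    }
    found <- list()
    for (i in seq_along(cut$modules)) {
      enr <- hypergeomEnrich(cut$modules[[i]], go, alpha = alpha,
                             adjust = adjust)
      if (nrow(enr))
        found[[length(found) + 1L]] <- data.frame(
          lnc = l, term = enr$term, term_name = enr$term_name,
          p_value = enr$p_value, module_id = i,
          module_genes = paste(cut$modules[[i]], collapse = ","))
    }
    if (!length(found)) {
      misses[[l]] <- data.frame(lnc = l, reason = "no enrichment")
      next
    }
    res <- do.call(rbind, found)
    # keep the best-supported record per term
    res <- res[order(res$term, res$p_value), , drop = FALSE]
    res <- res[!duplicated(res$term), , drop = FALSE]
    hits[[l]] <- res
  }
  assignments <- if (length(hits)) do.call(rbind, hits) else
    data.frame(lnc = character(), term = character(),
               term_name = character(), p_value = numeric(),
               module_id = integer(), module_genes = character())
  unannotated <- if (length(misses)) do.call(rbind, misses) else
    data.frame(lnc = character(), reason = character())
  rownames(assignments) <- rownames(unannotated) <- NULL
  list(assignments = assignments, unannotated = unannotated)
}
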