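#' Extract the lncRNA-incident regulatory network from a learned DAG
#'
#' Keeps exactly the directed edges with at least one lncRNA endpoint;
#' gene-gene edges are dropped. Idempotent.
#'
#' @param dag a \linkS4class{DiscreteDAG}
#' @param lncIds lncRNA variable ids (disjoint from `codingIds`)
#' @param codingIds protein-coding variable ids
#' @return a \linkS4class{RegulatoryNetwork}
#' @export
extractNetwork <- function(dag, lncIds, codingIds) {
  if (length(intersect(lncIds, codingIds)))
    stop("lncRNA and coding id sets overlap")
  e <- dagEdges(dag)
  keep <- e$from %in% lncIds | e$to %in% lncIds
  new("RegulatoryNetwork", edges = e[keep, , drop = FALSE],
      lncIds = as.character(lncIds), codingIds = as.character(codingIds))
}

#' Degree summary of the lncRNAs in a regulatory network
#'
#' Degree counts both edge directions (in + out) over the kept edges.
#'
#' @param net a \linkS4class{RegulatoryNetwork}
#' @return list with `degrees` (named vector over lncRNAs appearing in the
#'   network), `mean`, `max`, and `empty` (TRUE when the network has no
#'   edges; mean and max are then reported as 0)
#' @export
degreeSummary <- function(net) {
  e <- net@edges
  deg <- table(factor(c(e$from, e$to),
                      levels = sort(unique(c(e$from, e$to)))))
  deg <- deg[names(deg) %in% net@lncIds]
  deg <- stats::setNames(as.integer(deg), names(deg))
  if (!length(deg))
    return(list(degrees = deg, mean = 0, max = 0, empty = TRUE))
  list(degrees = deg, mean = mean(deg), max = max(deg), empty = FALSE)
}

#' Gene midpoints from a catalog
#'
#' Position anchor for distance analyses: the midpoint of the merged-exon
#' genomic span.
#' @param catalog a \linkS4class{TranscriptCatalog}
#' @return data.frame with columns gene_id, chrom, midpoint
#' @export
geneMidpoints <- function(catalog) {
  sp <- unlist(range(catalog@exons))
  data.frame(gene_id = names(sp),
             chrom = as.character(seqnames(sp)),
             midpoint = (start(sp) + end(sp)) / 2,
             stringsAsFactors = FALSE)
}

#' Cis/trans profile of lncRNA-gene links
#'
#' For each lncRNA of the network: how many of its linked protein-coding
#' genes lie on the same chromosome, their midpoint distances, and how many
#' fall within the cis window (<= `cisWindow` bp, 100 kb by default,
#' boundary inclusive).
#'
#' @param net a \linkS4class{RegulatoryNetwork}
#' @param coords data.frame (gene_id, chrom, midpoint), e.g. from
#'   [geneMidpoints()]; ids without coordinates are skipped with a warning
#' @param cisWindow cis distance threshold in bp
#' @return list with `perLnc` (data.frame: lnc, linked, same_chrom, cis),
#'   `distances` (numeric vector over all same-chromosome pairs), and
#'   `cisLncCount` (lncRNAs with >= 1 link within the window)
#' @export
cisTrans <- function(net, coords, cisWindow = 1e5) {
  pos <- stats::setNames(coords$midpoint, coords$gene_id)
  chr <- stats::setNames(coords$chrom, coords$gene_id)
  lncs <- intersect(net@lncIds, unique(c(net@edges$from, net@edges$to)))
  missing <- character()
  rows <- list(); dists <- numeric()
  for (l in lncs) {
    genes <- linkedGenes(net, l)
    known <- genes[genes %in% names(pos)]
    missing <- c(missing, setdiff(genes, known))
    if (!(l %in% names(pos))) { missing <- c(missing, l); next }
    same <- known[chr[known] == chr[[l]]]
    d <- abs(pos[same] - pos[[l]])
    dists <- c(dists, unname(d))
    rows[[l]] <- data.frame(lnc = l, linked = length(known),
                            same_chrom = length(same),
                            cis = sum(d <= cisWindow))
  }
  if (length(missing))
    warning(length(unique(missing)), " id(s) without coordinates skipped")
  perLnc <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lnc = character(), linked = integer(),
               same_chrom = integer(), cis = integer())
  rownames(perLnc) <- NULL
  list(perLnc = perLnc, distances = dists,
       cisLncCount = sum(perLnc$cis > 0))
}

#' Categorize network edges by differential-expression direction
#'
#' Each edge is assigned by the (lncRNA endpoint, coding endpoint) label pair
#' to consistent up/up, consistent down/down, lncRNA-up/gene-down,
#' lncRNA-down/gene-up, or `other` (any endpoint not differential, unlabeled,
#' or a lncRNA-lncRNA edge). The five counts partition the edge set.
#'
#' @param net a \linkS4class{RegulatoryNetwork}
#' @param labels named character vector over node ids with values `up`,
#'   `down`, `ns`
#' @return named integer vector: up_up, down_down, up_down, down_up, other
#' @export
edgeDeCategories <- function(net, labels) {
  bad <- setdiff(unique(labels), c("up", "down", "ns"))
  if (length(bad)) stop("unknown DE label: ", bad[1])
  out <- c(up_up = 0L, down_down = 0L, up_down = 0L, down_up = 0L,
           other = 0L)
  lab <- function(id) if (id %in% names(labels)) labels[[id]] else "ns"
  e <- net@edges
  for (i in seq_len(nrow(e))) {
    a <- e$from[i]; b <- e$to[i]
    if (a %in% net@lncIds && b %in% net@codingIds) { l <- a; g <- b }
    else if (b %in% net@lncIds && a %in% net@codingIds) { l <- b; g <- a }
    else { out[["other"]] <- out[["other"]] + 1L; next }
    key <- paste(lab(l), lab(g), sep = "_")
    if (key %in% names(out)) out[[key]] <- out[[key]] + 1L
    else out[["other"]] <- out[["other"]] + 1L
  }
  out
}

#' Nearest protein-coding gene of each lncRNA
#'
#' Nearest by midpoint distance on the same chromosome; ties go to the
#' lexicographically smaller gene id. lncRNAs on a chromosome without coding
#' genes are absent from the result (with a warning).
#'
#' @param lncCoords data.frame (gene_id, chrom, midpoint) for lncRNAs
#' @param codingCoords same for protein-coding genes
#' @return named character vector: lncRNA id -> nearest coding gene id
#' @export
nearestNeighborGenes <- function(lncCoords, codingCoords) {
  out <- character()
  orphans <- character()
  for (i in seq_len(nrow(lncCoords))) {
    l <- lncCoords$gene_id[i]
    cand <- codingCoords[codingCoords$chrom == lncCoords$chrom[i], ]
    if (!nrow(cand)) { orphans <- c(orphans, l); next }
    d <- abs(cand$midpoint - lncCoords$midpoint[i])
    best <- which(d == min(d))
    out[[l]] <- sort(cand$gene_id[best])[1]
  }
  if (length(orphans))
    warning(length(orphans),
            " lncRNA(s) on chromosomes without coding genes skipped")
  out
}
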