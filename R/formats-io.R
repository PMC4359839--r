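#' @importFrom rtracklayer import
#' @importFrom igraph graph_from_data_frame simplify components induced_subgraph
#'   V vcount ecount distances degree
NULL

# Build a catalog from an exon-level GRanges carrying a gene_id column.
.catalogFromExons <- function(gr) {
  if (length(gr) == 0L) {
    return(new("TranscriptCatalog", exons = GRangesList(),
               geneData = DataFrame(gene_id = character(),
                                    chrom = character(), strand = character(),
                                    exonic_length = integer())))
  }
  byGene <- GenomicRanges::reduce(
    GenomicRanges::split(gr, gr$gene_id))
  byGene <- byGene[order(names(byGene))]
  firstRange <- unlist(range(byGene))
  gd <- DataFrame(
    gene_id = names(byGene),
    chrom = as.character(seqnames(firstRange)),
    strand = as.character(strand(firstRange)),
    exonic_length = vapply(width(byGene), sum, integer(1)))
  new("TranscriptCatalog", exons = byGene, geneData = gd)
}

#' Read gene models from a GTF file
#'
#' Parses a tab-separated GTF, keeps exon features (all features when no
#' `exon` rows are present), and merges overlapping exons per `gene_id` into
#' a \linkS4class{TranscriptCatalog}. Records whose start exceeds their end
#' are rejected with a warning; structurally malformed lines raise an error
#' naming the offending line.
#'
#' @param path path to a GTF file
#' @return a \linkS4class{TranscriptCatalog}
#' @export
readGtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9L)
  if (length(bad))
    stop("malformed GTF line ", which(keep)[bad[1]], " in ", path,
         ": expected 9 tab-separated fields")
  if (!any(keep)) return(.catalogFromExons(GRanges()))
  starts <- as.numeric(vapply(fields, `[[`, "", 4L))
  ends <- as.numeric(vapply(fields, `[[`, "", 5L))
  if (anyNA(starts) || anyNA(ends)) {
    badLine <- which(keep)[which(is.na(starts) | is.na(ends))[1]]
    stop("malformed GTF line ", badLine, " in ", path,
         ": non-numeric coordinates")
  }
  inverted <- starts > ends
  if (any(inverted)) {
    warning(sum(inverted), " GTF record(s) with start > end rejected")
    if (all(inverted)) return(.catalogFromExons(GRanges()))
  }
  tmp <- tempfile(fileext = ".gtf")
  on.exit(unlink(tmp))
  writeLines(lines[keep][!inverted], tmp)
  gr <- rtracklayer::import(tmp, format = "gtf")
  if (is.null(gr$gene_id) || anyNA(gr$gene_id))
    stop("GTF in ", path, " lacks a gene_id attribute on some records")
  if ("type" %in% names(mcols(gr)) && any(gr$type == "exon"))
    gr <- gr[gr$type == "exon"]
  .catalogFromExons(gr)
}

#' Write a catalog as GTF
#'
#' Emits one `exon` feature per merged exon, carrying the `gene_id`
#' attribute. `readGtf(writeGtf(x))` reproduces the merged exon sets of `x`.
#'
#' @param catalog a \linkS4class{TranscriptCatalog}
#' @param path output path
#' @param source value for the GTF source column
#' @return `path`, invisibly
#' @export
writeGtf <- function(catalog, path, source = "lncFunNet") {
  ex <- unlist(catalog@exons)
  gene <- names(ex)
  lines <- if (length(ex)) {
    sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
            as.character(seqnames(ex)), source, start(ex), end(ex),
            as.character(strand(ex)), gene)
  } else character()
  writeLines(lines, path)
  invisible(path)
}

#' Read a genes-by-samples expression matrix
#'
#' Expects a TSV with a header row of sample ids and gene ids in the first
#' column. Missing cells (`NA` or empty) are zero-filled: absence of a
#' transcript in a sample is treated as zero abundance, not as missing data.
#'
#' @param path path to the TSV
#' @return numeric matrix, genes in rows (rownames), samples in columns
#' @export
readExpressionMatrix <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  if (ncol(tab) < 2L) stop("expression table needs gene ids plus >=1 sample")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicate gene id in expression matrix: ",
         ids[duplicated(ids)][1])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  m[is.na(m)] <- 0
  if (any(!is.finite(m))) stop("non-finite expression value")
  if (any(m < 0)) stop("negative expression value")
  rownames(m) <- ids
  m
}

#' Write a genes-by-samples matrix as TSV
#' @param m matrix with gene rownames and sample colnames
#' @param path output path
#' @param idColumn header for the gene-id column
#' @return `path`, invisibly
#' @export
writeExpressionMatrix <- function(m, path, idColumn = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- idColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an undirected protein-protein interaction edge list
#'
#' Two-column TSV of gene-id pairs. Duplicate edges (in either orientation)
#' and self-loops are removed.
#'
#' @param path path to the TSV (no header expected; a `gene1 gene2`-style
#'   header line is tolerated and dropped)
#' @return an undirected \pkg{igraph} graph
#' @export
readPpi <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("PPI table needs two columns")
  g <- igraph::graph_from_data_frame(tab[, 1:2], directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (igraph::ecount(g) == 0L) stop("PPI network has no usable edges")
  g
}

#' Restrict a PPI graph to its maximum connected component
#'
#' Ties on component size are broken toward the component containing the
#' lexicographically smallest member id. Idempotent.
#'
#' @param g an undirected igraph graph
#' @return the induced subgraph on the largest component
#' @export
maxComponent <- function(g) {
  comp <- igraph::components(g)
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1L) {
    firstMember <- vapply(cand, function(ci)
      min(igraph::V(g)$name[comp$membership == ci]), character(1))
    cand <- cand[order(firstMember)][1]
  }
  igraph::induced_subgraph(g, which(comp$membership == cand[1]))
}

#' Read a flat gene-to-GO-term table
#'
#' Two columns gene id, term id; an optional third column supplies the term
#' name. Genes outside the background are dropped (count reported via
#' `message`); terms left empty are removed.
#'
#' @param path path to the TSV
#' @param background character vector: the enrichment universe
#' @return a \linkS4class{GOAnnotation}
#' @export
readGoTable <- function(path, background) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("GO table has no rows")
  if (ncol(tab) < 2L) stop("GO table needs gene and term columns")
  gene <- as.character(tab[[1]]); term <- as.character(tab[[2]])
  dropped <- !(gene %in% background)
  if (any(dropped))
    message(sum(dropped), " annotation row(s) outside the background dropped")
  gene <- gene[!dropped]; term <- term[!dropped]
  if (!length(gene)) {
    warning("no annotation rows map to the background")
    return(new("GOAnnotation", termToGenes = list(),
               termNames = character(), background = unique(background)))
  }
  termNames <- character()
  if (ncol(tab) >= 3L) {
    nm <- as.character(tab[[3]])[!dropped]
    termNames <- stats::setNames(nm, term)[!duplicated(term)]
  }
  GOAnnotation(split(gene, term), background = background,
               termNames = termNames)
}
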