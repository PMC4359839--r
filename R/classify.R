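#' Fraction of a gene's exonic bases covered by a reference annotation
#'
#' Overlap is computed on merged exonic bases: the numerator is the number of
#' query exonic bases intersecting the reference's exonic bases, the
#' denominator the query's merged exonic length (or its genomic span when
#' `denominator = "span"`). Strand is ignored.
#'
#' @param query a GRanges of exons (any overlap structure; merged internally)
#' @param reference a GRanges of reference exons, or a
#'   \linkS4class{TranscriptCatalog} whose exons are pooled
#' @param denominator `"exonic"` (default) or `"span"`
#' @return a fraction in \[0, 1\]
#' @export
overlapFraction <- function(query, reference, denominator = c("exonic", "span")) {
  denominator <- match.arg(denominator)
  if (is(reference, "TranscriptCatalog"))
    reference <- unlist(reference@exons)
  query <- GenomicRanges::reduce(GenomicRanges::granges(query),
                                 ignore.strand = TRUE)
  qlen <- if (denominator == "exonic") sum(width(query)) else {
    sp <- range(query, ignore.strand = TRUE); sum(width(sp))
  }
  if (qlen == 0L) stop("query gene has zero exonic length")
  if (length(reference) == 0L) return(0)
  reference <- GenomicRanges::reduce(GenomicRanges::granges(reference),
                                     ignore.strand = TRUE)
  # disjoint seqlevel sets (nothing on a shared chromosome) are a valid
  # zero-overlap case, not worth a warning
  hit <- suppressWarnings(
    GenomicRanges::intersect(query, reference, ignore.strand = TRUE))
  sum(width(hit)) / qlen
}

.CLASS_ORDER <- c("PSEUDOGENE", "NCRNA", "LINCRNA", "CODING")

#' Default annotation-overlap thresholds
#'
#' Pseudogene, noncoding-RNA and lincRNA calls require at least 90% exonic
#' overlap with the respective annotation; the protein-coding call requires
#' at least 60%. Thresholds are inclusive ("at least").
#' @return named numeric vector
#' @export
defaultOverlapThresholds <- function() {
  c(PSEUDOGENE = 0.90, NCRNA = 0.90, LINCRNA = 0.90, CODING = 0.60)
}

#' Classify assembled genes against reference annotation
#'
#' Applies the ordered overlap rules: a gene is a pseudogene if its exonic
#' overlap with the pseudogene annotation reaches the threshold; surviving
#' genes are tested against known noncoding RNAs, then lincRNAs (90% each),
#' then protein-coding genes (60%); anything left is UNANNOTATED. The first
#' rule met wins, so the rule order is part of the definition.
#'
#' @param catalog a \linkS4class{TranscriptCatalog} of assembled genes
#' @param annotations named list with any of `PSEUDOGENE`, `NCRNA`,
#'   `LINCRNA`, `CODING`; each a \linkS4class{TranscriptCatalog} or GRanges.
#'   Missing categories are treated as empty annotation.
#' @param thresholds named overlap thresholds, see
#'   [defaultOverlapThresholds()]
#' @param denominator passed to [overlapFraction()]
#' @return the catalog with `class` and `best_overlap` metadata columns
#' @export
classifyCatalog <- function(catalog, annotations,
                            thresholds = defaultOverlapThresholds(),
                            denominator = "exonic") {
  refs <- lapply(.CLASS_ORDER, function(cl) {
    a <- annotations[[cl]]
    if (is.null(a)) return(GRanges())
    if (is(a, "TranscriptCatalog")) a <- unlist(a@exons)
    GenomicRanges::reduce(GenomicRanges::granges(a), ignore.strand = TRUE)
  })
  names(refs) <- .CLASS_ORDER
  n <- length(catalog)
  cls <- rep("UNANNOTATED", n)
  best <- numeric(n)
  for (i in seq_len(n)) {
    q <- catalog@exons[[i]]
    for (cl in .CLASS_ORDER) {
      f <- overlapFraction(q, refs[[cl]], denominator = denominator)
      if (f > best[i]) best[i] <- f
      if (f >= thresholds[[cl]]) { cls[i] <- cl; break }
    }
  }
  catalog@geneData$class <- cls
  catalog@geneData$best_overlap <- best
  validObject(catalog)
  catalog
}

#' Select lncRNAs from a classified catalog
#'
#' lncRNAs are the union of noncoding-RNA genes whose merged exonic length
#' strictly exceeds `minLength` (200 bp by default) and all lincRNA genes;
#' the length rule applies to lincRNAs too only when `applyLengthToAll`.
#'
#' @param catalog a classified \linkS4class{TranscriptCatalog}
#' @param minLength minimum exonic length in bp, exclusive
#' @param applyLengthToAll also subject lincRNAs to the length rule
#' @return sorted character vector of lncRNA gene ids
#' @export
selectLncRNAs <- function(catalog, minLength = 200, applyLengthToAll = FALSE) {
  cls <- geneClasses(catalog)
  len <- exonicLength(catalog)
  nc <- names(cls)[cls == "NCRNA" & len > minLength]
  li <- names(cls)[cls == "LINCRNA"]
  if (applyLengthToAll) li <- li[len[li] > minLength]
  sort(unique(c(nc, li)))
}

#' Filter genes by sample presence
#'
#' Keeps genes expressed (abundance strictly above `minFpkm`) in at least
#' `minSamples` samples. Columns are untouched; idempotent.
#'
#' @param m numeric genes-by-samples matrix
#' @param minSamples minimum number of expressing samples
#' @param minFpkm expression threshold, exclusive (0 means any nonzero value
#'   counts as "present")
#' @return the row-filtered matrix
#' @export
presenceFilter <- function(m, minSamples = 50, minFpkm = 0) {
  if (minSamples > ncol(m))
    stop("minSamples (", minSamples, ") exceeds the sample count (",
         ncol(m), ")")
  keep <- rowSums(m > minFpkm) >= minSamples
  m[keep, , drop = FALSE]
}
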