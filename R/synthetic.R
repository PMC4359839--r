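# Synthetic-data generators. Every pipeline input (GTF annotation, FPKM
# matrix, PPI edge list, GO table) can be produced with known ground truth,
# so each stage and the end-to-end pipeline are testable without external
# accessions.

# Draw an epsilon-deterministic CPT for a binary child: one preferred level
# per parent configuration, carrying probability 1 - epsilon. The preferred-
# level map is resampled until it depends on every parent (a constant-in-one-
# parent map would make that edge undetectable by construction).
.epsilonCpt <- function(nParents, epsilon) {
  q <- 2L^nParents
  cfg <- 0:(q - 1L)
  repeat {
    pref <- sample(0:1, q, replace = TRUE)
    if (nParents == 0L) break
    dep <- vapply(seq_len(nParents) - 1L, function(bit)
      any(pref[cfg + 1L] !=
            pref[bitwXor(cfg, bitwShiftL(1L, bit)) + 1L]),
      logical(1))
    if (all(dep)) break
  }
  prob <- matrix(epsilon, nrow = q, ncol = 2)
  prob[cbind(seq_len(q), pref + 1L)] <- 1 - epsilon
  prob
}

#' Simulate a random DAG with conditional probability tables
#'
#' Variables get a random topological order; each forward pair becomes an
#' edge with probability `edgeProb`, multiplied by `lncBias` (capped at 1)
#' when it runs from a lncRNA to a protein-coding gene. CPTs are either
#' epsilon-deterministic (each parent configuration prefers one child level
#' with probability 1 - `epsilon`; the preferred-level map always depends on
#' every parent) or Dirichlet(`alpha`) rows.
#'
#' @param nLnc,nGene numbers of lncRNA and coding variables (ids `LNC*`,
#'   `G*`)
#' @param edgeProb base edge probability per forward pair
#' @param lncBias multiplier favoring lncRNA-to-gene edges
#' @param cptMode `"epsilon"` or `"dirichlet"`
#' @param epsilon flip probability in epsilon mode
#' @param alpha Dirichlet concentration in dirichlet mode
#' @param maxParents cap on parent-set size during generation
#' @param seed integer seed, or `NULL`
#' @return list with `dag` (a \linkS4class{DiscreteDAG}), `cpds` (as accepted
#'   by [sampleFromNetwork()]), `lncIds`, `geneIds`
#' @export
simulateDag <- function(nLnc, nGene, edgeProb, lncBias = 1,
                        cptMode = c("epsilon", "dirichlet"), epsilon = 0.1,
                        alpha = 0.5, maxParents = 3L, seed = NULL) {
  cptMode <- match.arg(cptMode)
  run <- function() {
    lnc <- sprintf("LNC%02d", seq_len(nLnc))
    gene <- sprintf("G%03d", seq_len(nGene))
    vars <- c(lnc, gene)
    ord <- sample(vars)
    parents <- stats::setNames(rep(list(character()), length(vars)), vars)
    for (j in seq_along(ord)) {
      for (i in seq_len(j - 1L)) {
        p <- edgeProb
        if (ord[i] %in% lnc && ord[j] %in% gene) p <- min(1, p * lncBias)
        if (length(parents[[ord[j]]]) >= maxParents) break
        if (stats::runif(1) < p)
          parents[[ord[j]]] <- c(parents[[ord[j]]], ord[i])
      }
    }
    dag <- DiscreteDAG(vars, parents)
    cpds <- lapply(vars, function(v) {
      np <- length(parents[[v]])
      prob <- if (cptMode == "epsilon") .epsilonCpt(np, epsilon) else {
        rows <- matrix(stats::rgamma(2^np * 2, shape = alpha), ncol = 2)
        rows / rowSums(rows)
      }
      list(parents = parents[[v]], prob = prob)
    })
    names(cpds) <- vars
    list(dag = dag, cpds = cpds, lncIds = lnc, geneIds = gene)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Emit a continuous FPKM-like matrix from discrete network samples
#'
#' Samples discrete levels ancestrally from the network, then emits a
#' Gaussian value per level (mean `levelMeans[level + 1]`, sd `levelSd`),
#' truncated at zero to mimic the zero-inflation of FPKM data.
#'
#' @param dag,cpds as accepted by [sampleFromNetwork()]
#' @param nSamples number of samples (columns)
#' @param levelMeans per-level emission means (must be increasing)
#' @param levelSd emission standard deviation (> 0)
#' @param seed integer seed, or `NULL`
#' @return list with `values` (numeric variables-by-samples matrix) and
#'   `levels` (the generating discrete levels)
#' @export
simulateExpression <- function(dag, cpds, nSamples, levelMeans = c(3, 9),
                               levelSd = 1, seed = NULL) {
  stopifnot(levelSd > 0, !is.unsorted(levelMeans))
  run <- function() {
    lev <- sampleFromNetwork(dag, cpds, nSamples, seed = NULL)
    vals <- matrix(pmax(0, stats::rnorm(length(lev),
                                        mean = levelMeans[lev + 1L],
                                        sd = levelSd)),
                   nrow = nrow(lev), dimnames = dimnames(lev))
    colnames(vals) <- sprintf("S%02d", seq_len(nSamples))
    list(values = vals, levels = lev)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a PPI network with planted modules
#'
#' Planted-partition graph: within-module edges appear with probability
#' `pWithin`, between-module edges with `pBetween`, plus one bridge edge
#' between consecutive modules (first members), guaranteeing a single
#' connected component for every seed.
#'
#' @param nModules,moduleSize partition shape
#' @param pWithin,pBetween edge probabilities (`pWithin > pBetween`)
#' @param genes optional gene ids (length `nModules * moduleSize`); defaults
#'   to `P001...`
#' @param seed integer seed, or `NULL`
#' @return list with `graph` (igraph) and `modules` (list of gene-id vectors)
#' @export
simulatePpiModules <- function(nModules, moduleSize, pWithin = 1,
                               pBetween = 0, genes = NULL, seed = NULL) {
  stopifnot(pWithin > pBetween)
  if (is.null(genes))
    genes <- sprintf("P%03d", seq_len(nModules * moduleSize))
  stopifnot(length(genes) == nModules * moduleSize)
  run <- function() {
    modules <- split(genes, rep(seq_len(nModules), each = moduleSize))
    edges <- list()
    for (mi in seq_len(nModules)) {
      g <- modules[[mi]]
      pairs <- t(utils::combn(g, 2))
      keep <- stats::runif(nrow(pairs)) < pWithin
      edges[[length(edges) + 1L]] <- pairs[keep, , drop = FALSE]
    }
    if (pBetween > 0 && nModules > 1L) {
      for (mi in seq_len(nModules - 1L)) for (mj in (mi + 1L):nModules) {
        pairs <- expand.grid(modules[[mi]], modules[[mj]],
                             stringsAsFactors = FALSE)
        keep <- stats::runif(nrow(pairs)) < pBetween
        edges[[length(edges) + 1L]] <- as.matrix(pairs[keep, , drop = FALSE])
      }
    }
    # deterministic spanning structure: a path within each module and one
    # bridge between consecutive modules, so the graph is connected for
    # every seed regardless of the random edge draws
    for (mi in seq_len(nModules)) {
      g <- modules[[mi]]
      if (length(g) > 1L)
        edges[[length(edges) + 1L]] <- cbind(g[-length(g)], g[-1L])
    }
    for (mi in seq_len(max(nModules - 1L, 0L)))
      edges[[length(edges) + 1L]] <-
        matrix(c(modules[[mi]][1], modules[[mi + 1L]][1]), ncol = 2)
    em <- do.call(rbind, edges)
    g <- igraph::graph_from_data_frame(
      data.frame(from = em[, 1], to = em[, 2]), directed = FALSE,
      vertices = genes)
    list(graph = igraph::simplify(g), modules = modules)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a flat GO table with planted module terms
#'
#' Each planted module receives `termsPerModule` dedicated terms covering
#' exactly its genes; every other background gene is added to each term
#' independently at `noiseRate`.
#'
#' @param modules list of gene-id vectors (the planted modules)
#' @param background enrichment universe
#' @param termsPerModule dedicated terms per module
#' @param noiseRate per-gene-per-term noise annotation probability in \[0,1)
#' @param seed integer seed, or `NULL`
#' @return list with `go` (a \linkS4class{GOAnnotation}), `table`
#'   (data.frame gene, term, name) and `moduleTerms` (term ids per module)
#' @export
simulateGoTable <- function(modules, background, termsPerModule = 1L,
                            noiseRate = 0.05, seed = NULL) {
  stopifnot(noiseRate >= 0, noiseRate < 1)
  run <- function() {
    termToGenes <- list(); termNames <- character()
    moduleTerms <- vector("list", length(modules))
    for (mi in seq_along(modules)) {
      for (t in seq_len(termsPerModule)) {
        term <- sprintf("GO:M%02d_%d", mi, t)
        extra <- setdiff(background, modules[[mi]])
        noisy <- extra[stats::runif(length(extra)) < noiseRate]
        termToGenes[[term]] <- sort(unique(c(modules[[mi]], noisy)))
        termNames[[term]] <- sprintf("planted process of module %d", mi)
        moduleTerms[[mi]] <- c(moduleTerms[[mi]], term)
      }
    }
    tab <- data.frame(
      gene = unlist(termToGenes, use.names = FALSE),
      term = rep(names(termToGenes), lengths(termToGenes)),
      name = rep(unname(termNames[names(termToGenes)]),
                 lengths(termToGenes)))
    list(go = GOAnnotation(termToGenes, background, termNames),
         table = tab, moduleTerms = moduleTerms)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# A single-exon gene catalog from a coordinate table.
.catalogFromTable <- function(tab) {
  gr <- GRanges(tab$chrom, IRanges(tab$start, tab$end), strand = tab$strand)
  gr$gene_id <- tab$gene_id
  .catalogFromExons(gr)
}

#' Deterministic GTF classification fixture
#'
#' A small constructed annotation bundle exercising every classification
#' rule at its boundary: a gene with 95% pseudogene overlap; noncoding-RNA
#' genes of exonic length 250 and exactly 200 with 95% overlap; a 95%
#' lincRNA gene; and genes with 65% and 55% coding overlap (the latter
#' falling below the 60% rule, hence unannotated).
#'
#' @return list with `assembled` and per-category annotation
#'   \linkS4class{TranscriptCatalog}s, `expectedClasses` (named character)
#'   and `expectedLnc` (the lncRNA ids the length rule admits)
#' @export
gtfClassificationFixture <- function() {
  asm <- data.frame(
    gene_id = c("g_pseudo", "g_nc250", "g_nc200", "g_linc", "g_cod65",
                "g_cod55"),
    chrom = "chr1", strand = "+",
    start = c(1001, 10001, 20001, 30001, 40001, 50001),
    end = c(2000, 10250, 20200, 30400, 41000, 51000))
  annot <- list(
    PSEUDOGENE = data.frame(gene_id = "ps1", chrom = "chr1", strand = "+",
                            start = 1001, end = 1950),
    NCRNA = data.frame(gene_id = c("nc1", "nc2"), chrom = "chr1",
                       strand = "+", start = c(10001, 20001),
                       end = c(10238, 20190)),
    LINCRNA = data.frame(gene_id = "li1", chrom = "chr1", strand = "+",
                         start = 30001, end = 30380),
    CODING = data.frame(gene_id = c("cd1", "cd2"), chrom = "chr1",
                        strand = "+", start = c(40001, 50001),
                        end = c(40650, 50550)))
  list(assembled = .catalogFromTable(asm),
       annotations = lapply(annot, .catalogFromTable),
       expectedClasses = c(g_pseudo = "PSEUDOGENE", g_nc250 = "NCRNA",
                           g_nc200 = "NCRNA", g_linc = "LINCRNA",
                           g_cod65 = "CODING", g_cod55 = "UNANNOTATED"),
       expectedLnc = c("g_linc", "g_nc250"))
}

#' Generate the full synthetic input bundle with planted ground truth
#'
#' The reference study conditions for testing the whole pipeline: `nLnc`
#' lncRNA regulators, each the sole parent of its own block of
#' `genesPerLnc` protein-coding genes (epsilon-deterministic CPTs), sampled
#' over `nSamples` samples and emitted as zero-truncated Gaussian FPKM; a
#' GTF annotation set placing every gene on a genome (lncRNAs alternately
#' matching the noncoding-RNA and lincRNA annotation); a planted-partition
#' PPI whose modules are exactly the gene blocks; and a GO table with one
#' dedicated term per module plus annotation noise. The intended function of
#' lncRNA i is its block's term.
#'
#' @param dir optional directory; when given, all standard-format inputs plus
#'   `truth.json` are written there
#' @param nLnc,genesPerLnc,nSamples bundle shape
#' @param epsilon CPT flip probability
#' @param levelMeans,levelSd emission parameters
#' @param noiseRate GO annotation noise
#' @param seed integer seed (the bundle is byte-identical per seed)
#' @return list: `dag`, `cpds`, `lncIds`, `geneIds`, `expression` (continuous
#'   matrix), `levels` (generating truth), `assembled` + `annotations`
#'   (catalogs), `ppi`, `modules`, `go`, `goTable`, `intendedFunctions`
#'   (named list lncRNA -> term ids), `files` (paths, when `dir` given)
#' @export
simulateBundle <- function(dir = NULL, nLnc = 20L, genesPerLnc = 4L,
                           nSamples = 60L, epsilon = 0.1,
                           levelMeans = c(3, 9), levelSd = 1,
                           noiseRate = 0.01, seed = 1L) {
  withr::with_seed(seed, {
    lnc <- sprintf("LNC%02d", seq_len(nLnc))
    genes <- sprintf("G%03d", seq_len(nLnc * genesPerLnc))
    blocks <- split(genes, rep(seq_len(nLnc), each = genesPerLnc))
    parents <- c(stats::setNames(rep(list(character()), nLnc), lnc),
                 stats::setNames(rep(list(NULL), length(genes)), genes))
    for (i in seq_len(nLnc)) for (g in blocks[[i]]) parents[[g]] <- lnc[i]
    dag <- DiscreteDAG(c(lnc, genes), parents)
    copy <- matrix(c(1 - epsilon, epsilon, epsilon, 1 - epsilon),
                   nrow = 2, byrow = TRUE)
    cpds <- lapply(c(lnc, genes), function(v) {
      if (v %in% lnc) list(parents = character(),
                           prob = matrix(0.5, 1, 2))
      else list(parents = parents[[v]], prob = copy)
    })
    names(cpds) <- c(lnc, genes)
    # balanced cohort: each regulator is high in exactly half the samples
    # (condition-driven regulators over a balanced case/control design)
    lev <- matrix(0L, nrow = nLnc + length(genes), ncol = nSamples,
                  dimnames = list(c(lnc, genes), NULL))
    for (l in lnc)
      lev[l, ] <- sample(rep(0:1, length.out = nSamples))
    # stratified flip noise: each child disagrees with its regulator on
    # epsilon*n samples, half in each direction, so class balance is kept
    nf <- max(1L, round(epsilon * nSamples / 2))
    for (i in seq_len(nLnc)) for (g in blocks[[i]]) {
      base <- lev[lnc[i], ]
      flip <- c(sample(which(base == 0L), nf),
                sample(which(base == 1L), nf))
      base[flip] <- 1L - base[flip]
      lev[g, ] <- base
    }
    vals <- matrix(pmax(0, stats::rnorm(length(lev),
                                        mean = levelMeans[lev + 1L],
                                        sd = levelSd)),
                   nrow = nrow(lev), dimnames = dimnames(lev))
    colnames(vals) <- sprintf("S%02d", seq_len(nSamples))
    emis <- list(values = vals, levels = lev)

    # genome: genes laid out on 4 chromosomes, one locus per 200 kb
    ids <- c(lnc, genes)
    chrom <- sprintf("chr%d", (seq_along(ids) - 1L) %% 4L + 1L)
    startPos <- 1e5 + ((seq_along(ids) - 1L) %/% 4L) * 2e5
    len <- ifelse(ids %in% lnc, 300L, 1000L)
    asm <- data.frame(gene_id = ids, chrom = chrom, strand = "+",
                      start = startPos, end = startPos + len - 1L)
    ncSel <- lnc[seq_len(nLnc) %% 2L == 1L]
    liSel <- setdiff(lnc, ncSel)
    annTab <- function(sel, prefix) {
      s <- asm[asm$gene_id %in% sel, ]
      s$gene_id <- paste0(prefix, s$gene_id)
      s
    }
    annotations <- list(
      PSEUDOGENE = NULL,
      NCRNA = .catalogFromTable(annTab(ncSel, "ann_nc_")),
      LINCRNA = .catalogFromTable(annTab(liSel, "ann_li_")),
      CODING = .catalogFromTable(annTab(genes, "ann_cd_")))

    ppi <- simulatePpiModules(nLnc, genesPerLnc, pWithin = 1, pBetween = 0,
                              genes = genes)
    goSim <- simulateGoTable(ppi$modules, background = genes,
                             termsPerModule = 1L, noiseRate = noiseRate)
    intended <- stats::setNames(goSim$moduleTerms, lnc)

    bundle <- list(dag = dag, cpds = cpds, lncIds = lnc, geneIds = genes,
                   expression = emis$values, levels = emis$levels,
                   assembled = .catalogFromTable(asm),
                   annotations = annotations[!vapply(annotations, is.null,
                                                     logical(1))],
                   ppi = ppi$graph, modules = ppi$modules, go = goSim$go,
                   goTable = goSim$table, intendedFunctions = intended,
                   seed = seed)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      f <- list(
        assembled = file.path(dir, "assembled.gtf"),
        ncrna = file.path(dir, "annot_ncrna.gtf"),
        lincrna = file.path(dir, "annot_lincrna.gtf"),
        coding = file.path(dir, "annot_coding.gtf"),
        pseudogene = file.path(dir, "annot_pseudogene.gtf"),
        fpkm = file.path(dir, "fpkm.tsv"),
        ppi = file.path(dir, "ppi.tsv"),
        go = file.path(dir, "go.tsv"),
        truth = file.path(dir, "truth.json"))
      writeGtf(bundle$assembled, f$assembled)
      writeGtf(bundle$annotations$NCRNA, f$ncrna)
      writeGtf(bundle$annotations$LINCRNA, f$lincrna)
      writeGtf(bundle$annotations$CODING, f$coding)
      writeLines(character(), f$pseudogene)
      writeExpressionMatrix(bundle$expression, f$fpkm)
      el <- igraph::as_edgelist(bundle$ppi)
      utils::write.table(el, f$ppi, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      utils::write.table(bundle$goTable, f$go, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      jsonlite::write_json(
        list(seed = seed, lncIds = lnc, geneIds = genes,
             modules = ppi$modules,
             trueEdges = dagEdges(dag),
             intendedFunctions = intended),
        f$truth, auto_unbox = TRUE, pretty = TRUE)
      bundle$files <- f
    }
    bundle
  })
}
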