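#' Default pipeline configuration
#'
#' One flat list holding every pipeline constant: presence filter
#' `min_samples = 50`, lncRNA length rule `min_lnc_length = 200` (exclusive),
#' overlap thresholds 0.90/0.90/0.90/0.60, discretization `ibreaks = 4` to
#' `target_levels = 2`, search `restarts = 10` / `perturbations = 5` /
#' `max_parents = 8`, cis window 100 kb, module minimum size 3 and enrichment
#' threshold 0.05. Path entries (`assembled_gtf`, `pseudogene_gtf`,
#' `ncrna_gtf`, `lincrna_gtf`, `coding_gtf`, `fpkm_tsv`, `ppi_tsv`, `go_tsv`,
#' optional `de_labels_tsv`, `out_dir`) must be filled in by the caller or
#' the config file.
#'
#' @param ... overrides of individual keys
#' @return named list
#' @export
lncfunConfig <- function(...) {
  cfg <- list(
    assembled_gtf = NULL, pseudogene_gtf = NULL, ncrna_gtf = NULL,
    lincrna_gtf = NULL, coding_gtf = NULL, fpkm_tsv = NULL, ppi_tsv = NULL,
    go_tsv = NULL, de_labels_tsv = NULL, out_dir = NULL,
    min_samples = 50L, min_fpkm = 0, min_lnc_length = 200L,
    overlap_pseudogene = 0.90, overlap_ncrna = 0.90, overlap_lincrna = 0.90,
    overlap_coding = 0.60,
    ibreaks = 4L, target_levels = 2L,
    restarts = 10L, perturbations = 5L, max_parents = 8L, seed = 1L,
    cis_window = 1e5, min_module = 3L, alpha = 0.05)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config key: ", unknown[1])
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with keys as in [lncfunConfig()]
#' @return named list
#' @export
readConfig <- function(path) {
  do.call(lncfunConfig, yaml::read_yaml(path))
}

.validateConfig <- function(cfg) {
  stopifnot(cfg$min_samples >= 0, cfg$min_lnc_length >= 0,
            cfg$ibreaks >= 2, cfg$target_levels >= 2,
            cfg$restarts >= 0, cfg$perturbations >= 1 || cfg$restarts == 0,
            cfg$max_parents >= 1, cfg$cis_window >= 0,
            cfg$min_module >= 2, cfg$alpha > 0, cfg$alpha <= 1)
  for (k in c("overlap_pseudogene", "overlap_ncrna", "overlap_lincrna",
              "overlap_coding"))
    stopifnot(cfg[[k]] >= 0, cfg[[k]] <= 1)
  need <- c("assembled_gtf", "ncrna_gtf", "coding_gtf", "fpkm_tsv",
            "ppi_tsv", "go_tsv", "out_dir")
  miss <- need[vapply(cfg[need], is.null, logical(1))]
  if (length(miss)) stop("config is missing: ", paste(miss, collapse = ", "))
  invisible(cfg)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full lncRNA function-prediction pipeline
#'
#' Executes classify, filter, discretize, learn, extract, stats and
#' predict in order, writing every intermediate in its standard format under
#' `cfg$out_dir` together with `manifest.json` (package version, seed,
#' config and its hash, per-stage gene accounting). Any stage failure aborts
#' with the stage name; intermediates written so far are preserved.
#'
#' @param cfg configuration list from [lncfunConfig()] or [readConfig()]
#' @return (invisibly) a list with the in-memory results: `catalog`,
#'   `lncIds`, `codingIds`, `expression`, `discrete`, `fit`, `network`,
#'   `stats`, `functions`, `manifest`
#' @export
runPipeline <- function(cfg) {
  .validateConfig(cfg)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  # --- classify ------------------------------------------------------
  res <- .stage("classify", {
    asm <- readGtf(cfg$assembled_gtf)
    annots <- list()
    if (!is.null(cfg$pseudogene_gtf) && file.exists(cfg$pseudogene_gtf))
      annots$PSEUDOGENE <- readGtf(cfg$pseudogene_gtf)
    annots$NCRNA <- readGtf(cfg$ncrna_gtf)
    if (!is.null(cfg$lincrna_gtf) && file.exists(cfg$lincrna_gtf))
      annots$LINCRNA <- readGtf(cfg$lincrna_gtf)
    annots$CODING <- readGtf(cfg$coding_gtf)
    thr <- c(PSEUDOGENE = cfg$overlap_pseudogene, NCRNA = cfg$overlap_ncrna,
             LINCRNA = cfg$overlap_lincrna, CODING = cfg$overlap_coding)
    catalog <- classifyCatalog(asm, annots, thresholds = thr)
    gd <- as.data.frame(geneData(catalog))
    utils::write.table(gd[, c("gene_id", "class", "exonic_length",
                              "best_overlap")],
                       file.path(out, "classes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    catalog
  })
  catalog <- res
  lnc <- selectLncRNAs(catalog, minLength = cfg$min_lnc_length)
  coding <- names(geneClasses(catalog))[geneClasses(catalog) == "CODING"]
  counts$classify <- list(genes_in = length(catalog),
                          lncRNAs = length(lnc), coding = length(coding))

  # --- filter --------------------------------------------------------
  expr <- .stage("filter", {
    m <- readExpressionMatrix(cfg$fpkm_tsv)
    m <- m[rownames(m) %in% c(lnc, coding), , drop = FALSE]
    nIn <- nrow(m)
    m <- presenceFilter(m, minSamples = cfg$min_samples,
                        minFpkm = cfg$min_fpkm)
    counts$filter <- list(genes_in = nIn, genes_kept = nrow(m),
                           genes_dropped = nIn - nrow(m))
    writeExpressionMatrix(m, file.path(out, "filtered.tsv"))
    m
  })

  # --- discretize ----------------------------------------------------
  disc <- .stage("discretize", {
    d <- discretizeExpression(expr, ibreaks = cfg$ibreaks,
                              target = cfg$target_levels)
    counts$discretize <- list(genes_in = nrow(expr), genes_kept = nrow(d),
                               genes_dropped = length(attr(d, "degenerate")))
    writeExpressionMatrix(d, file.path(out, "disc.tsv"))
    d
  })

  # --- learn ---------------------------------------------------------
  fit <- .stage("learn", {
    f <- hillClimb(disc, restarts = cfg$restarts,
                   perturbations = cfg$perturbations,
                   maxParents = cfg$max_parents, seed = cfg$seed)
    utils::write.table(dagEdges(f$dag), file.path(out, "dag.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts$learn <- list(variables = nrow(disc), edges = numEdges(f$dag),
                          score = f$score)
    f
  })

  # --- extract network ----------------------------------------------
  net <- .stage("network", {
    n <- extractNetwork(fit$dag, intersect(lnc, rownames(disc)),
                        intersect(coding, rownames(disc)))
    utils::write.table(networkEdges(n), file.path(out, "regnet.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    n
  })
  counts$network <- list(edges = nrow(networkEdges(net)))

  # --- stats ---------------------------------------------------------
  netStats <- .stage("stats", {
    degs <- degreeSummary(net)
    ct <- suppressWarnings(cisTrans(net, geneMidpoints(catalog),
                                    cisWindow = cfg$cis_window))
    s <- list(n_edges = nrow(networkEdges(net)),
              n_lnc_connected = length(degs$degrees),
              mean_lnc_degree = degs$mean, max_lnc_degree = degs$max,
              same_chrom_pairs = sum(ct$perLnc$same_chrom),
              cis_lnc_count = ct$cisLncCount,
              median_link_distance = if (length(ct$distances))
                stats::median(ct$distances) else NA)
    if (!is.null(cfg$de_labels_tsv) && file.exists(cfg$de_labels_tsv)) {
      lab <- utils::read.delim(cfg$de_labels_tsv, header = FALSE,
                               stringsAsFactors = FALSE)
      s$de_categories <- as.list(
        edgeDeCategories(net, stats::setNames(lab[[2]], lab[[1]])))
    }
    jsonlite::write_json(s, file.path(out, "stats.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    s
  })

  # --- predict -------------------------------------------------------
  fun <- .stage("predict", {
    ppi <- maxComponent(readPpi(cfg$ppi_tsv))
    bg0 <- intersect(coding, igraph::V(ppi)$name)
    go0 <- suppressMessages(readGoTable(cfg$go_tsv, background = bg0))
    annotated <- unique(unlist(termGenes(go0), use.names = FALSE))
    go <- GOAnnotation(termGenes(go0), background = annotated,
                       termNames = termNames(go0))
    res <- assignFunctions(net, ppi, go, minModule = cfg$min_module,
                           alpha = cfg$alpha)
    utils::write.table(res$assignments, file.path(out, "functions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$unannotated, file.path(out, "unannotated.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res
  })
  counts$predict <- list(
    lnc_in_network = length(unique(c(fun$assignments$lnc,
                                     fun$unannotated$lnc))),
    lnc_annotated = length(unique(fun$assignments$lnc)),
    lnc_unannotated = length(unique(fun$unannotated$lnc)))

  # --- manifest ------------------------------------------------------
  cfgJson <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                              null = "null")
  tmp <- tempfile(); writeLines(as.character(cfgJson), tmp)
  manifest <- list(
    package = "lncFunNet",
    version = as.character(utils::packageVersion("lncFunNet")),
    seed = cfg$seed, config = cfg, config_md5 = unname(tools::md5sum(tmp)),
    stage_counts = counts)
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(catalog = catalog, lncIds = lnc, codingIds = coding,
                 expression = expr, discrete = disc, fit = fit,
                 network = net, stats = netStats, functions = fun,
                 manifest = manifest))
}
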