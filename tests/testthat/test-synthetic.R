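test_that("random DAG simulation respects edge probability extremes", {
  none <- simulateDag(3, 5, edgeProb = 0, seed = 1)
  expect_equal(numEdges(none$dag), 0L)
  full <- simulateDag(2, 4, edgeProb = 1, maxParents = 10, seed = 2)
  k <- length(dagNodes(full$dag))
  expect_equal(numEdges(full$dag), k * (k - 1) / 2)
  expect_false(is.null(topologicalOrder(full$dag)))
  # seed determinism
  a <- simulateDag(3, 6, edgeProb = 0.3, seed = 9)
  b <- simulateDag(3, 6, edgeProb = 0.3, seed = 9)
  expect_identical(dagParents(a$dag), dagParents(b$dag))
  expect_identical(a$cpds, b$cpds)
})

test_that("epsilon CPTs depend on every declared parent", {
  sim <- simulateDag(2, 8, edgeProb = 0.5, epsilon = 0.1, seed = 21)
  for (v in dagNodes(sim$dag)) {
    cp <- sim$cpds[[v]]
    np <- length(cp$parents)
    if (np == 0) next
    pref <- apply(cp$prob, 1, which.max)
    for (bit in seq_len(np) - 1L) {
      cfg <- 0:(2^np - 1)
      expect_true(any(pref[cfg + 1] !=
                        pref[bitwXor(cfg, bitwShiftL(1L, bit)) + 1]))
    }
  }
})

test_that("expression emission tracks the sampled levels", {
  sim <- simulateDag(1, 3, edgeProb = 0.6, seed = 31)
  em <- simulateExpression(sim$dag, sim$cpds, 40,
                           levelMeans = c(2, 9), levelSd = 1e-9, seed = 32)
  expect_equal(unname(em$values),
               unname(matrix(c(2, 9)[em$levels + 1], nrow = nrow(em$levels))),
               tolerance = 1e-6)
  em2 <- simulateExpression(sim$dag, sim$cpds, 40,
                            levelMeans = c(2, 9), levelSd = 1e-9, seed = 32)
  expect_identical(em$values, em2$values)
  expect_true(all(em$values >= 0))
})

test_that("planted PPI graphs are connected for every seed", {
  for (seed in 1:10) {
    sim <- simulatePpiModules(4, 5, pWithin = 0.7, pBetween = 0, seed = seed)
    expect_equal(igraph::components(sim$graph)$no, 1L)
  }
  cliques <- simulatePpiModules(2, 6, pWithin = 1, pBetween = 0, seed = 1)
  for (mod in cliques$modules) {
    sub <- igraph::induced_subgraph(cliques$graph, mod)
    expect_equal(igraph::ecount(sub), choose(length(mod), 2))
  }
})

test_that("GO simulation plants exact, significantly enriched terms", {
  sim <- simulatePpiModules(3, 6, pWithin = 1, pBetween = 0, seed = 41)
  bg <- unlist(sim$modules)
  noiseless <- simulateGoTable(sim$modules, bg, noiseRate = 0, seed = 42)
  for (i in seq_along(sim$modules)) {
    term <- noiseless$moduleTerms[[i]]
    expect_setequal(termGenes(noiseless$go)[[term]], sim$modules[[i]])
    enr <- hypergeomEnrich(sim$modules[[i]], noiseless$go, alpha = 0.05)
    expect_true(term %in% enr$term)
  }
  t1 <- simulateGoTable(sim$modules, bg, noiseRate = 0.1, seed = 5)
  t2 <- simulateGoTable(sim$modules, bg, noiseRate = 0.1, seed = 5)
  expect_identical(t1$table, t2$table)
})

test_that("the GTF fixture forces every classification rule", {
  fx <- gtfClassificationFixture()
  cc <- classifyCatalog(fx$assembled, fx$annotations)
  expect_equal(sort(unname(geneClasses(cc))),
               sort(unname(fx$expectedClasses)))
  expect_setequal(selectLncRNAs(cc), fx$expectedLnc)
  # round-trip through GTF files preserves the classes
  dir <- tempfile(); dir.create(dir)
  writeGtf(fx$assembled, file.path(dir, "asm.gtf"))
  for (nm in names(fx$annotations))
    writeGtf(fx$annotations[[nm]], file.path(dir, paste0(nm, ".gtf")))
  asm2 <- readGtf(file.path(dir, "asm.gtf"))
  ann2 <- lapply(names(fx$annotations), function(nm)
    readGtf(file.path(dir, paste0(nm, ".gtf"))))
  names(ann2) <- names(fx$annotations)
  cc2 <- classifyCatalog(asm2, ann2)
  expect_equal(geneClasses(cc2)[names(fx$expectedClasses)],
               fx$expectedClasses)
})

test_that("the full bundle is seed-deterministic and self-consistent", {
  b1 <- simulateBundle(seed = 77)
  b2 <- simulateBundle(seed = 77)
  expect_identical(b1$expression, b2$expression)
  expect_identical(b1$goTable, b2$goTable)
  expect_identical(dagParents(b1$dag), dagParents(b2$dag))

  # planted truths line up: each lncRNA's children are its PPI module
  for (i in seq_along(b1$lncIds)) {
    children <- dagEdges(b1$dag)
    kids <- children$to[children$from == b1$lncIds[i]]
    expect_setequal(kids, b1$modules[[i]])
  }
  expect_equal(igraph::components(b1$ppi)$no, 1L)
  # every gene is expressed in nearly all samples (presence filter passes)
  keep <- presenceFilter(b1$expression, minSamples = 50)
  expect_equal(nrow(keep), nrow(b1$expression))
})
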