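pathGraph <- function(edges) {
  igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE)
}

test_that("shortest paths route through the whole network", {
  g <- pathGraph(cbind(c("a", "b"), c("b", "c")))
  d <- shortestPathDistances(c("a", "c"), g)
  expect_equal(d["a", "c"], 2)            # through b, outside the query set
  expect_equal(diag(d), c(a = 0, c = 0))
  # adjacent pair
  expect_equal(shortestPathDistances(c("a", "b"), g)["a", "b"], 1)
  # 5-cycle: opposite nodes at distance 2
  cyc <- pathGraph(cbind(c("n1", "n2", "n3", "n4", "n5"),
                         c("n2", "n3", "n4", "n5", "n1")))
  expect_equal(shortestPathDistances(c("n1", "n3"), cyc)["n1", "n3"], 2)
  # unmapped genes dropped with warning; a lone survivor is flagged
  expect_warning(d1 <- shortestPathDistances(c("a", "zz"), g), "absent")
  expect_equal(attr(d1, "reason"), "no module possible")
})

test_that("distance matrices from a connected PPI are metric", {
  sim <- simulatePpiModules(3, 4, pWithin = 0.8, pBetween = 0.1, seed = 3)
  genes <- igraph::V(sim$graph)$name
  d <- shortestPathDistances(genes, sim$graph)
  expect_equal(d, t(d))
  expect_true(all(is.finite(d)))
  for (k in seq_along(genes))
    expect_true(all(d <= outer(d[, k], d[k, ], "+") + 1e-9))
})

test_that("average linkage matches hand-computed and oracle heights", {
  dm2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  h2 <- averageLinkage(dm2)
  expect_equal(h2$height, 3)

  # three equidistant genes: both merges at the same height
  dm3 <- matrix(2, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(dm3) <- 0
  h3 <- averageLinkage(dm3)
  expect_equal(h3$height, c(2, 2))

  # 6-gene two-block matrix: last merge at the between-block distance
  ids <- paste0("g", 1:6)
  dm6 <- matrix(4, 6, 6, dimnames = list(ids, ids))
  dm6[1:3, 1:3] <- 1; dm6[4:6, 4:6] <- 1; diag(dm6) <- 0
  h6 <- averageLinkage(dm6)
  expect_equal(max(h6$height), 4)
  expect_equal(sort(h6$height), sort(oracleUpgma(dm6)), tolerance = 1e-10)
})

test_that("average linkage equals the naive oracle on random instances", {
  set.seed(61)
  for (rep in 1:8) {
    n <- sample(4:12, 1)
    g <- igraph::sample_gnp(n + 6, 0.4)
    while (igraph::components(g)$no > 1) g <- igraph::sample_gnp(n + 6, 0.4)
    igraph::V(g)$name <- paste0("v", seq_len(n + 6))
    genes <- paste0("v", seq_len(n))
    dm <- shortestPathDistances(genes, g)
    h <- averageLinkage(dm)
    expect_equal(h$height, oracleUpgma(dm), tolerance = 1e-10)
    expect_true(all(diff(h$height) >= -1e-10))   # monotone heights
  }
})

test_that("tree cutting extracts planted modules and respects minSize", {
  sim <- simulatePpiModules(2, 6, pWithin = 1, pBetween = 0, seed = 5)
  genes <- unlist(sim$modules)
  d <- shortestPathDistances(genes, sim$graph)
  cut <- treeCutModules(averageLinkage(d), minSize = 3)
  expect_equal(length(cut$modules), 2L)
  expect_setequal(cut$modules[[1]], sim$modules[[1]])
  expect_setequal(cut$modules[[2]], sim$modules[[2]])
  expect_false(anyNA(cut$assignment))

  # all genes mutually adjacent: one module
  dm <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(dm) <- 0
  one <- treeCutModules(averageLinkage(dm), minSize = 3)
  expect_equal(length(one$modules), 1L)
  expect_setequal(one$modules[[1]], letters[1:4])

  # two genes cannot meet minSize = 3
  dm2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  none <- treeCutModules(averageLinkage(dm2), minSize = 3)
  expect_equal(length(none$modules), 0L)
  expect_true(all(is.na(none$assignment)))
  expect_error(treeCutModules(averageLinkage(dm2), minSize = 1), "minSize")
})

test_that("raising minSize never increases the module count", {
  sim <- simulatePpiModules(3, 5, pWithin = 0.9, pBetween = 0.05, seed = 8)
  d <- shortestPathDistances(unlist(sim$modules), sim$graph)
  dend <- averageLinkage(d)
  counts <- vapply(2:6, function(ms)
    length(treeCutModules(dend, minSize = ms)$modules), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("hypergeometric p-values match the exact tail sum", {
  bg <- paste0("g", 1:10)
  go <- GOAnnotation(list(T1 = c("g1", "g2")), background = bg)
  res <- hypergeomEnrich(c("g1", "g2"), go, alpha = 0.05)
  expect_equal(res$p_value, 1 / 45, tolerance = 1e-12)

  # k = 0 gives p = 1; a term covering the background gives p = 1
  go2 <- GOAnnotation(list(T1 = c("g1", "g2"), T2 = bg), background = bg)
  all2 <- hypergeomEnrich(c("g3", "g4"), go2, alpha = 1.1)
  expect_true(all(abs(all2$p_value - 1) < 1e-12))

  # random tuples against the choose() oracle
  set.seed(71)
  for (rep in 1:200) {
    N <- sample(5:60, 1); K <- sample(1:N, 1)
    m <- sample(1:N, 1); k <- sample(0:min(m, K), 1)
    p <- stats::phyper(k - 1, K, N - K, m, lower.tail = FALSE)
    expect_equal(p, oracleHyperTail(N, K, m, k), tolerance = 1e-12)
  }
})

test_that("enrichment is invariant under gene relabeling", {
  bg <- paste0("g", 1:20)
  go <- GOAnnotation(list(T1 = bg[1:5], T2 = bg[6:12]), background = bg)
  res <- hypergeomEnrich(bg[c(1:4, 7)], go, alpha = 1.1)
  perm <- setNames(sample(bg), bg)   # relabel every gene
  go2 <- GOAnnotation(lapply(termGenes(go), function(g) unname(perm[g])),
                      background = unname(perm))
  res2 <- hypergeomEnrich(unname(perm[bg[c(1:4, 7)]]), go2, alpha = 1.1)
  expect_equal(res$p_value[order(res$term)], res2$p_value[order(res2$term)],
               tolerance = 1e-12)
})

test_that("function assignment recovers a planted module end to end", {
  sim <- simulatePpiModules(3, 6, pWithin = 1, pBetween = 0, seed = 12)
  goSim <- simulateGoTable(sim$modules,
                           background = unlist(sim$modules),
                           noiseRate = 0, seed = 13)
  dag <- DiscreteDAG(c("L1", "L2", unlist(sim$modules)),
                     c(setNames(lapply(sim$modules[[1]], function(g) "L1"),
                                sim$modules[[1]]),
                       list(L2 = sim$modules[[2]][1])))
  net <- extractNetwork(dag, c("L1", "L2"), unlist(sim$modules))
  res <- assignFunctions(net, sim$graph, goSim$go, minModule = 3)
  # L1: six linked genes forming one planted module -> its term
  expect_equal(res$assignments$lnc, "L1")
  expect_equal(res$assignments$term, goSim$moduleTerms[[1]])
  # L2 has a single linked gene -> no module
  expect_equal(res$unannotated$lnc, "L2")
  expect_equal(res$unannotated$reason, "no module")
})
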