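mkNet <- function(edges, lnc = c("L1", "L2"), coding = c("G1", "G2", "G3")) {
  dag <- DiscreteDAG(c(lnc, coding), edges)
  extractNetwork(dag, lnc, coding)
}

test_that("network extraction keeps exactly lncRNA-incident edges", {
  net <- mkNet(list(G1 = "L1", G2 = "G1"))   # L1->G1, G1->G2
  e <- networkEdges(net)
  expect_equal(nrow(e), 1L)
  expect_equal(e$from, "L1"); expect_equal(e$to, "G1")
  expect_equal(linkedGenes(net, "L1"), "G1")

  # direction-agnostic linkage
  net2 <- mkNet(list(L1 = "G1"))
  expect_equal(linkedGenes(net2, "L1"), "G1")

  # no lncRNA-incident edge -> empty network
  net3 <- mkNet(list(G2 = "G1"))
  expect_equal(nrow(networkEdges(net3)), 0L)

  expect_error(extractNetwork(DiscreteDAG(c("a", "b")), "a", c("a", "b")),
               "overlap")
})

test_that("lncRNA-lncRNA edges are kept but never contribute linked genes", {
  net <- mkNet(list(L2 = "L1", G1 = "L1"))
  expect_equal(nrow(networkEdges(net)), 2L)
  expect_equal(linkedGenes(net, "L1"), "G1")
  expect_equal(linkedGenes(net, "L2"), character())
})

test_that("degree summary counts both directions", {
  net <- mkNet(list(G1 = "L1", G2 = "L1", L1 = "G3", G3 = "L2"))
  ds <- degreeSummary(net)
  expect_equal(unname(ds$degrees[c("L1", "L2")]), c(3L, 1L))
  expect_equal(ds$mean, 2)
  expect_equal(ds$max, 3L)
  empty <- mkNet(list(G2 = "G1"))
  expect_true(degreeSummary(empty)$empty)
  expect_equal(degreeSummary(empty)$mean, 0)
})

test_that("cis/trans distances use midpoints with an inclusive window", {
  coords <- data.frame(
    gene_id = c("L1", "G1", "G2", "G3"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    midpoint = c(1e6, 1.05e6, 1.1e6, 1e6))
  net <- mkNet(list(G1 = "L1", G2 = "L1", G3 = "L1"),
               lnc = "L1", coding = c("G1", "G2", "G3"))
  ct <- cisTrans(net, coords)
  expect_equal(ct$perLnc$linked, 3L)
  expect_equal(ct$perLnc$same_chrom, 2L)   # G3 on another chromosome
  expect_setequal(ct$distances, c(5e4, 1e5))
  expect_equal(ct$perLnc$cis, 2L)          # exactly 100 kb counts as cis
  expect_equal(ct$cisLncCount, 1L)
  # uniform per-chromosome shift leaves the profile unchanged
  shifted <- coords
  shifted$midpoint <- shifted$midpoint + ifelse(shifted$chrom == "chr1",
                                                7e6, 3e6)
  expect_equal(cisTrans(net, shifted)$distances, ct$distances)
})

test_that("DE edge categories partition the edge set", {
  net <- mkNet(list(G1 = "L1", G2 = "L1", G3 = "L2", L2 = "L1"))
  labels <- c(L1 = "up", L2 = "down", G1 = "up", G2 = "down", G3 = "up")
  cats <- edgeDeCategories(net, labels)
  expect_equal(sum(cats), nrow(networkEdges(net)))
  expect_equal(unname(cats["up_up"]), 1L)     # L1 - G1
  expect_equal(unname(cats["up_down"]), 1L)   # L1 - G2
  expect_equal(unname(cats["down_up"]), 1L)   # L2 - G3
  expect_equal(unname(cats["other"]), 1L)     # the lncRNA-lncRNA edge
  # ns endpoints fall into other; unlabeled nodes default to ns
  cats2 <- edgeDeCategories(net, c(L1 = "ns"))
  expect_equal(unname(cats2["other"]), 4L)
  expect_error(edgeDeCategories(net, c(L1 = "higher")), "unknown")
})

test_that("nearest coding neighbors break ties lexicographically", {
  lnc <- data.frame(gene_id = c("L1", "L2"), chrom = c("chr1", "chr9"),
                    midpoint = c(300, 100))
  cod <- data.frame(gene_id = c("G1", "G2", "G3"),
                    chrom = "chr1", midpoint = c(100, 900, 500))
  expect_warning(nn <- nearestNeighborGenes(lnc, cod), "skipped")
  expect_equal(nn[["L1"]], "G1")
  expect_false("L2" %in% names(nn))
  # equidistant -> smaller id
  tie <- data.frame(gene_id = c("Gb", "Ga"), chrom = "chr1",
                    midpoint = c(200, 400))
  nn2 <- nearestNeighborGenes(lnc[1, ], tie)
  expect_equal(nn2[["L1"]], "Ga")
})

test_that("network extraction is idempotent through a DAG round-trip", {
  net <- mkNet(list(G1 = "L1", G2 = "G1", L2 = "G2"))
  e <- networkEdges(net)
  dag2 <- DiscreteDAG(c("L1", "L2", "G1", "G2", "G3"),
                      split(e$from, e$to))
  net2 <- extractNetwork(dag2, c("L1", "L2"), c("G1", "G2", "G3"))
  expect_equal(sort(paste(networkEdges(net2)$from, networkEdges(net2)$to)),
               sort(paste(e$from, e$to)))
})
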