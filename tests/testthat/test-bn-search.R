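test_that("legal moves respect acyclicity and parent bounds", {
  empty2 <- DiscreteDAG(c("a", "b"))
  mv <- legalMoves(empty2)
  expect_equal(mv$type, c("ADD", "ADD"))
  expect_setequal(paste(mv$from, mv$to), c("a b", "b a"))

  chain <- DiscreteDAG(c("a", "b", "c"), list(b = "a", c = "b"))
  mv2 <- legalMoves(chain)
  expect_true(any(mv2$type == "REVERSE" & mv2$from == "a" & mv2$to == "b"))
  expect_false(any(mv2$type == "ADD" & mv2$from == "c" & mv2$to == "a"))
  expect_true(any(mv2$type == "ADD" & mv2$from == "a" & mv2$to == "c"))

  empty3 <- DiscreteDAG(c("a", "b", "c"))
  expect_equal(sum(legalMoves(empty3)$type == "ADD"), 6L)
  # maxParents = 0 forbids every addition
  expect_equal(nrow(legalMoves(empty3, maxParents = 0)), 0L)
  # blacklist removes the pair
  bl <- data.frame(from = "a", to = "b")
  expect_false(any(with(legalMoves(empty3, blacklist = bl),
                        type == "ADD" & from == "a" & to == "b")))
})

test_that("hill climbing finds the exhaustive optimum on small problems", {
  # independent fair variables: the empty graph wins
  set.seed(51)
  ind <- matrix(sample(0:1, 2 * 200, replace = TRUE), nrow = 2,
                dimnames = list(c("a", "b"), NULL))
  fit <- hillClimb(ind, restarts = 3, perturbations = 2, seed = 1)
  expect_equal(numEdges(fit$dag), 0L)
  expect_equal(fit$score, exhaustiveSearch(ind)$score, tolerance = 1e-10)

  # deterministic copy: exactly one edge, either orientation
  x <- sample(0:1, 200, replace = TRUE)
  cp <- rbind(a = x, b = x)
  fit2 <- hillClimb(cp, restarts = 3, perturbations = 2, seed = 1)
  expect_equal(numEdges(fit2$dag), 1L)
  expect_equal(fit2$score, exhaustiveSearch(cp)$score, tolerance = 1e-10)

  # 3-variable chain with strong dependencies
  a <- sample(0:1, 500, replace = TRUE)
  b <- ifelse(runif(500) < 0.1, 1L - a, a)
  c <- ifelse(runif(500) < 0.1, 1L - b, b)
  ch <- rbind(a = a, b = b, c = c)
  fit3 <- hillClimb(ch, restarts = 5, perturbations = 3, seed = 1)
  expect_equal(fit3$score, exhaustiveSearch(ch)$score, tolerance = 1e-10)
})

test_that("the climb never returns less than the empty-graph score", {
  set.seed(52)
  d <- matrix(sample(0:1, 4 * 100, replace = TRUE), nrow = 4,
              dimnames = list(letters[1:4], NULL))
  fit <- hillClimb(d, restarts = 2, perturbations = 3, seed = 9)
  expect_gte(fit$score, bicScore(DiscreteDAG(letters[1:4]), d) - 1e-12)
  expect_equal(fit$score, bicScore(fit$dag, d), tolerance = 1e-10)
  # the result is a valid DAG
  expect_false(is.null(topologicalOrder(fit$dag)))
})

test_that("hill climbing is reproducible for a fixed seed", {
  set.seed(53)
  d <- matrix(sample(0:1, 5 * 150, replace = TRUE), nrow = 5,
              dimnames = list(letters[1:5], NULL))
  f1 <- hillClimb(d, restarts = 4, perturbations = 4, seed = 99)
  f2 <- hillClimb(d, restarts = 4, perturbations = 4, seed = 99)
  expect_identical(dagParents(f1$dag), dagParents(f2$dag))
  expect_identical(f1$score, f2$score)
})

test_that("blacklisted edges never appear in the learned graph", {
  set.seed(54)
  x <- sample(0:1, 300, replace = TRUE)
  y <- ifelse(runif(300) < 0.05, 1L - x, x)
  d <- rbind(a = x, b = y)
  bl <- data.frame(from = "a", to = "b")
  fit <- hillClimb(d, restarts = 2, perturbations = 2, seed = 3,
                   blacklist = bl)
  e <- dagEdges(fit$dag)
  expect_false(any(e$from == "a" & e$to == "b"))
  expect_true(any(e$from == "b" & e$to == "a"))   # the other orientation
})

test_that("ancestral sampling honors CPDs, order and seed", {
  dag <- DiscreteDAG(c("p", "c"), list(c = "p"))
  cpds <- list(p = c(0.3, 0.7),
               c = list(parents = "p",
                        prob = rbind(c(1, 0), c(0, 1))))
  s <- sampleFromNetwork(dag, cpds, 500, seed = 5)
  expect_equal(s["c", ], s["p", ])   # deterministic copy CPD
  expect_identical(s, sampleFromNetwork(dag, cpds, 500, seed = 5))

  # root marginal within 3 binomial SEs
  big <- sampleFromNetwork(dag, cpds, 10000, seed = 6)
  p1 <- mean(big["p", ] == 1)
  expect_lt(abs(p1 - 0.7), 3 * sqrt(0.3 * 0.7 / 10000))

  badCpd <- list(p = c(0.5, 0.6),
                 c = list(parents = "p", prob = rbind(c(1, 0), c(0, 1))))
  expect_error(sampleFromNetwork(dag, badCpd, 10), "distributions")
})

test_that("single moves change the score by exactly the family deltas", {
  set.seed(55)
  d <- matrix(sample(0:1, 4 * 120, replace = TRUE), nrow = 4,
              dimnames = list(letters[1:4], NULL))
  g0 <- DiscreteDAG(letters[1:4], list(b = "a", c = c("a", "b")))
  base <- bicScore(g0, d)
  # ADD d -> c
  g1 <- DiscreteDAG(letters[1:4], list(b = "a", c = c("a", "b", "d")))
  delta <- familyScore("c", c("a", "b", "d"), d)$bic -
    familyScore("c", c("a", "b"), d)$bic
  expect_equal(bicScore(g1, d) - base, delta, tolerance = 1e-10)
  # REVERSE a -> b
  g2 <- DiscreteDAG(letters[1:4], list(a = "b", c = c("a", "b")))
  delta2 <- (familyScore("b", character(), d)$bic -
             familyScore("b", "a", d)$bic) +
            (familyScore("a", "b", d)$bic -
             familyScore("a", character(), d)$bic)
  expect_equal(bicScore(g2, d) - base, delta2, tolerance = 1e-10)
})
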