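# Discrete BIC family scores.
#
# Data convention throughout: an integer genes-by-samples matrix of 0-based
# levels, with rownames = variable ids. Level counts come from the `nLevels`
# attribute when present, otherwise from the data (never below 2, so that a
# binary variable observed at a single level still counts one free
# parameter).

.dataLevels <- function(data, nLevels = NULL) {
  if (is.null(nLevels)) nLevels <- attr(data, "nLevels")
  if (is.null(nLevels))
    nLevels <- stats::setNames(pmax(apply(data, 1, max) + 1L, 2L),
                               rownames(data))
  nLevels
}

# Parent-configuration index (0-based) for each sample; first parent varies
# slowest. Parents taken in the order given.
.configIndex <- function(parents, data, nLevels) {
  idx <- integer(ncol(data))
  for (p in parents) idx <- idx * nLevels[[p]] + data[p, ]
  idx
}

#' BIC family score of one variable given a parent set
#'
#' The local term of the decomposable BIC network score for discrete data:
#' maximized log likelihood \eqn{\sum_{j,k} N_{jk} \ln(N_{jk}/N_{j\cdot})}
#' over parent configurations j and child levels k (0 ln 0 = 0), penalized by
#' \eqn{(d_i/2)\ln n} with \eqn{d_i = (r_i - 1) q_i} free parameters, where
#' \eqn{r_i} is the child's level count and \eqn{q_i} the number of parent
#' level configurations. Natural logarithms throughout.
#'
#' @param var variable id (a rowname of `data`)
#' @param parents character vector of parent ids, excluding `var`
#' @param data integer genes-by-samples level matrix
#' @param nLevels optional named level counts (see details above)
#' @return list with `var`, `parents`, `loglik`, `d`, `bic`
#' @export
familyScore <- function(var, parents, data, nLevels = NULL) {
  ids <- c(var, parents)
  if (!all(ids %in% rownames(data)))
    stop("unknown variable id: ", setdiff(ids, rownames(data))[1])
  if (var %in% parents) stop("a variable cannot be its own parent")
  nLevels <- .dataLevels(data, nLevels)
  r <- nLevels[[var]]
  q <- if (length(parents)) prod(nLevels[parents]) else 1
  n <- ncol(data)
  cell <- .configIndex(parents, data, nLevels) * r + data[var, ] + 1L
  cnt <- matrix(tabulate(cell, nbins = q * r), nrow = r)  # r x q
  nj <- colSums(cnt)
  nz <- cnt > 0
  ll <- sum(cnt[nz] * log(cnt[nz] / rep(nj, each = r)[nz]))
  d <- (r - 1) * q
  list(var = var, parents = sort(parents), loglik = ll, d = d,
       bic = ll - d / 2 * log(n))
}

# Cached local BIC; cache is an environment keyed by "var|p1,p2,...".
.familyBic <- function(var, parents, data, nLevels, cache = NULL) {
  if (is.null(cache)) return(familyScore(var, parents, data, nLevels)$bic)
  key <- paste0(var, "|", paste(sort(parents), collapse = ","))
  val <- cache[[key]]
  if (is.null(val)) {
    val <- familyScore(var, parents, data, nLevels)$bic
    cache[[key]] <- val
  }
  val
}

#' BIC score of a DAG
#'
#' Decomposable network score: the sum over variables of their
#' [familyScore()] local BIC terms, equal to the maximized log likelihood of
#' the factorized joint distribution minus \eqn{(d/2)\ln n} with d the total
#' free-parameter count.
#'
#' @param dag a \linkS4class{DiscreteDAG} over the rownames of `data`
#' @param data integer genes-by-samples level matrix
#' @param nLevels optional named level counts
#' @return a single number (natural-log scale)
#' @export
bicScore <- function(dag, data, nLevels = NULL) {
  nLevels <- .dataLevels(data, nLevels)
  sum(vapply(dag@nodes, function(v)
    familyScore(v, dag@parents[[v]], data, nLevels)$bic, numeric(1)))
}

#' Exhaustively score every DAG over a small variable set
#'
#' Enumerates all directed graphs over the variables (feasible for up to 4),
#' filters to the acyclic ones, and returns the best BIC score and one
#' maximizing DAG. Intended as the ground-truth optimum for validating the
#' heuristic search on small problems.
#'
#' @param data integer genes-by-samples level matrix with <= 4 rows
#' @param nLevels optional named level counts
#' @return list with `score`, `dag` (a \linkS4class{DiscreteDAG}) and
#'   `nDags`, the number of DAGs enumerated
#' @export
exhaustiveSearch <- function(data, nLevels = NULL) {
  vars <- rownames(data)
  k <- length(vars)
  if (k > 4L) stop("exhaustive enumeration is limited to 4 variables")
  nLevels <- .dataLevels(data, nLevels)
  pairs <- expand.grid(from = seq_len(k), to = seq_len(k))
  pairs <- pairs[pairs$from != pairs$to, ]
  m <- nrow(pairs)
  cache <- new.env(parent = emptyenv())
  best <- -Inf; bestDag <- NULL; nDags <- 0L
  for (mask in 0:(2^m - 1)) {
    sel <- bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L
    pa <- lapply(seq_len(k), function(j)
      vars[pairs$from[sel & pairs$to == j]])
    names(pa) <- vars
    # acyclicity by Kahn's algorithm on the small graph
    indeg <- lengths(pa); order <- 0L; active <- rep(TRUE, k)
    repeat {
      src <- which(active & vapply(vars, function(v)
        !any(pa[[v]] %in% vars[active]), logical(1)))
      if (!length(src)) break
      active[src] <- FALSE; order <- order + length(src)
    }
    if (order < k) next
    nDags <- nDags + 1L
    sc <- sum(vapply(vars, function(v)
      .familyBic(v, pa[[v]], data, nLevels, cache), numeric(1)))
    if (sc > best) { best <- sc; bestDag <- pa }
  }
  list(score = best, dag = DiscreteDAG(vars, bestDag), nDags = nDags)
}
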