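# Greedy hill-climbing structure search with random restarts.
#
# The search state is kept in plain index space (variables sorted by id, so
# lexicographic tie-breaking equals index order): an adjacency matrix A,
# per-node parent index lists, the per-family BIC vector fs, and a matrix of
# ADD-move deltas that is refreshed only for the columns whose family
# changed. Family scores are memoized across the whole run (including
# restarts) in an environment keyed by (variable, sorted parent set).

.reachMatrix <- function(A) {
  R <- A
  repeat {
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) return(R)
    R <- R2
  }
}

# BFS from `from` over A with edge from->drop removed; TRUE if `to` reached.
.pathExistsWithout <- function(A, from, to, dropTo) {
  Arow <- A
  Arow[from, dropTo] <- FALSE
  seen <- logical(nrow(A))
  queue <- from
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    nb <- which(Arow[v, ] & !seen)
    if (to %in% nb) return(TRUE)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  FALSE
}

#' Legal structure moves of a DAG
#'
#' All single-edge moves (ADD, DELETE, REVERSE) that keep the graph acyclic,
#' respect `maxParents`, and avoid blacklisted directed edges (a blacklisted
#' pair can be neither added nor created by a reversal). Rows are ordered
#' lexicographically by (type ADD < DELETE < REVERSE, source id, target id).
#'
#' @param dag a \linkS4class{DiscreteDAG}
#' @param maxParents parent-set size bound
#' @param blacklist optional data.frame of forbidden directed edges
#'   (columns `from`, `to`)
#' @return data.frame with columns `type`, `from`, `to`
#' @export
legalMoves <- function(dag, maxParents = Inf, blacklist = NULL) {
  vars <- sort(dag@nodes)
  N <- length(vars)
  A <- matrix(FALSE, N, N, dimnames = list(vars, vars))
  for (v in dag@nodes) for (p in dag@parents[[v]]) A[p, v] <- TRUE
  black <- matrix(FALSE, N, N, dimnames = list(vars, vars))
  if (!is.null(blacklist) && nrow(blacklist))
    black[cbind(match(blacklist$from, vars), match(blacklist$to, vars))] <- TRUE
  R <- .reachMatrix(A * 1) > 0
  npar <- colSums(A)
  addOk <- !A & !t(R) & !black &
    matrix(npar < maxParents, N, N, byrow = TRUE)
  diag(addOk) <- FALSE
  edges <- which(t(A))   # from-major order
  out <- list()
  idx <- which(t(addOk))
  out$add <- data.frame(type = rep("ADD", length(idx)),
                        from = vars[(idx - 1) %/% N + 1],
                        to = vars[(idx - 1) %% N + 1])
  ef <- (edges - 1) %/% N + 1; et <- (edges - 1) %% N + 1
  out$del <- data.frame(type = rep("DELETE", length(ef)),
                        from = vars[ef], to = vars[et])
  revOk <- vapply(seq_along(ef), function(i)
    npar[ef[i]] < maxParents && !black[et[i], ef[i]] &&
      !.pathExistsWithout(A, ef[i], et[i], et[i]),
    logical(1))
  out$rev <- data.frame(type = rep("REVERSE", sum(revOk)),
                        from = vars[ef[revOk]], to = vars[et[revOk]])
  do.call(rbind, out)
}

# One full greedy climb from state `st`; mutates and returns the state.
# st: list(A, pa [list of integer vectors], fs, deltaAdd, npar)
.climb <- function(st, data, vars, nLevels, cache, maxParents, black,
                   protect, tol = 1e-10) {
  N <- length(vars)
  repeat {
    R <- .reachMatrix(st$A * 1) > 0
    addOk <- !st$A & !t(R) & !black &
      matrix(st$npar < maxParents, N, N, byrow = TRUE)
    diag(addOk) <- FALSE
    bestDelta <- tol; best <- NULL
    if (any(addOk)) {
      da <- ifelse(addOk, st$deltaAdd, -Inf)
      mx <- max(da)
      if (mx > bestDelta) {
        idx <- which(t(da) >= mx - 1e-12)[1]   # lexicographic (from, to)
        bestDelta <- mx
        best <- list(type = "ADD", from = (idx - 1) %/% N + 1,
                     to = (idx - 1) %% N + 1)
      }
    }
    eidx <- which(t(st$A))
    ef <- (eidx - 1) %/% N + 1; et <- (eidx - 1) %% N + 1
    for (i in seq_along(ef)) {
      x <- ef[i]; y <- et[i]
      if (protect[x, y]) next
      dDel <- .familyBic(vars[y], vars[setdiff(st$pa[[y]], x)],
                         data, nLevels, cache) - st$fs[y]
      if (dDel > bestDelta + 1e-12) {
        bestDelta <- dDel
        best <- list(type = "DELETE", from = x, to = y)
      }
      dRev <- dDel + st$deltaAdd[y, x]
      if (dRev > bestDelta + 1e-12 && st$npar[x] < maxParents &&
          !black[y, x] && !.pathExistsWithout(st$A, x, y, y)) {
        bestDelta <- dRev
        best <- list(type = "REVERSE", from = x, to = y, dDel = dDel)
      }
    }
    if (is.null(best)) return(st)
    st <- .applyMove(st, best, data, vars, nLevels, cache)
  }
}

.refreshAddColumn <- function(st, y, data, vars, nLevels, cache) {
  N <- length(vars)
  pay <- vars[st$pa[[y]]]
  col <- rep(NA_real_, N)
  for (x in seq_len(N)) {
    if (x == y || st$A[x, y]) { col[x] <- -Inf; next }
    col[x] <- .familyBic(vars[y], c(pay, vars[x]), data, nLevels, cache) -
      st$fs[y]
  }
  st$deltaAdd[, y] <- col
  st
}

.applyMove <- function(st, mv, data, vars, nLevels, cache) {
  x <- mv$from; y <- mv$to
  touched <- y
  if (mv$type == "ADD") {
    st$A[x, y] <- TRUE
    st$pa[[y]] <- c(st$pa[[y]], x)
    st$npar[y] <- st$npar[y] + 1L
  } else if (mv$type == "DELETE") {
    st$A[x, y] <- FALSE
    st$pa[[y]] <- setdiff(st$pa[[y]], x)
    st$npar[y] <- st$npar[y] - 1L
  } else {
    st$A[x, y] <- FALSE; st$A[y, x] <- TRUE
    st$pa[[y]] <- setdiff(st$pa[[y]], x)
    st$pa[[x]] <- c(st$pa[[x]], y)
    st$npar[y] <- st$npar[y] - 1L
    st$npar[x] <- st$npar[x] + 1L
    touched <- c(y, x)
  }
  for (t in touched) {
    st$fs[t] <- .familyBic(vars[t], vars[st$pa[[t]]], data, nLevels, cache)
    st <- .refreshAddColumn(st, t, data, vars, nLevels, cache)
  }
  st
}

.freshState <- function(parents, data, vars, nLevels, cache) {
  N <- length(vars)
  A <- matrix(FALSE, N, N)
  pa <- rep(list(integer()), N)
  for (v in seq_len(N)) {
    pa[[v]] <- match(parents[[vars[v]]], vars)
    if (length(pa[[v]])) A[cbind(pa[[v]], v)] <- TRUE
  }
  fs <- vapply(seq_len(N), function(v)
    .familyBic(vars[v], vars[pa[[v]]], data, nLevels, cache), numeric(1))
  st <- list(A = A, pa = pa, fs = fs, npar = colSums(A),
             deltaAdd = matrix(-Inf, N, N))
  for (y in seq_len(N))
    st <- .refreshAddColumn(st, y, data, vars, nLevels, cache)
  st
}

# k random legal moves applied to the state (uses the current RNG stream).
.perturb <- function(st, k, data, vars, nLevels, cache, maxParents, black,
                     protect) {
  N <- length(vars)
  for (i in seq_len(k)) {
    R <- .reachMatrix(st$A * 1) > 0
    addOk <- !st$A & !t(R) & !black &
      matrix(st$npar < maxParents, N, N, byrow = TRUE)
    diag(addOk) <- FALSE
    adds <- which(addOk)
    dels <- which(st$A & !protect)
    eidx <- which(st$A)
    ef <- (eidx - 1) %% N + 1; et <- (eidx - 1) %/% N + 1
    revOk <- vapply(seq_along(ef), function(j)
      !protect[ef[j], et[j]] && st$npar[ef[j]] < maxParents &&
        !black[et[j], ef[j]] &&
        !.pathExistsWithout(st$A, ef[j], et[j], et[j]), logical(1))
    cand <- c(if (length(adds)) paste0("A", adds),
              if (length(dels)) paste0("D", dels),
              if (any(revOk)) paste0("R", eidx[revOk]))
    if (!length(cand)) break
    pick <- sample(cand, 1)
    idx <- as.integer(substring(pick, 2))
    from <- (idx - 1) %% N + 1; to <- (idx - 1) %/% N + 1
    type <- c(A = "ADD", D = "DELETE", R = "REVERSE")[[substring(pick, 1, 1)]]
    st <- .applyMove(st, list(type = type, from = from, to = to),
                     data, vars, nLevels, cache)
  }
  st
}

#' Learn a Bayesian network structure by hill climbing with random restarts
#'
#' Greedy search over DAG space under the decomposable BIC score: at each
#' step the single edge addition, deletion or reversal with the largest
#' positive score gain is applied (gains are computed from the one or two
#' affected families only), until a local optimum is reached. The best graph
#' is then perturbed by `perturbations` random legal moves and re-climbed,
#' `restarts` times; the best-scoring graph seen anywhere is returned.
#' Equal-gain moves are resolved lexicographically by
#' (ADD < DELETE < REVERSE, source id, target id), so the search is
#' deterministic given the seed.
#'
#' @param data integer genes-by-samples level matrix (0-based levels)
#' @param restarts number of random restarts (0 = single climb)
#' @param perturbations random moves applied to the incumbent per restart
#' @param maxParents parent-set size bound
#' @param seed integer seed for the restart perturbations; `NULL` uses the
#'   current RNG state
#' @param blacklist optional data.frame (`from`, `to`) of forbidden edges
#' @param whitelist optional data.frame (`from`, `to`) of edges fixed into
#'   the graph and protected from deletion/reversal
#' @param start optional \linkS4class{DiscreteDAG} to start from (default:
#'   empty graph, plus any whitelisted edges)
#' @param nLevels optional named level counts
#' @return list with `dag` (a \linkS4class{DiscreteDAG}) and `score`
#' @export
hillClimb <- function(data, restarts = 10, perturbations = 5, maxParents = 8,
                      seed = NULL, blacklist = NULL, whitelist = NULL,
                      start = NULL, nLevels = NULL) {
  run <- function() .hillClimbImpl(data, restarts, perturbations, maxParents,
                                   blacklist, whitelist, start, nLevels)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

.hillClimbImpl <- function(data, restarts, perturbations, maxParents,
                           blacklist, whitelist, start, nLevels) {
  vars <- sort(rownames(data))
  if (length(vars) < 2L) stop("need at least two variables")
  N <- length(vars)
  nLevels <- .dataLevels(data, nLevels)
  cache <- new.env(parent = emptyenv())
  black <- matrix(FALSE, N, N)
  if (!is.null(blacklist) && nrow(blacklist))
    black[cbind(match(blacklist$from, vars), match(blacklist$to, vars))] <- TRUE
  protect <- matrix(FALSE, N, N)
  parents <- stats::setNames(rep(list(character()), N), vars)
  if (!is.null(start)) parents[vars] <- dagParents(start)[vars]
  if (!is.null(whitelist) && nrow(whitelist)) {
    for (i in seq_len(nrow(whitelist))) {
      f <- whitelist$from[i]; t <- whitelist$to[i]
      parents[[t]] <- unique(c(parents[[t]], f))
      protect[match(f, vars), match(t, vars)] <- TRUE
    }
  }
  st <- .freshState(parents, data, vars, nLevels, cache)
  st <- .climb(st, data, vars, nLevels, cache, maxParents, black, protect)
  best <- st; bestScore <- sum(st$fs)
  for (r in seq_len(restarts)) {
    st <- .perturb(best, perturbations, data, vars, nLevels, cache,
                   maxParents, black, protect)
    st <- .climb(st, data, vars, nLevels, cache, maxParents, black, protect)
    if (sum(st$fs) > bestScore + 1e-12) { best <- st; bestScore <- sum(st$fs) }
  }
  pa <- lapply(best$pa, function(ix) vars[ix])
  names(pa) <- vars
  dag <- DiscreteDAG(rownames(data), pa)
  list(dag = dag, score = bestScore)
}

#' Ancestral sampling from a discrete Bayesian network
#'
#' Draws `n` joint samples by sampling each variable, in topological order,
#' from its conditional distribution given the sampled parent levels.
#'
#' @param dag a \linkS4class{DiscreteDAG}
#' @param cpds named list, one entry per node: a list with `parents`
#'   (character, the order in which parent levels index the table; must equal
#'   the node's DAG parent set) and `prob`, a q-by-r matrix of conditional
#'   distributions (rows = parent configurations with the first listed parent
#'   varying slowest, columns = child levels; each row sums to 1). Root nodes
#'   may supply a bare probability vector.
#' @param n number of samples
#' @param seed integer seed, or `NULL` for the current RNG state
#' @return integer variables-by-samples level matrix with attribute `nLevels`
#' @export
sampleFromNetwork <- function(dag, cpds, n, seed = NULL) {
  run <- function() .sampleImpl(dag, cpds, n)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

.sampleImpl <- function(dag, cpds, n) {
  ord <- topologicalOrder(dag)
  nodes <- dag@nodes
  r <- integer(length(nodes)); names(r) <- nodes
  for (v in nodes) {
    cp <- cpds[[v]]
    if (is.numeric(cp)) cp <- list(parents = character(),
                                   prob = matrix(cp, nrow = 1))
    if (!setequal(cp$parents, dag@parents[[v]]))
      stop("CPD parents of ", v, " disagree with the DAG")
    if (any(cp$prob < 0) || any(abs(rowSums(cp$prob) - 1) > 1e-8))
      stop("CPD rows of ", v, " must be distributions")
    cpds[[v]] <- cp
    r[[v]] <- ncol(cp$prob)
  }
  out <- matrix(0L, nrow = length(nodes), ncol = n,
                dimnames = list(nodes, NULL))
  for (v in ord) {
    cp <- cpds[[v]]
    cfg <- integer(n)
    for (p in cp$parents) cfg <- cfg * r[[p]] + out[p, ]
    u <- stats::runif(n)
    cum <- t(apply(cp$prob, 1, cumsum))
    lev <- integer(n)
    for (j in unique(cfg)) {
      sel <- cfg == j
      lev[sel] <- findInterval(u[sel], cum[j + 1L, ],
                               rightmost.closed = FALSE)
    }
    out[v, ] <- pmin(lev, r[[v]] - 1L)
  }
  attr(out, "nLevels") <- r
  out
}
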