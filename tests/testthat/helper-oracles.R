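# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: MI by direct cell summation, BIC by naive joint counting,
# UPGMA by the O(n^3) textbook recursion, hypergeometric tails by choose().

oracleMI <- function(x, y) {
  n <- length(x)
  total <- 0
  for (a in unique(x)) for (b in unique(y)) {
    pxy <- sum(x == a & y == b) / n
    if (pxy == 0) next
    total <- total + pxy * log(pxy / ((sum(x == a) / n) * (sum(y == b) / n)))
  }
  total
}

# Naive BIC of a DAG given data (genes x samples, 0-based levels, binary
# unless nLevels given): counts every (parent config, child level) cell by
# explicit looping over samples.
oracleBic <- function(parents, data, nLevels = NULL) {
  if (is.null(nLevels))
    nLevels <- stats::setNames(pmax(apply(data, 1, max) + 1, 2),
                               rownames(data))
  n <- ncol(data)
  total <- 0
  for (v in names(parents)) {
    pa <- parents[[v]]
    key <- apply(data[c(pa, v), , drop = FALSE], 2, paste, collapse = "|")
    pkey <- if (length(pa))
      apply(data[pa, , drop = FALSE], 2, paste, collapse = "|")
    else rep("", n)
    ll <- 0
    for (cell in unique(key)) {
      njk <- sum(key == cell)
      nj <- sum(pkey == pkey[which(key == cell)[1]])
      ll <- ll + njk * log(njk / nj)
    }
    d <- (nLevels[[v]] - 1) * prod(c(1, nLevels[pa]))
    total <- total + ll - d / 2 * log(n)
  }
  total
}

# All DAGs over <= 4 variables as parent lists (for enumeration checks).
oracleAllDags <- function(vars) {
  k <- length(vars)
  pairs <- expand.grid(from = seq_len(k), to = seq_len(k))
  pairs <- pairs[pairs$from != pairs$to, ]
  out <- list()
  for (mask in 0:(2^nrow(pairs) - 1)) {
    sel <- bitwAnd(mask, bitwShiftL(1L, seq_len(nrow(pairs)) - 1L)) != 0L
    pa <- lapply(seq_len(k), function(j) vars[pairs$from[sel & pairs$to == j]])
    names(pa) <- vars
    ok <- tryCatch({ DiscreteDAG(vars, pa); TRUE },
                   error = function(e) FALSE)
    if (ok) out[[length(out) + 1L]] <- pa
  }
  out
}

# Textbook UPGMA: heights of successive merges by recomputing all mean
# inter-cluster distances from scratch at every step.
oracleUpgma <- function(dm) {
  clusters <- as.list(rownames(dm))
  heights <- numeric()
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- mean(dm[clusters[[i]], clusters[[j]]])
      if (d < best) { best <- d; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

oracleHyperTail <- function(N, K, m, k) {
  hi <- min(m, K)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(i)
    choose(K, i) * choose(N - K, m - i), numeric(1))) / choose(N, m)
}

# Retained total pairwise MI of the best adjacent binary collapse, by
# exhaustive enumeration of the 3^p cut positions (levels 0..3 -> one of
# the 3 adjacent splits per variable).
oracleBestCollapse <- function(levels4) {
  p <- nrow(levels4)
  cuts <- expand.grid(rep(list(1:3), p))
  best <- -Inf
  for (r in seq_len(nrow(cuts))) {
    bin <- levels4
    for (v in seq_len(p)) bin[v, ] <- as.integer(levels4[v, ] >= cuts[r, v])
    tot <- 0
    for (i in seq_len(p - 1)) for (j in (i + 1):p)
      tot <- tot + oracleMI(bin[i, ], bin[j, ])
    if (tot > best) best <- tot
  }
  best
}

totalPairwiseMI <- function(levels) {
  tot <- 0
  p <- nrow(levels)
  for (i in seq_len(p - 1)) for (j in (i + 1):p)
    tot <- tot + oracleMI(levels[i, ], levels[j, ])
  tot
}

# Shared fixture: write a small GTF text file.
writeGtfLines <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

skeletonF1 <- function(trueDag, learnedDag) {
  und <- function(d) {
    e <- dagEdges(d)
    unique(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  }
  t <- und(trueDag); l <- und(learnedDag)
  tp <- length(intersect(t, l))
  if (!length(l) || !length(t)) return(0)
  prec <- tp / length(l); rec <- tp / length(t)
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}
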