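#' Initial quantile discretization of one profile
#'
#' Assigns each value to one of `k` empirical-quantile bins. Duplicate cut
#' points (common for zero-inflated FPKM profiles) are collapsed, so fewer
#' than `k` distinct levels may result; values equal to a cut point fall in
#' the lower bin. Level order follows value order: higher value, higher level.
#'
#' @param values numeric vector
#' @param k number of initial bins (>= 2)
#' @return integer vector of 0-based levels with attributes `nLevels` (bins
#'   actually realized) and `degenerate` (TRUE when only one level remains)
#' @export
quantileBins <- function(values, k) {
  if (k < 2L) stop("k must be >= 2")
  breaks <- unique(stats::quantile(values, probs = seq(0, 1, length.out = k + 1),
                                   names = FALSE, type = 7))
  if (length(breaks) < 2L) {           # constant profile
    lev <- rep(0L, length(values))
    attr(lev, "nLevels") <- 1L
    attr(lev, "degenerate") <- TRUE
    return(lev)
  }
  lev <- as.integer(cut(values, breaks = breaks, include.lowest = TRUE,
                        right = TRUE, labels = FALSE)) - 1L
  attr(lev, "nLevels") <- length(breaks) - 1L
  attr(lev, "degenerate") <- length(breaks) - 1L < 2L
  lev
}

# MI (nats) from a joint count table; 0 ln 0 := 0.
.miFromCounts <- function(tab) {
  n <- sum(tab)
  if (n == 0) return(0)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Empirical pairwise mutual information of two discrete profiles
#'
#' Plug-in estimate \eqn{\sum_{x,y} p(x,y) \ln[p(x,y)/(p(x)p(y))]} in nats,
#' with the convention \eqn{0 \ln 0 = 0}.
#'
#' @param x,y integer level vectors of equal length
#' @return nonnegative mutual information in nats
#' @export
pairwiseMI <- function(x, y) {
  if (length(x) != length(y)) stop("level vectors differ in length")
  .miFromCounts(table(x, y))
}

# Joint count table of rows v and u of an integer level matrix, given the
# current level counts lv, lu; tabulated in one pass.
.jointCounts <- function(lv, lu, xv, xu) {
  matrix(tabulate(xu * lv + xv + 1L, nbins = lv * lu), nrow = lv)
}

#' Collapse discretization levels while preserving pairwise mutual information
#'
#' Hartemink's information-preserving collapse: variables are visited in row
#' order; on each visit the pair of *adjacent* levels whose merge loses the
#' least total pairwise mutual information with all other variables is
#' merged; sweeps repeat until every variable has `target` levels. Ties in
#' merge loss are broken toward the lower level pair. Because only adjacent
#' levels merge, the value order of levels is preserved (the top level stays
#' "high expression").
#'
#' @param levels integer genes-by-samples matrix of 0-based levels
#' @param nLevels named integer vector of level counts per gene (defaults to
#'   observed max + 1)
#' @param target final number of levels (2 for the high/low scheme)
#' @return integer matrix of 0-based levels with attribute `nLevels`
#' @export
harteminkCollapse <- function(levels, nLevels = NULL, target = 2L) {
  if (target < 2L) stop("target must be >= 2")
  L <- levels
  genes <- rownames(L)
  if (is.null(nLevels))
    nLevels <- stats::setNames(apply(L, 1, max) + 1L, genes)
  nl <- nLevels[genes]
  repeat {
    todo <- which(nl > target)
    if (!length(todo)) break
    for (vi in todo) {
      lv <- nl[[vi]]
      if (lv <= target) next
      others <- setdiff(seq_len(nrow(L)), vi)
      tabs <- lapply(others, function(ui)
        .jointCounts(lv, nl[[ui]], L[vi, ], L[ui, ]))
      retained <- vapply(seq_len(lv - 1L), function(j) {
        sum(vapply(tabs, function(tb) {
          tb[j, ] <- tb[j, ] + tb[j + 1L, ]
          .miFromCounts(tb[-(j + 1L), , drop = FALSE])
        }, numeric(1)))
      }, numeric(1))
      j <- which(retained >= max(retained) - 1e-12)[1]   # tie: lower pair
      row <- L[vi, ]
      row[row == j] <- j - 1L
      row[row > j] <- row[row > j] - 1L
      L[vi, ] <- row
      nl[[vi]] <- lv - 1L
    }
  }
  attr(L, "nLevels") <- nl
  L
}

#' Discretize an expression matrix to high/low levels
#'
#' Quantile-bins each gene's profile into `ibreaks` initial levels, drops
#' constant (degenerate) profiles with a warning, then applies
#' [harteminkCollapse()] jointly over all remaining genes down to `target`
#' levels (2: low = 0, high = 1).
#'
#' @param m numeric genes-by-samples matrix
#' @param ibreaks initial quantile bin count
#' @param target final level count
#' @return integer genes-by-samples matrix of 0-based levels with attributes
#'   `nLevels` (named) and `degenerate` (ids of dropped genes)
#' @export
discretizeExpression <- function(m, ibreaks = 4L, target = 2L) {
  bins <- lapply(seq_len(nrow(m)), function(i) quantileBins(m[i, ], ibreaks))
  nl <- vapply(bins, attr, integer(1), "nLevels")
  degenerate <- rownames(m)[nl < target]
  if (length(degenerate))
    warning(length(degenerate), " constant profile(s) dropped: ",
            paste(utils::head(degenerate, 5), collapse = ", "))
  keep <- nl >= target
  L <- do.call(rbind, bins[keep])
  rownames(L) <- rownames(m)[keep]
  colnames(L) <- colnames(m)
  out <- harteminkCollapse(L, stats::setNames(nl[keep], rownames(L)),
                           target = target)
  attr(out, "degenerate") <- degenerate
  out
}
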