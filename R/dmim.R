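# Distance-based mutual information scoring of herb pairs.
#
# The tendency of two herbs to form a pair is scored from two ingredients:
# the mutual information of their presence/absence across formulae, and the
# average between-herb-distance |b_ix - b_iy| over the formulae where they
# co-occur.  The default score S = MI / d_bar is strictly increasing in MI
# at fixed distance and strictly decreasing in distance at fixed MI.

#' Presence and co-occurrence counts for a herb pair
#'
#' @param corpus a [formula_corpus()].
#' @param x,y herb names or integer ids; must be distinct.
#' @return named numeric vector `n_x`, `n_y`, `n_xy`, `m` (frequencies are
#'   the counts divided by `m`).
#' @export
cooccurrence_counts <- function(corpus, x, y) {
  jx <- .herb_col(corpus, x)
  jy <- .herb_col(corpus, y)
  if (jx == jy) stop("x and y must be two distinct herbs")
  px <- corpus$A[, jx] > 0L
  py <- corpus$A[, jy] > 0L
  c(n_x = sum(px), n_y = sum(py), n_xy = sum(px & py), m = corpus$m)
}

# MI from 2x2 presence/absence counts.
#   pmi:      P(xy) * log2(P(xy) / (P(x) P(y))), 0 when P(xy) = 0
#   joint2x2: full mutual information of the joint presence/absence table
.mi_from_counts <- function(n_x, n_y, n_xy, m, mi_form = c("pmi", "joint2x2")) {
  mi_form <- match.arg(mi_form)
  if (n_x == 0 || n_y == 0)
    stop("herb absent from every formula; mutual information undefined")
  px <- n_x / m
  py <- n_y / m
  pxy <- n_xy / m
  if (mi_form == "pmi") {
    if (pxy == 0) return(0)
    return(pxy * log2(pxy / (px * py)))
  }
  p <- c(pxy, px - pxy, py - pxy, 1 - px - py + pxy)
  e <- c(px * py, px * (1 - py), (1 - px) * py, (1 - px) * (1 - py))
  ok <- p > 0
  max(0, sum(p[ok] * log2(p[ok] / e[ok])))  # clamp rounding at exact independence
}

#' Mutual information of two herbs' presence across formulae
#'
#' The default form is the joint-weighted pointwise mutual information
#' `P(xy) log2(P(xy) / (P(x)P(y)))` (zero when the herbs never co-occur),
#' which is large only under positive association.  `mi_form = "joint2x2"`
#' computes the full mutual information of the 2x2 presence/absence table,
#' which is also large under anti-correlation.
#'
#' @inheritParams cooccurrence_counts
#' @param mi_form `"pmi"` (default) or `"joint2x2"`.
#' @return mutual information in bits.
#' @export
mutual_information <- function(corpus, x, y, mi_form = c("pmi", "joint2x2")) {
  ct <- cooccurrence_counts(corpus, x, y)
  .mi_from_counts(ct[["n_x"]], ct[["n_y"]], ct[["n_xy"]], ct[["m"]],
                  match.arg(mi_form))
}

#' Between-herb-distance within one formula
#'
#' `d(x, y, i) = |b_ix - b_iy|`, the absolute difference of the two herbs'
#' normalized positions in formula `i`.  For a formula of size `k` the
#' distance lies in `[1/k, (k-1)/k]`.
#'
#' @inheritParams cooccurrence_counts
#' @param i formula id (character) or row index (integer).
#' @return distance in (0, 1).
#' @export
between_herb_distance <- function(corpus, x, y, i) {
  jx <- .herb_col(corpus, x)
  jy <- .herb_col(corpus, y)
  if (jx == jy) stop("x and y must be two distinct herbs")
  if (is.character(i)) {
    i <- match(i, corpus$formula_ids)
    if (is.na(i)) stop("unknown formula id")
  }
  if (i < 1L || i > corpus$m) stop("formula index out of range: ", i)
  if (corpus$A[i, jx] == 0L || corpus$A[i, jy] == 0L)
    stop(sprintf("herb '%s' and/or '%s' absent from formula '%s'",
                 corpus$herbs$name[jx], corpus$herbs$name[jy],
                 corpus$formula_ids[[i]]))
  abs(corpus$B[i, jx] - corpus$B[i, jy])
}

#' Average between-herb-distance over co-occurring formulae
#'
#' The arithmetic mean of `d(x, y, i)` over exactly the formulae in which
#' both herbs occur; undefined (error) for herbs that never co-occur.
#'
#' @inheritParams cooccurrence_counts
#' @return mean distance `d_bar` in (0, 1).
#' @export
mean_distance <- function(corpus, x, y) {
  jx <- .herb_col(corpus, x)
  jy <- .herb_col(corpus, y)
  if (jx == jy) stop("x and y must be two distinct herbs")
  rows <- which(corpus$A[, jx] > 0L & corpus$A[, jy] > 0L)
  if (!length(rows))
    stop(sprintf("herbs '%s' and '%s' never co-occur; mean distance undefined",
                 corpus$herbs$name[jx], corpus$herbs$name[jy]))
  mean(abs(corpus$B[rows, jx] - corpus$B[rows, jy]))
}

.combine_score <- function(mi, d_bar, score_form = c("ratio", "product")) {
  score_form <- match.arg(score_form)
  if (score_form == "ratio") mi / d_bar else mi * (1 - d_bar)
}

#' DMIM score of a single herb pair
#'
#' Combines mutual information and average between-herb-distance; the
#' default composition is `S = MI / d_bar`.  With `score_form = "product"`,
#' `S = MI * (1 - d_bar)`.  Both compositions are strictly increasing in MI
#' at fixed distance and strictly decreasing in distance at fixed MI.
#'
#' @inheritParams mutual_information
#' @param score_form `"ratio"` (default) or `"product"`.
#' @param min_cooccur minimum number of co-occurrences required (default 3);
#'   pairs below it are not scored.
#' @return the DMIM score (numeric scalar).
#' @export
dmim_score <- function(corpus, x, y, mi_form = c("pmi", "joint2x2"),
                       score_form = c("ratio", "product"), min_cooccur = 3L) {
  ct <- cooccurrence_counts(corpus, x, y)
  if (ct[["n_xy"]] < min_cooccur)
    stop(sprintf("pair co-occurs in %d formulae, below min_cooccur = %d",
                 ct[["n_xy"]], min_cooccur))
  mi <- .mi_from_counts(ct[["n_x"]], ct[["n_y"]], ct[["n_xy"]], ct[["m"]],
                        match.arg(mi_form))
  .combine_score(mi, mean_distance(corpus, x, y), match.arg(score_form))
}

#' Pearson chi-square test of herb co-occurrence
#'
#' Tests association of the two herbs' presence over the `m` formulae via
#' the 2x2 contingency table
#' `[[n_xy, n_x - n_xy], [n_y - n_xy, m - n_x - n_y + n_xy]]`,
#' 1 df, no continuity correction.  A zero marginal row or column makes the
#' statistic undefined; `p_value = 1` is returned with `degenerate = TRUE`.
#'
#' @param n_x,n_y,n_xy,m presence and co-occurrence counts.
#' @return list with `chi2`, `p_value`, `degenerate`.
#' @export
pair_chi2 <- function(n_x, n_y, n_xy, m) {
  if (m < 1 || n_xy > n_x || n_xy > n_y || n_x > m || n_y > m || n_xy < 0)
    stop("inconsistent counts")
  a <- n_xy
  b <- n_x - n_xy
  cc <- n_y - n_xy
  d <- m - n_x - n_y + n_xy
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    warning("degenerate 2x2 table (zero margin); returning p = 1")
    return(list(chi2 = NA_real_, p_value = 1, degenerate = TRUE))
  }
  chi2 <- m * (a * d - b * cc)^2 / (r1 * r2 * c1 * c2)
  list(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Score and rank every herb pair in a corpus
#'
#' Computes frequencies, mutual information, average between-herb-distance,
#' the DMIM score and the chi-square association test for every unordered
#' herb pair with at least `min_cooccur` co-occurrences, and ranks pairs by
#' descending score.  Ties are broken deterministically by smaller `d_bar`,
#' then lexicographic herb names.
#'
#' @param corpus a [formula_corpus()] with at least two herbs.
#' @inheritParams dmim_score
#' @return a `data.frame` of class `dmim_pairs` with columns `rank`,
#'   `herb_x`, `herb_y`, `n_x`, `n_y`, `n_xy`, `p_x`, `p_y`, `p_xy`, `mi`,
#'   `d_bar`, `score`, `chi2`, `p_value`, `degenerate`, sorted by rank.
#'   Attributes `mi_form`, `score_form`, `min_cooccur`, `m`, `n_herbs` and
#'   `n_filtered` (pairs with 1 <= n_xy < min_cooccur) record the
#'   configuration.
#' @export
score_all_pairs <- function(corpus, min_cooccur = 3L,
                            mi_form = c("pmi", "joint2x2"),
                            score_form = c("ratio", "product")) {
  stopifnot(inherits(corpus, "formula_corpus"))
  mi_form <- match.arg(mi_form)
  score_form <- match.arg(score_form)
  if (corpus$n < 2L) stop("corpus must contain at least two herbs")

  P <- corpus$A > 0L
  N <- crossprod(P)               # n x n co-occurrence counts
  nx <- diag(N)
  m <- corpus$m

  ut <- upper.tri(N)
  n_filtered <- sum(N[ut] >= 1 & N[ut] < min_cooccur)
  idx <- which(ut & N >= min_cooccur, arr.ind = TRUE)

  empty <- data.frame(rank = integer(0), herb_x = character(0),
                      herb_y = character(0), n_x = integer(0),
                      n_y = integer(0), n_xy = integer(0), p_x = numeric(0),
                      p_y = numeric(0), p_xy = numeric(0), mi = numeric(0),
                      d_bar = numeric(0), score = numeric(0),
                      chi2 = numeric(0), p_value = numeric(0),
                      degenerate = logical(0), stringsAsFactors = FALSE)
  if (nrow(idx) == 0L)
    return(.as_dmim_pairs(empty, mi_form, score_form, min_cooccur, corpus,
                          n_filtered))

  j1 <- idx[, 1L]
  j2 <- idx[, 2L]
  n_xy <- N[idx]
  n_x <- nx[j1]
  n_y <- nx[j2]

  d_bar <- numeric(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    rows <- which(P[, j1[r]] & P[, j2[r]])
    d_bar[r] <- mean(abs(corpus$B[rows, j1[r]] - corpus$B[rows, j2[r]]))
  }

  p_x <- n_x / m; p_y <- n_y / m; p_xy <- n_xy / m
  mi <- if (mi_form == "pmi") {
    p_xy * log2(p_xy / (p_x * p_y))
  } else {
    mapply(.mi_from_counts, n_x, n_y, n_xy, MoreArgs = list(m = m, mi_form = "joint2x2"))
  }
  score <- .combine_score(mi, d_bar, score_form)

  # vectorized Pearson chi-square on the 2x2 presence table
  a <- n_xy; b <- n_x - n_xy; cc <- n_y - n_xy; d <- m - n_x - n_y + n_xy
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
  degenerate <- r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0
  chi2 <- rep(NA_real_, length(a))
  ok <- !degenerate
  chi2[ok] <- m * (a[ok] * d[ok] - b[ok] * cc[ok])^2 /
    (r1[ok] * r2[ok] * c1[ok] * c2[ok])
  p_value <- rep(1, length(a))
  p_value[ok] <- stats::pchisq(chi2[ok], df = 1, lower.tail = FALSE)

  name_x <- corpus$herbs$name[j1]
  name_y <- corpus$herbs$name[j2]
  df <- data.frame(herb_x = name_x, herb_y = name_y,
                   n_x = as.integer(n_x), n_y = as.integer(n_y),
                   n_xy = as.integer(n_xy), p_x = p_x, p_y = p_y,
                   p_xy = p_xy, mi = mi, d_bar = d_bar, score = score,
                   chi2 = chi2, p_value = p_value, degenerate = degenerate,
                   stringsAsFactors = FALSE)
  ord <- order(-df$score, df$d_bar, pmin(name_x, name_y), pmax(name_x, name_y))
  df <- df[ord, , drop = FALSE]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  .as_dmim_pairs(df, mi_form, score_form, min_cooccur, corpus, n_filtered)
}

.as_dmim_pairs <- function(df, mi_form, score_form, min_cooccur, corpus,
                           n_filtered) {
  attr(df, "mi_form") <- mi_form
  attr(df, "score_form") <- score_form
  attr(df, "min_cooccur") <- as.integer(min_cooccur)
  attr(df, "m") <- corpus$m
  attr(df, "n_herbs") <- corpus$n
  attr(df, "n_filtered") <- as.integer(n_filtered)
  class(df) <- c("dmim_pairs", "data.frame")
  df
}
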