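# Highest-single-agent (HSA) scoring of dose-matrix combination
# experiments.  The additivity reference for a combination cell (i, j) is
# the greater of the two single-agent effects at the matched doses; the
# excess over that reference calls synergy (positive) or antagonism
# (negative).

#' Construct a dose-matrix combination experiment
#'
#' @param doses_a,doses_b ascending concentration vectors (e.g. uM) for the
#'   two agents.
#' @param effect_a,effect_b single-agent responses (percent growth or
#'   percent inhibition) at each dose.
#' @param effect_ab matrix of combination responses, rows = `doses_a`,
#'   columns = `doses_b`.
#' @param mode `"growth"` or `"inhibition"`; recorded for reporting only,
#'   the arithmetic is identical.
#' @return an object of class `dose_matrix`.
#' @export
dose_matrix <- function(doses_a, doses_b, effect_a, effect_b, effect_ab,
                        mode = c("growth", "inhibition")) {
  mode <- match.arg(mode)
  effect_ab <- as.matrix(effect_ab)
  if (length(effect_a) != length(doses_a) ||
      length(effect_b) != length(doses_b))
    stop("single-agent effect vectors must match their dose vectors")
  if (nrow(effect_ab) != length(doses_a) || ncol(effect_ab) != length(doses_b))
    stop(sprintf("combination matrix is %dx%d but doses imply %dx%d",
                 nrow(effect_ab), ncol(effect_ab),
                 length(doses_a), length(doses_b)))
  if (is.unsorted(doses_a) || is.unsorted(doses_b))
    stop("dose vectors must be ascending")
  if (!all(is.finite(effect_a)) || !all(is.finite(effect_b)) ||
      !all(is.finite(effect_ab)))
    stop("responses must be finite")
  dimnames(effect_ab) <- list(doses_a, doses_b)
  structure(list(doses_a = doses_a, doses_b = doses_b,
                 effect_a = stats::setNames(effect_a, doses_a),
                 effect_b = stats::setNames(effect_b, doses_b),
                 effect_ab = effect_ab, mode = mode),
            class = "dose_matrix")
}

#' Read a dose-matrix experiment from a long-format TSV
#'
#' Columns `dose_a`, `dose_b`, `response`.  Rows with `dose_b == 0` give
#' the single-agent responses of agent A (and vice versa); replicate rows
#' for the same dose cell are averaged.  The `(0, 0)` cell, if present, is
#' ignored.
#'
#' @param path input TSV.
#' @inheritParams dose_matrix
#' @return a [dose_matrix()] object.
#' @export
read_dose_matrix <- function(path, mode = c("growth", "inhibition")) {
  mode <- match.arg(mode)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("dose_a", "dose_b", "response")
  if (!all(need %in% names(df)))
    stop("dose matrix TSV needs columns: ", paste(need, collapse = ", "))

  avg <- function(sub, by) {
    out <- tapply(sub$response, sub[[by]], mean)
    out[order(as.numeric(names(out)))]
  }
  sa <- avg(df[df$dose_b == 0 & df$dose_a > 0, , drop = FALSE], "dose_a")
  sb <- avg(df[df$dose_a == 0 & df$dose_b > 0, , drop = FALSE], "dose_b")
  if (!length(sa) || !length(sb))
    stop("no single-agent rows (dose 0 for the partner agent) found")
  doses_a <- as.numeric(names(sa))
  doses_b <- as.numeric(names(sb))

  cmb <- df[df$dose_a > 0 & df$dose_b > 0, , drop = FALSE]
  M <- matrix(NA_real_, length(doses_a), length(doses_b))
  cell <- tapply(cmb$response, list(cmb$dose_a, cmb$dose_b), mean)
  ra <- match(doses_a, as.numeric(rownames(cell)))
  rb <- match(doses_b, as.numeric(colnames(cell)))
  if (anyNA(ra) || anyNA(rb) || anyNA(cell[ra, rb]))
    stop("incomplete dose grid: every (dose_a, dose_b) cell needs a response")
  M[] <- cell[ra, rb]
  dose_matrix(doses_a, doses_b, as.numeric(sa), as.numeric(sb), M, mode = mode)
}

#' Excess over the highest-single-agent additivity reference
#'
#' `excess(i, j) = effect_ab(i, j) - max(effect_a(i), effect_b(j))`.  Cells
#' with excess above `tol` percentage points are called `synergy`, below
#' `-tol` `antagonism`, otherwise `additive`.
#'
#' @param dm a [dose_matrix()].
#' @param tol additivity dead-band in percentage points (default 5).
#' @return an object of class `hsa_excess`: list with the `excess` matrix,
#'   the HSA reference matrix `hsa`, the character `calls` matrix, `tol`
#'   and `mode`.
#' @export
hsa_excess <- function(dm, tol = 5) {
  stopifnot(inherits(dm, "dose_matrix"))
  hsa <- outer(unname(dm$effect_a), unname(dm$effect_b), pmax)
  excess <- dm$effect_ab - hsa
  calls <- matrix("additive", nrow(excess), ncol(excess))
  calls[excess > tol] <- "synergy"
  calls[excess < -tol] <- "antagonism"
  dimnames(calls) <- dimnames(excess)
  structure(list(excess = excess, hsa = hsa, calls = calls, tol = tol,
                 mode = dm$mode), class = "hsa_excess")
}

#' @export
print.hsa_excess <- function(x, ...) {
  cat(sprintf("HSA excess matrix (%s mode, dead-band %g points)\n",
              x$mode, x$tol))
  print(round(x$excess, 2))
  tab <- table(factor(x$calls, c("synergy", "additive", "antagonism")))
  cat(sprintf("cells: %d synergy, %d additive, %d antagonism\n",
              tab[["synergy"]], tab[["additive"]], tab[["antagonism"]]))
  invisible(x)
}
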