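# Position-coded representation of ordered multi-herb formulae.
#
# A formula lists its herbs in decreasing traditional importance (the
# Master-Adviser-Soldier-Guide convention), so the listed position carries
# information.  A corpus of m formulae over n herbs is encoded as an m x n
# integer position matrix A (a_ij = position of herb j in formula i, 0 if
# absent) and a size-normalized matrix B with b_ij = a_ij / k_i, where k_i
# is the number of herbs in formula i.

HERB_PROPERTIES <- c("Cold", "Cool", "Neutral", "Warm", "Hot", "Unknown")

#' Build a formula corpus from ordered herb-name lists
#'
#' Herbs are assigned stable integer ids 1..n in order of first appearance
#' across the corpus, so the same input file always yields the same
#' encoding.
#'
#' @param formula_herbs list of character vectors, each the ordered herb
#'   names of one formula (first-listed herb first).
#' @param formula_ids optional character vector of formula identifiers;
#'   defaults to `F1`, `F2`, ...
#' @param properties optional named character vector mapping herb names to a
#'   natural property (`Cold`, `Cool`, `Neutral`, `Warm`, `Hot`).
#' @return An object of class `formula_corpus`: a list with `herbs`
#'   (data.frame `herb_id`, `name`, `natural_property`), `formulae` (list of
#'   integer herb-id vectors in listed order), `formula_ids`, the integer
#'   position matrix `A`, the normalized matrix `B`, and the sizes `m`
#'   (formulae) and `n` (herbs).
#' @export
formula_corpus <- function(formula_herbs, formula_ids = NULL, properties = NULL) {
  if (!is.list(formula_herbs) || length(formula_herbs) == 0L)
    stop("corpus contains no formulae")
  if (is.null(formula_ids))
    formula_ids <- sprintf("F%d", seq_along(formula_herbs))
  formula_ids <- as.character(formula_ids)
  if (length(formula_ids) != length(formula_herbs))
    stop("formula_ids must match the number of formulae")
  if (anyDuplicated(formula_ids))
    stop("duplicate formula ids: ", formula_ids[duplicated(formula_ids)][1L])
  for (i in seq_along(formula_herbs)) {
    h <- formula_herbs[[i]]
    if (length(h) < 1L)
      stop(sprintf("formula '%s' lists no herbs", formula_ids[[i]]))
    if (!is.character(h) || anyNA(h) || any(!nzchar(h)))
      stop(sprintf("formula '%s' has an empty herb name", formula_ids[[i]]))
    if (anyDuplicated(h))
      stop(sprintf("formula '%s' lists herb '%s' more than once",
                   formula_ids[[i]], h[duplicated(h)][1L]))
  }

  nm <- unique(unlist(formula_herbs, use.names = FALSE))
  n <- length(nm)
  m <- length(formula_herbs)
  prop <- stats::setNames(rep("Unknown", n), nm)
  if (!is.null(properties)) {
    properties <- .validate_properties(properties)
    keep <- intersect(names(properties), nm)
    prop[keep] <- properties[keep]
  }
  herbs <- data.frame(herb_id = seq_len(n), name = nm,
                      natural_property = unname(prop),
                      stringsAsFactors = FALSE)
  formulae <- lapply(formula_herbs, function(h) match(h, nm))
  k <- vapply(formulae, length, integer(1))

  A <- matrix(0L, m, n, dimnames = list(formula_ids, nm))
  for (i in seq_len(m)) A[i, formulae[[i]]] <- seq_len(k[[i]])
  B <- A / k  # k recycles down rows (column-major), i.e. row i divided by k_i

  structure(list(herbs = herbs, formulae = formulae,
                 formula_ids = formula_ids, A = A, B = B, m = m, n = n),
            class = "formula_corpus")
}

.validate_properties <- function(properties) {
  properties <- unlist(properties)
  if (is.null(names(properties)) || any(!nzchar(names(properties))))
    stop("herb properties must be a named vector (herb name -> property)")
  bad <- setdiff(unique(properties), HERB_PROPERTIES)
  if (length(bad))
    stop("unknown natural property: ", paste(bad, collapse = ", "))
  properties
}

#' @export
print.formula_corpus <- function(x, ...) {
  cat(sprintf("formula_corpus: %d formulae, %d herbs\n", x$m, x$n))
  k <- vapply(x$formulae, length, integer(1))
  cat(sprintf("  herbs per formula: %d-%d (median %g)\n",
              min(k), max(k), stats::median(k)))
  invisible(x)
}

#' Load an ordered formula corpus from a file
#'
#' Two plain-text formats are supported: TSV with lines
#' `formula_id<TAB>herb1|herb2|...` (pipe-separated, order significant), and
#' JSON lines with one `{"id": ..., "herbs": [...]}` object per line.
#' Lines that are blank or start with `#` are skipped.
#'
#' @param path path to the corpus file.
#' @param format `"tsv"` or `"jsonl"`.
#' @param dedupe if `TRUE`, a herb listed more than once in a formula keeps
#'   its first (most important) position; if `FALSE` (default) duplicates
#'   are an error.
#' @param properties optional named character vector of herb natural
#'   properties, or the path to a two-column TSV `herb<TAB>property`.
#' @return A [formula_corpus()] object.
#' @export
load_corpus <- function(path, format = c("tsv", "jsonl"), dedupe = FALSE,
                        properties = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("empty corpus file: ", path)

  if (format == "tsv") {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ids <- vapply(parts, function(p) trimws(p[[1L]]), "")
    herbs <- lapply(parts, function(p) {
      if (length(p) < 2L) return(character(0))
      trimws(strsplit(p[[2L]], "|", fixed = TRUE)[[1L]])
    })
  } else {
    recs <- lapply(lines, jsonlite::fromJSON)
    ids <- vapply(recs, function(r) as.character(r$id), "")
    herbs <- lapply(recs, function(r) trimws(as.character(r$herbs)))
  }
  herbs <- lapply(herbs, function(h) h[nzchar(h)])
  if (dedupe) herbs <- lapply(herbs, function(h) h[!duplicated(h)])

  if (is.character(properties) && length(properties) == 1L &&
      file.exists(properties))
    properties <- read_herb_properties(properties)

  formula_corpus(herbs, ids, properties = properties)
}

#' Write a corpus back to the pipe-separated TSV format
#'
#' The written file round-trips: reloading it reproduces the matrices `A`
#' and `B` bit-identically.
#'
#' @param corpus a [formula_corpus()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "formula_corpus"))
  lines <- vapply(seq_len(corpus$m), function(i) {
    paste0(corpus$formula_ids[[i]], "\t",
           paste(corpus$herbs$name[corpus$formulae[[i]]], collapse = "|"))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column herb property table
#'
#' @param path TSV with columns `herb<TAB>property`.
#' @return named character vector (herb name -> property).
#' @export
read_herb_properties <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  .validate_properties(stats::setNames(trimws(df[[2L]]), trimws(df[[1L]])))
}

#' Read a two-column synonym map
#'
#' @param path TSV with columns `variant<TAB>canonical`.
#' @return named character vector (variant -> canonical).
#' @export
read_synonym_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  stats::setNames(trimws(df[[2L]]), trimws(df[[1L]]))
}

#' Normalize herb names against a synonym map
#'
#' Every variant name is replaced by its canonical form (chains
#' `a -> b -> c` are followed to the fixed point; a cycle is an error).
#' Herbs whose names become identical are merged.  If merging creates a
#' duplicate within one formula, the earliest (most important) position is
#' kept and the remaining positions are compacted to `1..k'`.
#'
#' @param corpus a [formula_corpus()].
#' @param synonym_map named character vector `variant -> canonical` (or a
#'   two-column data.frame), e.g. from [read_synonym_map()].
#' @return a rebuilt [formula_corpus()] over the canonical names.
#' @export
normalize_names <- function(corpus, synonym_map) {
  stopifnot(inherits(corpus, "formula_corpus"))
  if (is.data.frame(synonym_map))
    synonym_map <- stats::setNames(as.character(synonym_map[[2L]]),
                                   as.character(synonym_map[[1L]]))
  synonym_map <- synonym_map[names(synonym_map) != synonym_map]  # drop no-ops
  if (!length(synonym_map)) return(corpus)

  resolve <- function(x) {
    seen <- character(0)
    while (x %in% names(synonym_map)) {
      if (x %in% seen) stop("cyclic synonym map at '", x, "'")
      seen <- c(seen, x)
      x <- synonym_map[[x]]
    }
    x
  }
  old <- corpus$herbs$name
  canon <- vapply(old, resolve, "")

  # carry properties: first non-Unknown property among merged herbs wins
  prop <- character(0)
  for (i in seq_along(old)) {
    p <- corpus$herbs$natural_property[[i]]
    cn <- canon[[i]]
    if (!cn %in% names(prop) || (prop[[cn]] == "Unknown" && p != "Unknown"))
      prop[cn] <- p
  }

  lists <- lapply(corpus$formulae, function(f) {
    h <- unname(canon[f])
    h[!duplicated(h)]  # keep earliest position, compact to 1..k'
  })
  formula_corpus(lists, corpus$formula_ids, properties = prop)
}

#' Recompute the position matrices of a corpus
#'
#' @param corpus a [formula_corpus()].
#' @return list with the integer position matrix `A` and the normalized
#'   matrix `B` (`b_ij = a_ij / k_i`).
#' @export
encode_positions <- function(corpus) {
  stopifnot(inherits(corpus, "formula_corpus"))
  k <- vapply(corpus$formulae, length, integer(1))
  A <- matrix(0L, corpus$m, corpus$n,
              dimnames = list(corpus$formula_ids, corpus$herbs$name))
  for (i in seq_len(corpus$m)) A[i, corpus$formulae[[i]]] <- seq_len(k[[i]])
  list(A = A, B = A / k)
}

#' Attach natural properties to the herbs of a corpus
#'
#' @param corpus a [formula_corpus()].
#' @param properties named character vector (herb name -> property).
#' @return the corpus with `herbs$natural_property` updated.
#' @export
set_herb_properties <- function(corpus, properties) {
  stopifnot(inherits(corpus, "formula_corpus"))
  properties <- .validate_properties(properties)
  keep <- intersect(names(properties), corpus$herbs$name)
  corpus$herbs$natural_property[match(keep, corpus$herbs$name)] <-
    unname(properties[keep])
  corpus
}

# herb lookup: accepts a herb name or an integer id, returns the column index
.herb_col <- function(corpus, x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (length(x) != 1L || is.na(x) || x < 1L || x > corpus$n)
      stop("herb id out of range: ", x)
    return(x)
  }
  j <- match(x, corpus$herbs$name)
  if (is.na(j)) stop("unknown herb: '", x, "'")
  j
}
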