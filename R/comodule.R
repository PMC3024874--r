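# Co-module analysis across herb-biomolecule-disease multilayer networks:
# pathway enrichment of gene sets, closeness (average shortest path) of two
# gene sets in an interaction network with a permutation null, cosine
# phenotype similarity with a permutation null, and the tripartite
# co-module projection (herb module / core genes / disease module).

#' Read gene sets in GMT format
#'
#' One set per line: `set_id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) {
    g <- p[-(1:2)]
    unique(g[nzchar(g)])
  })
  names(sets) <- vapply(parts, `[[`, "", 1L)
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions per-set description column (defaults to the names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[[i]], descriptions[[i]], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an undirected interaction network from a two-column edge list
#'
#' @param path TSV with two columns of node identifiers.
#' @return a simplified undirected `igraph` graph.
#' @export
read_edgelist <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(df[, 1:2], directed = FALSE)
  igraph::simplify(g)
}

#' Read a phenotype-by-feature matrix
#'
#' @param path TSV whose first column holds phenotype ids and whose
#'   remaining columns are numeric features.
#' @return numeric matrix with phenotype ids as row names.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Pathway enrichment of a gene set by one-sided Fisher exact test
#'
#' For each pathway, the enrichment p-value is the hypergeometric upper
#' tail P(X >= overlap) of drawing `|gene_set|` genes from the background;
#' Benjamini-Hochberg FDR is computed across the tested pathways.
#'
#' @param gene_set character vector of genes (intersected with the
#'   background before testing).
#' @param pathways named list of gene sets (e.g. from [read_gmt()]).
#' @param background character vector: the gene universe.
#' @return data.frame with columns `pathway_id`, `overlap`, `set_size`,
#'   `pathway_size`, `background_size`, `fisher_p`, `fdr`, sorted by `fdr`
#'   then `fisher_p`.
#' @export
pathway_enrichment <- function(gene_set, pathways, background) {
  background <- unique(background)
  if (!length(background)) stop("background gene universe is empty")
  gs <- intersect(unique(gene_set), background)
  if (!length(gs))
    stop("gene set has no members in the background universe")
  N <- length(background)
  n <- length(gs)
  rows <- lapply(names(pathways), function(id) {
    pw <- intersect(unique(pathways[[id]]), background)
    K <- length(pw)
    k <- length(intersect(gs, pw))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway_id = id, overlap = k, set_size = n, pathway_size = K,
               background_size = N, fisher_p = p, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$fdr <- stats::p.adjust(df$fisher_p, "BH")
  df <- df[order(df$fdr, df$fisher_p, df$pathway_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Closeness of two gene sets in an interaction network
#'
#' The mean shortest-path length over all cross pairs `(g_a, g_b)` with
#' distinct endpoints that are connected in the network; the fraction of
#' cross pairs that were connected is reported alongside, so disconnection
#' is visible rather than silently imputed.
#'
#' @param ppi an undirected `igraph` interaction network with named nodes.
#' @param set_a,set_b character gene sets (intersected with the network's
#'   nodes; an empty intersection is an error).
#' @return list with `mean`, `coverage` (connected fraction of cross
#'   pairs), `n_pairs` and `n_connected`.
#' @export
average_shortest_path <- function(ppi, set_a, set_b) {
  vn <- igraph::V(ppi)$name
  sa <- intersect(unique(set_a), vn)
  sb <- intersect(unique(set_b), vn)
  if (!length(sa) || !length(sb))
    stop("gene set has no members in the interaction network")
  D <- igraph::distances(ppi, v = sa, to = sb)
  valid <- outer(sa, sb, "!=")   # exclude self-pairs of shared genes
  if (!any(valid)) stop("no cross pair with distinct endpoints")
  d <- D[valid]
  fin <- is.finite(d)
  if (!any(fin))
    stop("no connected cross pair between the two gene sets")
  list(mean = mean(d[fin]), coverage = mean(fin),
       n_pairs = sum(valid), n_connected = sum(fin))
}

#' Permutation test for gene-set closeness
#'
#' Keeps `set_a` fixed and redraws `|set_b|` genes (after intersection with
#' the network) from `pool` without replacement `n_perm` times; the p-value
#' is `(r + 1) / (n_perm + 1)` where `r` counts permuted mean path lengths
#' less than or equal to the observed one, so p is never zero.
#'
#' @inheritParams average_shortest_path
#' @param pool character vector of genes to resample from (e.g. all
#'   networked disease genes); must be at least as large as `set_b`.
#' @param n_perm number of permutations (default 2000).
#' @param seed optional integer seed for reproducible draws.
#' @return list with `p_value`, `observed` (mean path), `permuted` (the
#'   `n_perm` permuted means) and `n_perm`.
#' @export
closeness_permutation <- function(ppi, set_a, set_b, pool, n_perm = 2000L,
                                  seed = NULL) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  vn <- igraph::V(ppi)$name
  sa <- intersect(unique(set_a), vn)
  sb <- intersect(unique(set_b), vn)
  pl <- intersect(unique(pool), vn)
  if (!length(sa) || !length(sb))
    stop("gene set has no members in the interaction network")
  if (length(pl) < length(sb))
    stop(sprintf("pool (%d networked genes) is smaller than the draw size %d",
                 length(pl), length(sb)))
  if (!is.null(seed)) set.seed(seed)

  cols <- union(pl, sb)
  D <- igraph::distances(ppi, v = sa, to = cols)
  mp <- function(cs) {
    sub <- D[, cs, drop = FALSE]
    ok <- outer(rownames(sub), cs, "!=")
    d <- sub[ok]
    d <- d[is.finite(d)]
    if (!length(d)) Inf else mean(d)
  }
  obs <- mp(sb)
  if (!is.finite(obs))
    stop("no connected cross pair for the observed sets")
  perm <- vapply(seq_len(n_perm),
                 function(i) mp(sample(pl, length(sb))), numeric(1))
  r <- sum(perm <= obs)
  list(p_value = (r + 1) / (n_perm + 1), observed = obs, permuted = perm,
       n_perm = as.integer(n_perm))
}

#' Mean pairwise cosine similarity of phenotype feature vectors
#'
#' @param phenotypes nonnegative numeric matrix, rows = phenotypes,
#'   columns = features.
#' @param members phenotype ids (row names) or row indices; at least two.
#' @return mean over all unordered member pairs of
#'   `cos(u, v) = u . v / (|u| |v|)`.
#' @export
phenotype_similarity <- function(phenotypes, members) {
  M <- as.matrix(phenotypes)
  if (is.null(rownames(M))) rownames(M) <- sprintf("P%d", seq_len(nrow(M)))
  if (is.numeric(members)) members <- rownames(M)[members]
  miss <- setdiff(members, rownames(M))
  if (length(miss)) stop("unknown phenotype id(s): ", paste(miss, collapse = ", "))
  if (length(members) < 2L) stop("need at least two phenotypes")
  X <- M[members, , drop = FALSE]
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0))
    stop("zero-norm feature vector for phenotype '",
         members[which(nrm == 0)[1L]], "'")
  U <- X / nrm
  S <- tcrossprod(U)
  mean(S[upper.tri(S)])
}

#' Permutation test for phenotype-set similarity
#'
#' Draws `n_perm` random phenotype sets of the same size from the matrix
#' rows; the p-value is `(r + 1) / (n_perm + 1)` with `r` the number of
#' permuted mean similarities greater than or equal to the observed one.
#'
#' @inheritParams phenotype_similarity
#' @param n_perm number of permutations (default 2000).
#' @param seed optional integer seed.
#' @return list with `p_value`, `observed`, `permuted`, `n_perm`.
#' @export
phenotype_permutation <- function(phenotypes, members, n_perm = 2000L,
                                  seed = NULL) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  M <- as.matrix(phenotypes)
  if (is.null(rownames(M))) rownames(M) <- sprintf("P%d", seq_len(nrow(M)))
  if (is.numeric(members)) members <- rownames(M)[members]
  if (nrow(M) < length(members))
    stop("phenotype matrix has fewer rows than the member set")
  obs <- phenotype_similarity(M, members)
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    phenotype_similarity(M, sample(rownames(M), length(members)))
  }, numeric(1))
  r <- sum(perm >= obs)
  list(p_value = (r + 1) / (n_perm + 1), observed = obs, permuted = perm,
       n_perm = as.integer(n_perm))
}

# shared-gene projection of a gene-set list onto a weighted graph
.shared_gene_graph <- function(sets, min_shared) {
  nm <- names(sets)
  ed <- NULL
  if (length(nm) >= 2L) {
    cmb <- utils::combn(nm, 2L)
    w <- apply(cmb, 2L, function(p) length(intersect(sets[[p[1L]]], sets[[p[2L]]])))
    keep <- w >= min_shared
    ed <- data.frame(from = cmb[1L, keep], to = cmb[2L, keep],
                     weight = w[keep], stringsAsFactors = FALSE)
  }
  igraph::graph_from_data_frame(ed, directed = FALSE,
                                vertices = data.frame(name = nm))
}

#' Build the herb-biomolecule-disease co-module
#'
#' Projects herb and disease gene-set layers into weighted modules (two
#' herbs/diseases are linked when they share at least `min_shared` genes;
#' the edge weight is the shared-gene count), extracts the core genes
#' belonging to at least one herb set and one disease set, maps them onto
#' the interaction network, and (when the needed inputs are supplied)
#' fills in the closeness and phenotype-similarity statistics with their
#' permutation p-values.
#'
#' @param herb_genes named list: herb -> responsive gene set (>= 2 herbs).
#' @param disease_genes named list: disease -> disease gene set (>= 2).
#' @param ppi optional undirected `igraph` interaction network; when given,
#'   core genes are mapped onto it and closeness is computed between the
#'   pooled herb genes and pooled disease genes.
#' @param min_shared minimum shared-gene count for a module edge (default 1).
#' @param neighborhood 0 (default) keeps only the shared genes in the
#'   biomolecular layer; 1 additionally includes their direct network
#'   neighbors.
#' @param disease_pool optional gene pool for the closeness permutation
#'   null (e.g. all networked disease genes).
#' @param phenotypes,phenotype_members optional phenotype matrix and member
#'   ids for the phenotype-similarity statistic.
#' @param n_perm permutations for both tests (default 2000).
#' @param seed optional integer seed driving both permutation streams.
#' @return an object of class `comodule`: list with `herb_module` and
#'   `disease_module` (weighted `igraph` graphs), `core_genes`,
#'   `core_empty`, and when computable `closeness`, `closeness_coverage`,
#'   `closeness_p`, `phenotype_similarity`, `phenotype_p`.
#' @export
build_comodule <- function(herb_genes, disease_genes, ppi = NULL,
                           min_shared = 1L, neighborhood = 0L,
                           disease_pool = NULL, phenotypes = NULL,
                           phenotype_members = NULL, n_perm = 2000L,
                           seed = NULL) {
  if (length(herb_genes) < 2L || length(disease_genes) < 2L)
    stop("need at least two herbs and two diseases")
  if (any(!lengths(herb_genes)) || any(!lengths(disease_genes)))
    stop("empty gene mapping for ",
         paste(c(names(herb_genes)[!lengths(herb_genes)],
                 names(disease_genes)[!lengths(disease_genes)]),
               collapse = ", "))
  if (!neighborhood %in% c(0L, 1L)) stop("neighborhood must be 0 or 1")
  if (!is.null(seed)) set.seed(seed)

  herb_module <- .shared_gene_graph(herb_genes, min_shared)
  disease_module <- .shared_gene_graph(disease_genes, min_shared)

  hg <- unique(unlist(herb_genes, use.names = FALSE))
  dg <- unique(unlist(disease_genes, use.names = FALSE))
  core <- intersect(hg, dg)
  core_genes <- core
  if (!is.null(ppi)) {
    vn <- igraph::V(ppi)$name
    core_genes <- intersect(core, vn)
    if (neighborhood == 1L && length(core_genes)) {
      nb <- lapply(igraph::ego(ppi, order = 1, nodes = core_genes), names)
      core_genes <- unique(c(core_genes, unlist(nb)))
    }
  }

  res <- list(herb_module = herb_module, disease_module = disease_module,
              core_genes = core_genes, core_empty = length(core) == 0L,
              min_shared = as.integer(min_shared),
              neighborhood = as.integer(neighborhood))

  if (!is.null(ppi)) {
    asp <- tryCatch(average_shortest_path(ppi, hg, dg), error = function(e) NULL)
    if (!is.null(asp)) {
      res$closeness <- asp$mean
      res$closeness_coverage <- asp$coverage
      if (!is.null(disease_pool)) {
        cp <- closeness_permutation(ppi, hg, dg, disease_pool,
                                    n_perm = n_perm, seed = NULL)
        res$closeness_p <- cp$p_value
      }
    }
  }
  if (!is.null(phenotypes) && !is.null(phenotype_members)) {
    res$phenotype_similarity <- phenotype_similarity(phenotypes,
                                                     phenotype_members)
    pp <- phenotype_permutation(phenotypes, phenotype_members,
                                n_perm = n_perm, seed = NULL)
    res$phenotype_p <- pp$p_value
  }
  structure(res, class = "comodule")
}

#' @export
print.comodule <- function(x, ...) {
  cat("co-module analysis\n")
  cat(sprintf("  herb module:    %d herbs, %d shared-gene edges\n",
              igraph::vcount(x$herb_module), igraph::ecount(x$herb_module)))
  cat(sprintf("  disease module: %d diseases, %d shared-gene edges\n",
              igraph::vcount(x$disease_module),
              igraph::ecount(x$disease_module)))
  cat(sprintf("  core genes:     %d%s\n", length(x$core_genes),
              if (x$core_empty) " (no herb-disease gene overlap)" else ""))
  if (!is.null(x$closeness))
    cat(sprintf("  closeness:      %.4f (coverage %.2f%s)\n", x$closeness,
                x$closeness_coverage,
                if (!is.null(x$closeness_p))
                  sprintf(", permutation p = %.4g", x$closeness_p) else ""))
  if (!is.null(x$phenotype_similarity))
    cat(sprintf("  phenotype sim.: %.4f%s\n", x$phenotype_similarity,
                if (!is.null(x$phenotype_p))
                  sprintf(" (permutation p = %.4g)", x$phenotype_p) else ""))
  invisible(x)
}
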