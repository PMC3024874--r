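# Synthetic data with the statistical structure the pair-mining and
# co-module analyses assume: formula corpora with planted high-affinity
# adjacent herb pairs and a high-frequency randomly-positioned guide herb,
# plus random interaction networks, gene sets and block-structured
# phenotype matrices.

.synth_herb_names <- function(n) sprintf("H%03d", seq_len(n))

.resample <- function(x) x[sample.int(length(x), 1L)]

#' Specification of a synthetic formula corpus
#'
#' Defaults emulate a mid-sized mining corpus: 60 herbs, 500 formulae of
#' 4-10 herbs, five planted pairs that co-occur in 30% of formulae and sit
#' adjacently 90% of the time, and one guide herb present in 40% of
#' formulae at a uniformly random position (mirroring a ubiquitous
#' supplementary herb whose placement carries no pairing signal).
#'
#' @param n_herbs total number of herbs.
#' @param m_formulae number of formulae.
#' @param size_range integer vector `c(k_min, k_max)` of formula sizes;
#'   `k_min >= 2`, `k_max <= n_herbs`.
#' @param planted_pairs data.frame with columns `herb_x`, `herb_y`,
#'   `co_prob`, `adjacency_prob`; planted herbs must be distinct.  Default:
#'   five pairs over herbs `H001`-`H010` at co_prob 0.3, adjacency 0.9.
#' @param guide_herbs data.frame with columns `herb`, `marginal_freq`.
#'   Default: `H011` at 0.4.
#' @param seed integer seed; the corpus is fully determined by it.
#' @return an object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_herbs = 60L, m_formulae = 500L,
                        size_range = c(4L, 10L), planted_pairs = NULL,
                        guide_herbs = NULL, seed = 1L) {
  herbs <- .synth_herb_names(n_herbs)
  size_range <- as.integer(size_range)
  if (length(size_range) != 2L || size_range[1L] < 2L ||
      size_range[1L] > size_range[2L])
    stop("size_range must be c(k_min, k_max) with 2 <= k_min <= k_max")
  if (size_range[2L] > n_herbs)
    stop("infeasible spec: k_max exceeds the number of herbs")
  if (is.null(planted_pairs))
    planted_pairs <- data.frame(
      herb_x = herbs[c(1L, 3L, 5L, 7L, 9L)],
      herb_y = herbs[c(2L, 4L, 6L, 8L, 10L)],
      co_prob = 0.3, adjacency_prob = 0.9, stringsAsFactors = FALSE)
  if (is.null(guide_herbs))
    guide_herbs <- data.frame(herb = herbs[11L], marginal_freq = 0.4,
                              stringsAsFactors = FALSE)
  ph <- c(planted_pairs$herb_x, planted_pairs$herb_y)
  if (anyDuplicated(ph)) stop("planted herbs must be distinct")
  probs <- c(planted_pairs$co_prob, planted_pairs$adjacency_prob,
             guide_herbs$marginal_freq)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!all(c(ph, guide_herbs$herb) %in% herbs))
    stop("planted/guide herbs must be among the corpus herbs")
  structure(list(n_herbs = as.integer(n_herbs),
                 m_formulae = as.integer(m_formulae),
                 size_range = size_range, planted_pairs = planted_pairs,
                 guide_herbs = guide_herbs, seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Generate a synthetic formula corpus
#'
#' For each formula a size `k` is drawn uniformly from `size_range`; each
#' planted pair is included with its `co_prob` and, when included, placed
#' in adjacent positions with its `adjacency_prob` (otherwise at random
#' positions); each guide herb is included Bernoulli(`marginal_freq`) at a
#' uniformly random position; remaining slots are filled with distinct
#' herbs drawn from the non-planted, non-guide pool, so the planted and
#' guide marginals equal their specified rates.  When the included special
#' herbs exceed `k`, `k` grows to fit them.
#'
#' @param spec a [corpus_spec()].
#' @return a [formula_corpus()] with formula ids `S0001`, `S0002`, ...
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  set.seed(spec$seed)
  herbs <- .synth_herb_names(spec$n_herbs)
  pp <- spec$planted_pairs
  gh <- spec$guide_herbs
  special <- c(pp$herb_x, pp$herb_y, gh$herb)
  fillers <- setdiff(herbs, special)
  kmin <- spec$size_range[1L]
  kmax <- spec$size_range[2L]

  out <- vector("list", spec$m_formulae)
  for (i in seq_len(spec$m_formulae)) {
    k <- .resample(seq.int(kmin, kmax))
    inc <- stats::runif(nrow(pp)) < pp$co_prob
    adj <- stats::runif(nrow(pp)) < pp$adjacency_prob
    ing <- if (nrow(gh)) stats::runif(nrow(gh)) < gh$marginal_freq else logical(0)
    n_req <- 2L * sum(inc) + sum(ing)
    if (n_req > k) k <- n_req

    slots <- rep(NA_character_, k)
    for (p in which(inc)) {
      pair <- c(pp$herb_x[[p]], pp$herb_y[[p]])
      pair <- pair[sample.int(2L)]            # random within-pair order
      placed <- FALSE
      if (adj[[p]]) {
        free <- which(is.na(slots))
        cand <- free[free < k]
        cand <- cand[is.na(slots[cand + 1L])]
        if (length(cand)) {
          s <- .resample(cand)
          slots[c(s, s + 1L)] <- pair
          placed <- TRUE
        }
      }
      if (!placed) {
        free <- which(is.na(slots))
        slots[free[sample.int(length(free), 2L)]] <- pair
      }
    }
    for (h in gh$herb[ing]) {
      free <- which(is.na(slots))
      slots[.resample(free)] <- h
    }
    free <- which(is.na(slots))
    if (length(free)) {
      pool <- setdiff(fillers, slots)
      if (length(pool) < length(free))        # tiny corpora: top up
        pool <- c(pool, setdiff(herbs, c(slots, pool)))
      slots[free] <- pool[sample.int(length(pool), length(free))]
    }
    out[[i]] <- slots
  }
  formula_corpus(out, sprintf("S%04d", seq_len(spec$m_formulae)))
}

#' Specification of a synthetic omics context
#'
#' Drives [generate_omics()]: a random gene interaction network, herb and
#' disease gene sets with a tunable shared fraction, random pathway sets,
#' and a phenotype-by-feature matrix with planted similar blocks.
#'
#' @param n_genes number of genes.
#' @param model `"erdos_renyi"` (edge probability `density`) or
#'   `"scale_free"` (preferential attachment, `attachment` edges per node).
#' @param density edge probability for the Erdos-Renyi model.
#' @param attachment edges per new node for the scale-free model.
#' @param n_herbs,n_diseases number of herb / disease gene sets.
#' @param herb_set_size,disease_set_size integer ranges `c(lo, hi)`.
#' @param herb_disease_overlap fraction of each disease set drawn from the
#'   pooled herb genes; the remainder is drawn from genes outside that
#'   pool, so 0 guarantees no herb-disease gene overlap.
#' @param n_pathways,pathway_size pathway count and size range.
#' @param n_phenotypes,n_features phenotype matrix dimensions.
#' @param n_blocks number of planted similarity blocks.
#' @param block_similarity mixing weight in `[0, 1]` between the block's
#'   shared base vector and per-phenotype noise; 1 makes block members
#'   identical (within-block cosine 1).
#' @param seed integer seed.
#' @return an object of class `net_spec`.
#' @export
net_spec <- function(n_genes = 200L, model = c("erdos_renyi", "scale_free"),
                     density = 0.04, attachment = 2L, n_herbs = 6L,
                     n_diseases = 8L, herb_set_size = c(8L, 15L),
                     disease_set_size = c(8L, 15L),
                     herb_disease_overlap = 0.3, n_pathways = 15L,
                     pathway_size = c(10L, 40L), n_phenotypes = 40L,
                     n_features = 25L, n_blocks = 4L,
                     block_similarity = 0.8, seed = 1L) {
  model <- match.arg(model)
  if (herb_disease_overlap < 0 || herb_disease_overlap > 1 ||
      block_similarity < 0 || block_similarity > 1 ||
      density < 0 || density > 1)
    stop("rates must lie in [0, 1]")
  structure(list(n_genes = as.integer(n_genes), model = model,
                 density = density, attachment = as.integer(attachment),
                 n_herbs = as.integer(n_herbs),
                 n_diseases = as.integer(n_diseases),
                 herb_set_size = as.integer(herb_set_size),
                 disease_set_size = as.integer(disease_set_size),
                 herb_disease_overlap = herb_disease_overlap,
                 n_pathways = as.integer(n_pathways),
                 pathway_size = as.integer(pathway_size),
                 n_phenotypes = as.integer(n_phenotypes),
                 n_features = as.integer(n_features),
                 n_blocks = as.integer(n_blocks),
                 block_similarity = block_similarity,
                 seed = as.integer(seed)),
            class = "net_spec")
}

#' Generate a synthetic omics context
#'
#' @param spec a [net_spec()].
#' @return an object of class `omics_context`: list with `ppi` (named
#'   undirected `igraph`), `pathways`, `herb_genes`, `disease_genes`
#'   (named gene-set lists), `phenotypes` (matrix), `phenotype_blocks`
#'   (named block membership), `background` (all genes) and `disease_pool`
#'   (networked genes, degree >= 1).
#' @export
generate_omics <- function(spec) {
  stopifnot(inherits(spec, "net_spec"))
  set.seed(spec$seed)
  genes <- sprintf("g%04d", seq_len(spec$n_genes))

  g <- if (spec$model == "erdos_renyi") {
    igraph::sample_gnp(spec$n_genes, spec$density)
  } else {
    igraph::sample_pa(spec$n_genes, power = 1, m = spec$attachment,
                      directed = FALSE)
  }
  igraph::V(g)$name <- genes

  draw_size <- function(rng) .resample(seq.int(rng[1L], rng[2L]))
  herb_genes <- stats::setNames(
    lapply(seq_len(spec$n_herbs),
           function(i) sample(genes, draw_size(spec$herb_set_size))),
    sprintf("Herb%02d", seq_len(spec$n_herbs)))
  hu <- unique(unlist(herb_genes, use.names = FALSE))
  outside <- setdiff(genes, hu)

  disease_genes <- stats::setNames(
    lapply(seq_len(spec$n_diseases), function(i) {
      s <- draw_size(spec$disease_set_size)
      n_ov <- min(round(spec$herb_disease_overlap * s), length(hu))
      ov <- if (n_ov) sample(hu, n_ov) else character(0)
      rest <- sample(outside, min(s - n_ov, length(outside)))
      union(ov, rest)
    }),
    sprintf("Dis%02d", seq_len(spec$n_diseases)))

  pathways <- stats::setNames(
    lapply(seq_len(spec$n_pathways),
           function(i) sample(genes, draw_size(spec$pathway_size))),
    sprintf("PW%02d", seq_len(spec$n_pathways)))

  blocks <- sort(rep_len(seq_len(spec$n_blocks), spec$n_phenotypes))
  base <- matrix(stats::runif(spec$n_blocks * spec$n_features),
                 spec$n_blocks, spec$n_features)
  s <- spec$block_similarity
  phen <- t(vapply(seq_len(spec$n_phenotypes), function(i) {
    s * base[blocks[[i]], ] + (1 - s) * stats::runif(spec$n_features)
  }, numeric(spec$n_features)))
  rownames(phen) <- sprintf("Ph%03d", seq_len(spec$n_phenotypes))
  names(blocks) <- rownames(phen)

  structure(list(ppi = g, pathways = pathways, herb_genes = herb_genes,
                 disease_genes = disease_genes, phenotypes = phen,
                 phenotype_blocks = blocks, background = genes,
                 disease_pool = genes[igraph::degree(g) > 0]),
            class = "omics_context")
}
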