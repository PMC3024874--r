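# Independent brute-force oracles, computed straight from formula lists and
# adjacency lists (no position matrices, no igraph), used to cross-check
# the package implementation.

table1_corpus <- function() {
  load_corpus(system.file("extdata", "table1_formulae.tsv",
                          package = "herbnet"))
}

# direct loops over the herb-name lists: counts, MI, mean distance, score,
# Pearson chi-square from the textbook 2x2 formula
oracle_pair_stats <- function(formula_lists, x, y,
                              mi_form = "pmi", score_form = "ratio") {
  m <- length(formula_lists)
  n_x <- n_y <- n_xy <- 0L
  dsum <- 0
  for (f in formula_lists) {
    ix <- match(x, f)
    iy <- match(y, f)
    if (!is.na(ix)) n_x <- n_x + 1L
    if (!is.na(iy)) n_y <- n_y + 1L
    if (!is.na(ix) && !is.na(iy)) {
      n_xy <- n_xy + 1L
      k <- length(f)
      dsum <- dsum + abs(ix / k - iy / k)
    }
  }
  px <- n_x / m; py <- n_y / m; pxy <- n_xy / m
  mi <- if (mi_form == "pmi") {
    if (pxy == 0) 0 else pxy * log2(pxy / (px * py))
  } else {
    p <- c(pxy, px - pxy, py - pxy, 1 - px - py + pxy)
    e <- c(px * py, px * (1 - py), (1 - px) * py, (1 - px) * (1 - py))
    ok <- p > 0
    sum(p[ok] * log2(p[ok] / e[ok]))
  }
  d_bar <- if (n_xy > 0L) dsum / n_xy else NA_real_
  score <- if (n_xy > 0L) {
    if (score_form == "ratio") mi / d_bar else mi * (1 - d_bar)
  } else NA_real_
  a <- n_xy; b <- n_x - n_xy; cc <- n_y - n_xy; d <- m - n_x - n_y + n_xy
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    chi2 <- NA_real_; p_value <- 1
  } else {
    chi2 <- m * (a * d - b * cc)^2 / (r1 * r2 * c1 * c2)
    p_value <- pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  list(n_x = n_x, n_y = n_y, n_xy = n_xy, mi = mi, d_bar = d_bar,
       score = score, chi2 = chi2, p_value = p_value)
}

random_formula_lists <- function(n_herbs, m, seed) {
  set.seed(seed)
  herbs <- paste0("h", seq_len(n_herbs))
  lapply(seq_len(m), function(i) {
    sample(herbs, sample(2:min(6L, n_herbs), 1L))
  })
}

# plain-R BFS over an adjacency list (named list of character neighbors)
oracle_bfs_dist <- function(adj, from) {
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[[from]] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!is.finite(dist[[w]])) {
        dist[[w]] <- dist[[v]] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# mean shortest path over cross pairs with distinct endpoints, connected
# pairs only, via repeated BFS
oracle_mean_cross_path <- function(adj, set_a, set_b) {
  d <- c()
  for (a in set_a) {
    da <- oracle_bfs_dist(adj, a)
    for (b in set_b) {
      if (a != b) d <- c(d, da[[b]])
    }
  }
  fin <- is.finite(d)
  list(mean = mean(d[fin]), coverage = mean(fin))
}

igraph_to_adj <- function(g) {
  vn <- igraph::V(g)$name
  adj <- lapply(igraph::adjacent_vertices(g, vn), names)
  names(adj) <- vn
  lapply(adj, function(x) if (is.null(x)) character(0) else x)
}

random_test_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- paste0("g", seq_len(n))
  g
}
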