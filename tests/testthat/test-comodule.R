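# Enrichment, gene-set closeness, phenotype similarity and the tripartite
# co-module projection.

path_graph <- function(nodes) {
  igraph::graph_from_data_frame(
    data.frame(from = nodes[-length(nodes)], to = nodes[-1]),
    directed = FALSE)
}

test_that("enrichment p equals the direct hypergeometric tail sum", {
  bg <- paste0("g", 1:100)
  pw <- list(PW1 = bg[1:50])
  gs <- bg[1:5]
  res <- pathway_enrichment(gs, pw, bg)
  # oracle: direct summation of the hypergeometric pmf over k..min(n, K)
  oracle <- sum(dhyper(5:5, 50, 50, 5))
  expect_equal(res$fisher_p, oracle, tolerance = 1e-10)
  expect_equal(oracle, choose(50, 5) / choose(100, 5))
  expect_equal(res$fdr, res$fisher_p)  # single pathway: BH is the identity

  # zero overlap -> upper tail P(X >= 0) = 1
  res0 <- pathway_enrichment(bg[51:55], list(PW1 = bg[1:50],
                                             PW2 = bg[40:60]), bg)
  expect_equal(res0$fisher_p[res0$pathway_id == "PW1"], 1)

  expect_error(pathway_enrichment("nope", pw, bg), "no members")
})

test_that("BH-adjusted values are monotone in the raw p ranking", {
  set.seed(4)
  bg <- paste0("g", 1:200)
  pws <- setNames(lapply(1:12, function(i) sample(bg, 30)),
                  paste0("PW", 1:12))
  res <- pathway_enrichment(sample(bg, 20), pws, bg)
  ord <- order(res$fisher_p)
  expect_true(all(diff(res$fdr[ord]) >= -1e-15))
  expect_true(all(res$fdr >= res$fisher_p - 1e-15))
  expect_equal(res$fdr, p.adjust(res$fisher_p, "BH"))
})

test_that("average shortest path enumerates connected cross pairs", {
  g <- path_graph(c("a", "b", "c"))
  r <- average_shortest_path(g, "a", "c")
  expect_equal(r$mean, 2)
  expect_equal(r$coverage, 1)

  r2 <- average_shortest_path(g, c("a", "b"), "c")
  expect_equal(r2$mean, (2 + 1) / 2)

  # symmetric in the two sets
  expect_equal(average_shortest_path(g, "c", c("a", "b"))$mean, r2$mean)

  # shared genes contribute cross pairs, never self-pairs
  r3 <- average_shortest_path(g, c("a", "b"), c("b", "c"))
  expect_equal(r3$n_pairs, 3)   # (a,b), (a,c), (b,c); (b,b) excluded
  expect_equal(r3$mean, (1 + 2 + 1) / 3)

  # disconnected pair is an error
  g2 <- igraph::graph_from_data_frame(data.frame(from = "a", to = "x"),
                                      directed = FALSE,
                                      vertices = data.frame(name = c("a", "x", "b")))
  expect_error(average_shortest_path(g2, "a", "b"), "no connected cross pair")
})

test_that("average shortest path equals the brute-force BFS oracle", {
  for (seed in 1:8) {
    g <- random_test_graph(n = sample(10:40, 1), p = 0.12, seed = seed)
    adj <- igraph_to_adj(g)
    vn <- igraph::V(g)$name
    set.seed(seed + 100)
    sa <- sample(vn, 4)
    sb <- sample(vn, 5)
    o <- oracle_mean_cross_path(adj, sa, sb)
    if (!is.finite(o$mean)) next
    r <- average_shortest_path(g, sa, sb)
    expect_equal(r$mean, o$mean, tolerance = 1e-12)
    expect_equal(r$coverage, o$coverage, tolerance = 1e-12)
  }
})

test_that("closeness permutation uses the plus-one convention and a seed", {
  # star-ish graph: b adjacent to a; every pool gene two steps away
  ed <- rbind(data.frame(from = "a", to = "b"),
              data.frame(from = "a", to = "x"),
              data.frame(from = "x", to = paste0("y", 1:6)))
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  pool <- paste0("y", 1:6)

  # observed (a-b distance 1) beats every permuted draw from the pool
  r <- closeness_permutation(g, "a", "b", pool, n_perm = 50, seed = 1)
  expect_equal(r$p_value, 1 / 51)

  # observed worse than anything the pool offers -> p = 1
  r2 <- closeness_permutation(g, "b", paste0("y", 1), pool[-1],
                              n_perm = 50, seed = 1)
  expect_equal(r2$p_value, 1)

  # seeded runs reproduce exactly
  ra <- closeness_permutation(g, "a", pool[1:2], pool, n_perm = 30, seed = 7)
  rb <- closeness_permutation(g, "a", pool[1:2], pool, n_perm = 30, seed = 7)
  expect_identical(ra$permuted, rb$permuted)

  expect_error(closeness_permutation(g, "a", pool, pool[1:2], n_perm = 10),
               "smaller than the draw")
})

test_that("phenotype similarity is the mean pairwise cosine", {
  M <- rbind(p1 = c(1, 1, 0), p2 = c(1, 1, 0), p3 = c(0, 0, 2),
             p4 = c(0, 1, 1))
  expect_equal(phenotype_similarity(M, c("p1", "p2")), 1)
  expect_equal(phenotype_similarity(M, c("p1", "p3")), 0)
  expect_equal(phenotype_similarity(M, c("p1", "p4")), 0.5)
  # mean over the three unordered pairs
  expect_equal(phenotype_similarity(M, c("p1", "p2", "p3")), (1 + 0 + 0) / 3)

  Mz <- rbind(p1 = c(1, 0), pz = c(0, 0))
  expect_error(phenotype_similarity(Mz, c("p1", "pz")), "pz")
  expect_error(phenotype_similarity(M, "p1"), "at least two")
})

test_that("phenotype permutation is degenerate at full membership and detects planted blocks", {
  M <- matrix(runif(40), 8, 5, dimnames = list(paste0("p", 1:8), NULL))
  r <- phenotype_permutation(M, rownames(M), n_perm = 25, seed = 1)
  expect_equal(r$p_value, 1)

  om <- generate_omics(net_spec(n_phenotypes = 30, n_blocks = 3,
                                block_similarity = 0.95, seed = 11))
  members <- names(om$phenotype_blocks)[om$phenotype_blocks == 1]
  rp <- phenotype_permutation(om$phenotypes, members, n_perm = 200, seed = 2)
  expect_lt(rp$p_value, 0.05)
})

test_that("co-module projection weights edges by shared genes and finds core genes", {
  herbs <- list(H1 = c("g1", "g2", "g3"), H2 = c("g2", "g3", "g4"),
                H3 = c("g9"))
  dis <- list(D1 = c("g2", "g7"), D2 = c("g7", "g8"))
  cm <- build_comodule(herbs, dis)
  hed <- igraph::as_data_frame(cm$herb_module, "edges")
  expect_equal(nrow(hed), 1)
  expect_equal(hed$weight, 2)          # H1 and H2 share g2, g3
  ded <- igraph::as_data_frame(cm$disease_module, "edges")
  expect_equal(ded$weight, 1)          # D1 and D2 share g7
  expect_equal(cm$core_genes, "g2")    # in >= 1 herb set and >= 1 disease set
  expect_false(cm$core_empty)

  # toy from first principles: H1 {g1,g2}, H2 {g2}; D1 {g2,g3} -> core g2
  cm2 <- build_comodule(list(H1 = c("g1", "g2"), H2 = "g2"),
                        list(D1 = c("g2", "g3"), D2 = "g3"))
  expect_equal(cm2$core_genes, "g2")

  # no herb-disease overlap -> flagged empty core
  cm3 <- build_comodule(list(H1 = "g1", H2 = "g2"),
                        list(D1 = "g8", D2 = "g9"))
  expect_true(cm3$core_empty)
  expect_equal(length(cm3$core_genes), 0)

  expect_error(build_comodule(list(H1 = "g1"), dis), "at least two")
  expect_error(build_comodule(list(H1 = "g1", H2 = character(0)), dis),
               "empty gene mapping for H2")
})

test_that("co-module statistics are wired through and seed-reproducible", {
  om <- generate_omics(net_spec(seed = 5))
  members <- names(om$phenotype_blocks)[om$phenotype_blocks == 1]
  run <- function() build_comodule(om$herb_genes, om$disease_genes,
                                   ppi = om$ppi, disease_pool = om$disease_pool,
                                   phenotypes = om$phenotypes,
                                   phenotype_members = members,
                                   n_perm = 60, seed = 9)
  a <- run()
  b <- run()
  expect_identical(a$closeness_p, b$closeness_p)
  expect_identical(a$phenotype_p, b$phenotype_p)
  expect_gt(a$closeness, 0)
  expect_true(a$closeness_p > 0 && a$closeness_p <= 1)

  # neighborhood = 1 can only grow the biomolecular layer
  cm0 <- build_comodule(om$herb_genes, om$disease_genes, ppi = om$ppi)
  cm1 <- build_comodule(om$herb_genes, om$disease_genes, ppi = om$ppi,
                        neighborhood = 1)
  expect_true(all(cm0$core_genes %in% cm1$core_genes))
})
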