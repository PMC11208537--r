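test_that("prevalence filter keeps core OTUs by presence count", {
  counts <- matrix(0L, 10, 3, dimnames = list(paste0("S", 1:10),
                                              c("full", "nine", "five")))
  counts[, "full"] <- 5L
  counts[1:9, "nine"] <- 3L
  counts[1:5, "five"] <- 8L
  ot <- otu_table(counts)
  expect_equal(colnames(prevalence_filter(ot, 0.9)$counts), c("full", "nine"))
  expect_equal(ncol(prevalence_filter(ot, 1e-9)$counts), 3)
  expect_equal(colnames(prevalence_filter(ot, 1)$counts), "full")
  expect_error(prevalence_filter(otu_table(counts[1:7, c(1, 3)]), 0.9), NA)
  tiny <- otu_table(rbind(S1 = c(a = 1L, b = 0L), S2 = c(a = 0L, b = 1L),
                          S3 = c(a = 1L, b = 1L)))
  expect_error(prevalence_filter(tiny, 1), "lower min_prevalence")
})

test_that("correlation matrix is symmetric with unit diagonal", {
  set.seed(8)
  counts <- matrix(rpois(45 * 6, 50), 45, 6)
  counts[, 2] <- 2L * counts[, 1]   # perfect collinearity survives the log
  ot <- otu_table(counts)
  r <- correlation_matrix(ot)
  expect_equal(r[1, 2], 1, tolerance = 1e-3)  # pseudo-fraction shifts it slightly
  expect_identical(r, t(r))
  expect_equal(unname(diag(r)), rep(1, ncol(r)))
  expect_true(all(abs(r) <= 1 + 1e-12))
  expect_error(correlation_matrix(otu_table(counts[1:3, ])), ">= 4 samples")
})

test_that("independent taxa are uncorrelated on average", {
  set.seed(123)
  r_ab <- replicate(1000, {
    counts <- cbind(a = rpois(45, 10), b = rpois(45, 10), bg = rep(10000L, 45))
    rownames(counts) <- paste0("S", 1:45)
    correlation_matrix(otu_table(counts), transform = "none")["a", "b"]
  })
  expect_lt(abs(mean(r_ab)), 0.02)
})

test_that("network construction thresholds |r| and drops isolated nodes", {
  R <- matrix(0.9, 3, 3); diag(R) <- 1
  dimnames(R) <- list(c("a", "b", "c"), c("a", "b", "c"))
  tri <- build_network(R, 0.8)
  expect_equal(igraph::vcount(tri), 3)
  expect_equal(igraph::ecount(tri), 3)
  expect_equal(sort(unique(igraph::E(tri)$weight)), 0.9)
  expect_error(build_network(R, 0.95), "empty")
  # raising the threshold never adds edges or nodes
  Rp <- planted_corr(seed = 5)
  prev_e <- Inf; prev_n <- Inf
  for (st in c(0.3, 0.5, 0.7, 0.9)) {
    g <- build_network(Rp, st)
    expect_lte(igraph::ecount(g), prev_e)
    expect_lte(igraph::vcount(g), prev_n)
    expect_true(all(igraph::E(g)$weight >= st))
    expect_true(all(igraph::degree(g) >= 1))
    prev_e <- igraph::ecount(g); prev_n <- igraph::vcount(g)
  }
})

test_that("topology matches hand computations on closed-form graphs", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  tt <- network_topology(tri)
  expect_equal(tt$avg_k, 2)
  expect_equal(tt$gd, 1)
  expect_equal(tt$avg_cc, 1)

  path <- igraph::make_graph(~ a - b, b - c)
  tp <- network_topology(path)
  expect_equal(tp$avg_k, 4 / 3)
  expect_equal(tp$gd, 4 / 3)
  expect_equal(tp$avg_cc, 0)
  expect_equal(tp$power_law_r2, 1)   # two occupied degrees: collinear in log-log

  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  expect_equal(network_topology(k5)$modularity_q, 0)
})

test_that("greedy modularity recovers disjoint cliques", {
  two_tri <- igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d)
  mod <- detect_modules(two_tri)
  expect_equal(length(mod$sizes), 2)
  expect_equal(mod$modularity, 0.5)   # 2 * (3/6 - (6/12)^2)
  expect_equal(as.integer(mod$sizes), c(3L, 3L))
  # Q of the greedy partition beats the trivial single-module partition
  set.seed(2)
  g <- igraph::sample_gnp(40, 0.1)
  igraph::V(g)$name <- paste0("n", 1:40)
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  expect_gte(detect_modules(g)$modularity, 0)
})

test_that("planted modules are recovered from the correlation structure", {
  R <- planted_corr(n_blocks = 5, block_size = 20, seed = 3)
  scan <- suppressWarnings(rmt_threshold(R))
  expect_gte(scan$st, 0.4)
  expect_lte(scan$st, 0.84)
  net <- build_network(R, scan$st)
  expect_equal(igraph::components(net)$no, 5)
  mod <- detect_modules(net)
  truth <- attr(R, "block")[igraph::V(net)$name]
  expect_gt(adjusted_rand(mod$membership, truth), 0.9)
})

test_that("null ensemble preserves degrees and is seed-deterministic", {
  R <- planted_corr(n_blocks = 3, block_size = 12, seed = 4)
  net <- build_network(R, 0.6)
  nl <- null_model_ensemble(net, n_random = 100, seed = 5)
  expect_true(nl$degree_preserved)
  nl2 <- null_model_ensemble(net, n_random = 100, seed = 5)
  expect_identical(nl, nl2)
  # planted modularity far exceeds the degree-preserving null
  expect_gt(nl$modularity$z, 3)
  expect_error(null_model_ensemble(igraph::make_full_graph(4)), "degenerate")
})

test_that("Zi-Pi roles follow the participation formulas", {
  # star: centre concentrates within-module degree
  star <- igraph::make_star(11, mode = "undirected")
  igraph::V(star)$name <- paste0("v", 1:11)
  mod1 <- structure(list(membership = setNames(rep(1L, 11), paste0("v", 1:11)),
                         sizes = table(rep(1, 11)), modularity = 0),
                    class = "module_set")
  r <- node_roles(star, mod1)
  expect_equal(sum(r$role == "module_hub"), 1)
  expect_gt(r$zi[r$node == "v1"], 2.5)
  expect_equal(r$pi, rep(0, 11))      # all links inside the single module

  # degree-4 node split 2/2 across two modules: pi = 0.5
  g <- igraph::make_graph(~ x - a1, x - a2, x - b1, x - b2,
                          a1 - a2, b1 - b2)
  memb <- setNames(c(1L, 1L, 1L, 2L, 2L), c("x", "a1", "a2", "b1", "b2"))
  mod2 <- structure(list(membership = memb, sizes = table(memb),
                         modularity = 0), class = "module_set")
  r2 <- node_roles(g, mod2)
  expect_equal(r2$pi[r2$node == "x"], 0.5)
  expect_true(all(table(r2$role) >= 0))   # every node has exactly one role
  expect_equal(nrow(r2), 5)
  # degree decomposition: sum_s k_is = k_i holds implicitly via pi <= 1 - 1/M
  expect_true(all(r2$pi <= 1 - 1 / 2 + 1e-12))
})

test_that("module-environment Mantel detects gradient-driven modules", {
  b <- generate_dataset(generator_params(n_taxa = 300, n_modules = 3,
                                         module_size_range = c(15, 20),
                                         loading = 1.5, noise_sd = 0.3,
                                         seed = 21))
  core <- prevalence_filter(b$otu, 0.9)
  corr <- correlation_matrix(core)
  scan <- rmt_threshold(corr)
  net <- build_network(corr, scan$st)
  mod <- detect_modules(net)
  env <- data.frame(ph = b$soil$ph, tn = b$soil$tn,
                    row.names = b$soil$sample_id)
  mm <- suppressWarnings(
    module_environment_mantel(core, mod, env, permutations = 199, seed = 3))
  expect_true(all(c("module", "variable", "r", "p_value") %in% names(mm)))
  expect_true(all(mm$p_value >= 1 / 200))
  # identical joint reordering of samples leaves r unchanged
  set.seed(9)
  perm <- sample(nrow(core$counts))
  core_p <- otu_table(core$counts[perm, ], core$taxonomy)
  env_p <- env[perm, , drop = FALSE]
  mm_p <- suppressWarnings(
    module_environment_mantel(core_p, mod, env_p, permutations = 199, seed = 3))
  expect_equal(mm_p$r, mm$r)
})

test_that("exports round-trip through graphml, gexf and edge lists", {
  R <- planted_corr(n_blocks = 2, block_size = 8, seed = 6)
  net <- build_network(R, 0.6)
  mod <- detect_modules(net)
  roles <- node_roles(net, mod)
  tax <- setNames(paste0("Bacteria;Phy", attr(R, "block")), rownames(R))

  f1 <- tempfile(fileext = ".graphml")
  export_network(net, f1, "graphml", mod, roles, tax)
  g2 <- igraph::read_graph(f1, format = "graphml")
  expect_equal(igraph::vcount(g2), igraph::vcount(net))
  expect_equal(igraph::ecount(g2), igraph::ecount(net))
  expect_equal(sort(unique(igraph::V(g2)$module)),
               sort(unique(unname(mod$membership))))

  f2 <- tempfile(fileext = ".gexf")
  export_network(net, f2, "gexf", mod, roles, tax)
  x <- xml2::read_xml(f2)
  ns <- xml2::xml_ns(x)
  expect_equal(length(xml2::xml_find_all(x, "//d1:node", ns)),
               igraph::vcount(net))
  expect_equal(length(xml2::xml_find_all(x, "//d1:edge", ns)),
               igraph::ecount(net))

  f3 <- tempfile(fileext = ".tsv")
  export_network(net, f3, "edgelist_tsv")
  el <- read.delim(f3)
  expect_equal(nrow(el), igraph::ecount(net))
  expect_true(all(c("from", "to", "weight", "sign") %in% names(el)))
})
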