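# Co-occurrence network construction and analysis: prevalence filter,
# Pearson correlation on transformed relative abundances, RMT-thresholded
# graph, topology, greedy modularity, degree-preserving null ensemble,
# Zi-Pi node roles, per-module environment Mantel tests and export.

#' Prevalence filter
#'
#' Keeps OTUs with a nonzero count in at least
#' `ceiling(min_prevalence * n_samples)` samples (core taxa); the sample
#' set is unchanged.
#'
#' @param table an [otu_table].
#' @param min_prevalence required presence fraction in (0, 1\]; default
#'   0.9.
#' @return filtered [otu_table].
#' @export
prevalence_filter <- function(table, min_prevalence = 0.9) {
  if (min_prevalence <= 0 || min_prevalence > 1)
    stop("min_prevalence must be in (0, 1]", call. = FALSE)
  counts <- table$counts
  need <- ceiling(min_prevalence * nrow(counts))
  keep <- colSums(counts > 0) >= need
  if (!any(keep))
    stop("no OTU present in >= ", need,
         " samples; lower min_prevalence", call. = FALSE)
  otu_table(counts[, keep, drop = FALSE],
            if (!is.null(table$taxonomy)) table$taxonomy[keep])
}

#' Pairwise Pearson correlation of OTUs
#'
#' Converts counts to per-sample relative abundances and (by default)
#' log10-transforms them after adding half the smallest nonzero relative
#' abundance as a pseudo-fraction, then computes the Pearson correlation
#' between OTU profiles. OTUs with zero variance after the transform are
#' excluded with a warning. The matrix is symmetrised and the diagonal set
#' to exactly 1.
#'
#' @param table an [otu_table] with >= 4 samples and >= 2 OTUs.
#' @param transform `"log10_relabund"` (default) or `"none"`.
#' @return correlation matrix with OTU ids as dimnames; attribute
#'   `transform` records the choice.
#' @export
correlation_matrix <- function(table, transform = c("log10_relabund", "none")) {
  transform <- match.arg(transform)
  counts <- table$counts
  if (nrow(counts) < 4) stop("need >= 4 samples", call. = FALSE)
  if (ncol(counts) < 2) stop("need >= 2 OTUs", call. = FALSE)
  rel <- counts / rowSums(counts)
  x <- if (transform == "log10_relabund") {
    pseudo <- min(rel[rel > 0]) / 2
    log10(rel + pseudo)
  } else rel
  v <- apply(x, 2, stats::sd)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance OTU(s) excluded from correlation",
            call. = FALSE)
    x <- x[, v > 0, drop = FALSE]
  }
  r <- stats::cor(x)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  attr(r, "transform") <- transform
  r
}

#' Build the thresholded co-occurrence network
#'
#' Undirected graph with an edge between OTUs i and j iff |r_ij| >= `st`;
#' edge attributes `weight` (= |r|), `sign` (+1/-1) and `r`. Isolated
#' nodes are removed.
#'
#' @param corr correlation matrix (e.g. [correlation_matrix()]).
#' @param st threshold in (0, 1), e.g. the St of [rmt_threshold()].
#' @return an [igraph::igraph] object with OTU ids as vertex names.
#' @export
build_network <- function(corr, st) {
  if (st <= 0 || st >= 1) stop("st must be in (0, 1)", call. = FALSE)
  corr <- as.matrix(corr)
  sel <- which(abs(corr) >= st & upper.tri(corr), arr.ind = TRUE)
  if (nrow(sel) == 0)
    stop("no edge at threshold ", st, " (empty network)", call. = FALSE)
  ids <- rownames(corr)
  if (is.null(ids)) ids <- paste0("OTU_", seq_len(nrow(corr)))
  r <- corr[sel]
  edges <- data.frame(from = ids[sel[, 1]], to = ids[sel[, 2]],
                      weight = abs(r), sign = sign(r), r = r,
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

.unweighted <- function(net) {
  if ("weight" %in% igraph::edge_attr_names(net))
    net <- igraph::delete_edge_attr(net, "weight")
  net
}

#' Topological summary of a network
#'
#' Reports node/link counts, average degree (avgK = 2E/N), average
#' geodesic distance (GD; mean shortest-path length over reachable pairs,
#' i.e. within components), average clustering coefficient (avgCC;
#' degree < 2 nodes contribute 0 unless `low_degree_zero = FALSE`, which
#' excludes them), edge density, the R-squared of an OLS fit of
#' log10 degree-frequency on log10 degree (scale-free check), and the
#' greedy-modularity Q of [detect_modules()].
#'
#' @param net an igraph network (>= 3 nodes).
#' @param low_degree_zero count degree < 2 nodes as clustering 0 (default
#'   TRUE) or exclude them.
#' @return list with `n_nodes`, `n_links`, `avg_k`, `gd`, `avg_cc`,
#'   `density`, `power_law_r2`, `modularity_q`.
#' @export
network_topology <- function(net, low_degree_zero = TRUE) {
  n <- igraph::vcount(net)
  if (n < 3) stop("need >= 3 nodes", call. = FALSE)
  e <- igraph::ecount(net)
  cc <- igraph::transitivity(net, type = "localundirected",
                             isolates = if (low_degree_zero) "zero" else "NaN")
  deg <- igraph::degree(net)
  tab <- table(deg[deg > 0])
  plr2 <- NA_real_
  if (length(tab) >= 2) {
    k <- as.numeric(names(tab))
    fit <- stats::lm(log10(as.numeric(tab)) ~ log10(k))
    plr2 <- summary(fit)$r.squared
  }
  list(n_nodes = n, n_links = e, avg_k = 2 * e / n,
       gd = igraph::mean_distance(net, weights = NA, directed = FALSE,
                                  unconnected = TRUE),
       avg_cc = mean(cc, na.rm = TRUE),
       density = igraph::edge_density(net),
       power_law_r2 = plr2,
       modularity_q = detect_modules(net)$modularity)
}

#' Greedy modularity module detection
#'
#' Clauset-Newman-Moore greedy agglomeration maximising the
#' Newman-Girvan modularity Q on the unweighted graph (edge presence
#' only; set `weighted = TRUE` to use |r| weights). Deterministic: the
#' igraph implementation breaks ties by vertex ordering.
#'
#' @param net an igraph network.
#' @param weighted use edge weights (default FALSE).
#' @return a `module_set` list: `membership` (named integer vector),
#'   `sizes` (module id -> node count), `modularity` (Q).
#' @export
detect_modules <- function(net, weighted = FALSE) {
  g <- if (weighted) net else .unweighted(net)
  cl <- igraph::cluster_fast_greedy(g)
  memb <- as.integer(igraph::membership(cl))
  q <- igraph::modularity(g, memb)
  if (q < 0) {               # never worse than the trivial one-module split
    memb <- rep(1L, igraph::vcount(g))
    q <- igraph::modularity(g, memb)
  }
  structure(list(membership = stats::setNames(memb, igraph::V(g)$name),
                 sizes = table(memb),
                 modularity = q),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("Module set: %d modules over %d nodes, Q = %.3f\n",
              length(x$sizes), length(x$membership), x$modularity))
  invisible(x)
}

#' Degree-preserving null-model ensemble
#'
#' Rewires the network `n_random` times with double-edge swaps that
#' preserve every node's degree exactly (10 x E attempted swaps per
#' replicate, rejecting self-loops and multi-edges), and summarises the
#' null distribution of average geodesic distance, average clustering
#' coefficient and greedy modularity against the empirical values.
#'
#' @param net an igraph network with >= 2 edges and a non-degenerate
#'   degree sequence (a complete graph admits no legal swap).
#' @param n_random ensemble size (default 100).
#' @param seed integer seed; the ensemble is deterministic given it.
#' @return list with `n_random`, `degree_preserved` (TRUE iff every
#'   replicate's sorted degree sequence equals the empirical one), and per
#'   metric (`gd`, `avg_cc`, `modularity`): `mean`, `sd` (n-1),
#'   `empirical`, `z`.
#' @export
null_model_ensemble <- function(net, n_random = 100, seed = 42) {
  e <- igraph::ecount(net)
  n <- igraph::vcount(net)
  if (e < 2) stop("need >= 2 edges", call. = FALSE)
  if (e == n * (n - 1) / 2)
    stop("degenerate degree sequence: complete graph admits no legal swap",
         call. = FALSE)
  g0 <- .unweighted(net)
  set.seed(seed)
  ds0 <- sort(igraph::degree(g0))
  degree_ok <- logical(n_random)
  met <- matrix(NA_real_, n_random, 3,
                dimnames = list(NULL, c("gd", "avg_cc", "modularity")))
  for (i in seq_len(n_random)) {
    g <- igraph::rewire(g0, igraph::keeping_degseq(niter = 10 * e))
    degree_ok[i] <- identical(sort(igraph::degree(g)), ds0)
    met[i, ] <- c(igraph::mean_distance(g, weights = NA, directed = FALSE,
                                        unconnected = TRUE),
                  mean(igraph::transitivity(g, type = "localundirected",
                                            isolates = "zero")),
                  detect_modules(g)$modularity)
  }
  emp <- c(gd = igraph::mean_distance(net, weights = NA, directed = FALSE,
                                      unconnected = TRUE),
           avg_cc = mean(igraph::transitivity(net, type = "localundirected",
                                              isolates = "zero")),
           modularity = detect_modules(net)$modularity)
  out <- list(n_random = n_random, degree_preserved = all(degree_ok))
  for (m in colnames(met)) {
    mu <- mean(met[, m]); s <- stats::sd(met[, m])
    out[[m]] <- list(mean = mu, sd = s, empirical = unname(emp[m]),
                     z = if (s > 0) (unname(emp[m]) - mu) / s else NA_real_)
  }
  out
}

#' Zi-Pi topological roles of network nodes
#'
#' Within-module degree z-score
#' \eqn{z_i = (k_{i,own} - \bar k_{own}) / sd(k_{own})} (over nodes of the
#' same module; sd = 0 gives z = 0) and among-module participation
#' \eqn{P_i = 1 - \sum_s (k_{is}/k_i)^2}. Roles follow the
#' Guimera-Amaral convention: module hub (z >= 2.5, P < 0.62), connector
#' (P >= 0.62, z < 2.5), network hub (both), else peripheral.
#'
#' @param net an igraph network.
#' @param modules a [detect_modules()] result covering its nodes.
#' @return data frame: `node`, `module`, `degree`, `zi`, `pi`, `role`.
#' @export
node_roles <- function(net, modules) {
  memb <- modules$membership[igraph::V(net)$name]
  if (anyNA(memb)) stop("partition does not cover the network", call. = FALSE)
  A <- igraph::as_adjacency_matrix(.unweighted(net), sparse = FALSE)
  mods <- sort(unique(memb))
  Ind <- outer(memb, mods, "==") + 0
  kis <- A %*% Ind                      # node x module link counts
  k <- rowSums(A)
  own <- kis[cbind(seq_along(memb), match(memb, mods))]
  zi <- numeric(length(k))
  for (m in mods) {
    sel <- memb == m
    s <- stats::sd(own[sel])
    zi[sel] <- if (is.na(s) || s == 0) 0 else (own[sel] - mean(own[sel])) / s
  }
  pi <- 1 - rowSums((kis / k)^2)
  role <- ifelse(zi >= 2.5 & pi >= 0.62, "network_hub",
          ifelse(zi >= 2.5, "module_hub",
          ifelse(pi >= 0.62, "connector", "peripheral")))
  data.frame(node = igraph::V(net)$name, module = as.integer(memb),
             degree = as.integer(k), zi = zi, pi = pi, role = role,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Merge soil and metal tables into one environmental matrix
#'
#' Numeric per-sample environmental variables (soil properties plus total
#' and DTPA metal concentrations), matched on `sample_id`; row names are
#' sample ids.
#'
#' @param soil a [read_soil_table] result (optional).
#' @param metals a [read_metal_table] result (optional).
#' @return numeric data frame, samples in rows.
#' @export
environment_table <- function(soil = NULL, metals = NULL) {
  if (is.null(soil) && is.null(metals))
    stop("need soil and/or metals", call. = FALSE)
  take <- function(df) {
    out <- df[vapply(df, is.numeric, logical(1))]
    rownames(out) <- df$sample_id
    out
  }
  if (is.null(metals)) return(take(soil))
  met <- as.data.frame(metals)
  met$pli_reported <- NULL
  if (is.null(soil)) return(take(met))
  m <- merge(as.data.frame(soil), met, by = "sample_id", sort = FALSE)
  take(m)
}

#' Mantel tests between network modules and environmental variables
#'
#' For each module with at least `min_module_size` member OTUs, the
#' Bray-Curtis distance between samples restricted to the member OTUs is
#' tested (Spearman Mantel, [mantel_test()]) against the Euclidean
#' distance on each z-scored environmental variable.
#'
#' @param table the [otu_table] the network was built from.
#' @param modules a [detect_modules()] result.
#' @param env numeric data frame of environmental variables (samples in
#'   rows, same order as `table`; see [environment_table()]).
#' @param permutations,seed passed to [mantel_test()].
#' @param min_module_size smaller modules are skipped with a warning.
#' @return data frame: `module`, `n_otus`, `variable`, `r`, `p_value`.
#' @export
module_environment_mantel <- function(table, modules, env,
                                      permutations = 999, seed = 42,
                                      min_module_size = 5) {
  counts <- table$counts
  env <- as.data.frame(env)
  if (nrow(env) != nrow(counts))
    stop("env and OTU table sample sets differ", call. = FALSE)
  memb <- modules$membership
  memb <- memb[names(memb) %in% colnames(counts)]
  out <- list()
  for (m in sort(unique(memb))) {
    otus <- names(memb)[memb == m]
    if (length(otus) < min_module_size) {
      warning("module ", m, " has < ", min_module_size, " OTUs; skipped",
              call. = FALSE)
      next
    }
    sub <- counts[, otus, drop = FALSE]
    if (any(rowSums(sub) == 0)) next
    d_comm <- bray_curtis_matrix(sub)
    for (v in names(env)) {
      d_env <- as.matrix(stats::dist(scale(env[[v]])))
      dimnames(d_env) <- dimnames(d_comm)
      mt <- mantel_test(d_comm, d_env, method = "spearman",
                        permutations = permutations, seed = seed)
      out[[length(out) + 1]] <- data.frame(
        module = m, n_otus = length(otus), variable = v,
        r = mt$r, p_value = mt$p_value, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Export a network with module and role annotations
#'
#' Writes the network with node attributes (module id, zi, pi, role,
#' phylum) and edge attributes (weight, sign) as GraphML (via igraph),
#' GEXF 1.2 (Gephi's native format; written directly) or a plain TSV edge
#' list.
#'
#' @param net an igraph network.
#' @param path output file path.
#' @param format `"graphml"`, `"gexf"` or `"edgelist_tsv"`.
#' @param modules optional [detect_modules()] result.
#' @param roles optional [node_roles()] result.
#' @param taxonomy optional named lineage vector (`otu_table$taxonomy`);
#'   the second lineage field is exported as `phylum`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path,
                           format = c("graphml", "gexf", "edgelist_tsv"),
                           modules = NULL, roles = NULL, taxonomy = NULL) {
  format <- match.arg(format)
  g <- net
  vn <- igraph::V(g)$name
  if (!is.null(modules))
    g <- igraph::set_vertex_attr(g, "module",
                                 value = as.integer(modules$membership[vn]))
  if (!is.null(roles)) {
    ri <- match(vn, roles$node)
    g <- igraph::set_vertex_attr(g, "zi", value = roles$zi[ri])
    g <- igraph::set_vertex_attr(g, "pi", value = roles$pi[ri])
    g <- igraph::set_vertex_attr(g, "role", value = roles$role[ri])
  }
  if (!is.null(taxonomy)) {
    phylum <- vapply(strsplit(as.character(taxonomy[vn]), ";"), function(s)
      if (length(s) >= 2) trimws(s[2]) else "Unclassified", character(1))
    g <- igraph::set_vertex_attr(g, "phylum", value = phylum)
  }
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "edgelist_tsv") {
    el <- igraph::as_data_frame(g, what = "edges")
    utils::write.table(el, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    .write_gexf(g, path)
  }
  invisible(path)
}

# minimal GEXF 1.2 writer (igraph has no GEXF support)
.write_gexf <- function(g, path) {
  vattrs <- setdiff(igraph::vertex_attr_names(g), "name")
  vn <- .xml_escape(igraph::V(g)$name)
  att_decl <- paste(vapply(seq_along(vattrs), function(i) {
    a <- igraph::vertex_attr(g, vattrs[i])
    type <- if (is.numeric(a)) "double" else "string"
    sprintf('      <attribute id="%d" title="%s" type="%s"/>',
            i - 1, .xml_escape(vattrs[i]), type)
  }, character(1)), collapse = "\n")
  nodes <- vapply(seq_along(vn), function(v) {
    av <- paste(vapply(seq_along(vattrs), function(i) {
      val <- igraph::vertex_attr(g, vattrs[i])[v]
      sprintf('        <attvalue for="%d" value="%s"/>', i - 1,
              .xml_escape(as.character(val)))
    }, character(1)), collapse = "\n")
    if (length(vattrs))
      sprintf('      <node id="%s" label="%s">\n      <attvalues>\n%s\n      </attvalues>\n      </node>',
              vn[v], vn[v], av)
    else sprintf('      <node id="%s" label="%s"/>', vn[v], vn[v])
  }, character(1))
  el <- igraph::as_edgelist(g, names = TRUE)
  w <- if ("weight" %in% igraph::edge_attr_names(g))
    igraph::E(g)$weight else rep(1, nrow(el))
  sgn <- if ("sign" %in% igraph::edge_attr_names(g))
    igraph::E(g)$sign else rep(1, nrow(el))
  edges <- sprintf('      <edge id="%d" source="%s" target="%s" weight="%s" label="%s"/>',
                   seq_len(nrow(el)) - 1, .xml_escape(el[, 1]),
                   .xml_escape(el[, 2]), format(w, digits = 6),
                   ifelse(sgn >= 0, "positive", "negative"))
  xml <- c('<?xml version="1.0" encoding="UTF-8"?>',
           '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
           '  <graph mode="static" defaultedgetype="undirected">',
           '    <attributes class="node">', att_decl, '    </attributes>',
           '    <nodes>', nodes, '    </nodes>',
           '    <edges>', edges, '    </edges>',
           '  </graph>', '</gexf>')
  writeLines(xml, path, useBytes = TRUE)
  invisible(path)
}
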