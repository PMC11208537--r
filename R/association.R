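# Environment-community association statistics: polynomial regressions,
# Spearman taxon-environment grids, Mantel / partial Mantel permutation
# tests, variation partitioning and random-forest importance.

#' Polynomial regression of a diversity index on a soil variable
#'
#' Ordinary least squares of degree 1 or 2 with the overall F-test
#' p-value; for degree 2 the abscissa of the parabola vertex
#' (\eqn{-b/2a}) is reported, e.g. the soil-variable value at which the
#' fitted diversity response peaks.
#'
#' @param x,y finite numeric vectors of equal length, n >= degree + 2.
#' @param degree 1 (linear) or 2 (quadratic).
#' @return list with `degree`, `coefficients` (intercept first),
#'   `r_squared`, `p_value`, and `vertex_x` (degree 2 only).
#' @examples
#' fit_polynomial(1:10, 2 * (1:10) + 1, degree = 1)$r_squared
#' @export
fit_polynomial <- function(x, y, degree = 1) {
  if (!degree %in% 1:2) stop("degree must be 1 or 2", call. = FALSE)
  if (length(x) != length(y) || length(x) < degree + 2)
    stop("need n >= degree + 2 paired observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values", call. = FALSE)
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  coefs <- unname(stats::coef(fit))
  if (anyNA(coefs)) stop("degenerate (collinear) design", call. = FALSE)
  s <- summary(fit)
  fs <- s$fstatistic
  p <- stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  if (!is.finite(p)) p <- 0
  out <- list(degree = degree, coefficients = coefs,
              r_squared = s$r.squared, p_value = unname(p))
  if (degree == 2 && coefs[3] != 0)
    out$vertex_x <- -coefs[2] / (2 * coefs[3])
  out
}

#' Spearman correlation grid between taxa and soil variables
#'
#' Pairwise Spearman rank correlations (midranks for ties, t-approximation
#' p-values) between each taxon's relative abundance and each
#' environmental variable, with Benjamini-Hochberg adjustment across the
#' whole grid. Constant columns yield `NA` with a warning.
#'
#' @param taxa_abundance samples x taxa numeric matrix (e.g. phylum-level
#'   relative abundances).
#' @param env samples x variables numeric data frame or matrix, same row
#'   order as `taxa_abundance`.
#' @return data frame with columns `taxon`, `variable`, `rho`, `p`,
#'   `p_adjusted`.
#' @export
spearman_grid <- function(taxa_abundance, env) {
  ta <- as.matrix(taxa_abundance)
  ev <- as.data.frame(env)
  ev <- ev[vapply(ev, is.numeric, logical(1))]
  if (nrow(ta) != nrow(ev)) stop("sample sets do not match", call. = FALSE)
  grid <- expand.grid(taxon = colnames(ta), variable = names(ev),
                      stringsAsFactors = FALSE)
  res <- t(vapply(seq_len(nrow(grid)), function(i) {
    a <- ta[, grid$taxon[i]]; b <- ev[[grid$variable[i]]]
    keep <- stats::complete.cases(a, b)
    a <- a[keep]; b <- b[keep]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                           exact = FALSE))
    c(unname(ct$estimate), ct$p.value)
  }, numeric(2)))
  if (anyNA(res[, 1]))
    warning("constant column(s): rho undefined, emitted as NA", call. = FALSE)
  grid$rho <- res[, 1]
  grid$p <- res[, 2]
  grid$p_adjusted <- stats::p.adjust(grid$p, method = "BH")
  grid
}

# shared machinery: upper-triangle extraction with label checking
.mantel_prep <- function(dA, dB, context = "mantel") {
  A <- as.matrix(dA); B <- as.matrix(dB)
  if (nrow(A) != nrow(B)) stop(context, ": dimension mismatch", call. = FALSE)
  la <- rownames(A); lb <- rownames(B)
  if (!is.null(la) && !is.null(lb) && !identical(la, lb))
    stop(context, ": distance-matrix labels do not match", call. = FALSE)
  list(A = A, B = B, n = nrow(A))
}

# symmetric matrix whose upper-triangle values are replaced by `v`
.sym_from_ut <- function(v, n) {
  M <- matrix(0, n, n)
  M[upper.tri(M)] <- v
  M + t(M)
}

#' Mantel permutation test
#'
#' Correlation between the upper triangles of two distance matrices with a
#' permutation test: rows and columns of `dB` are permuted jointly and the
#' one-tailed (greater) p-value is
#' \eqn{(1 + \#\{r_{perm} \ge r_{obs}\})/(permutations + 1)}. With
#' `method = "spearman"` both triangles are midranked once (the multiset
#' of off-diagonal values is invariant under relabelling, so ranks are
#' permuted consistently). Deterministic given `seed`.
#'
#' @param dA,dB symmetric distance matrices with identical labels/order.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param permutations number of permutations (>= 99; default 999).
#' @param seed integer seed.
#' @return a `mantel_result` list: `r`, `p_value`, `permutations`,
#'   `method`, `partial = FALSE`.
#' @export
mantel_test <- function(dA, dB, method = c("spearman", "pearson"),
                        permutations = 999, seed = 42) {
  method <- match.arg(method)
  if (permutations < 99) stop("permutations must be >= 99", call. = FALSE)
  pr <- .mantel_prep(dA, dB)
  n <- pr$n
  ut <- upper.tri(pr$A)
  idx <- which(ut, arr.ind = TRUE)
  a <- pr$A[ut]; b <- pr$B[ut]
  if (method == "spearman") { a <- rank(a); b <- rank(b) }
  BM <- .sym_from_ut(b, n)
  r_obs <- stats::cor(a, b)
  set.seed(seed)
  r_perm <- vapply(seq_len(permutations), function(k) {
    p <- sample.int(n)
    stats::cor(a, BM[cbind(p[idx[, 1]], p[idx[, 2]])])
  }, numeric(1))
  structure(list(r = r_obs,
                 p_value = (1 + sum(r_perm >= r_obs)) / (permutations + 1),
                 permutations = permutations, method = method,
                 partial = FALSE),
            class = "mantel_result")
}

#' Partial Mantel permutation test
#'
#' First-order partial correlation of `dA` with `dB` controlling for `dC`:
#' \eqn{r_{AB.C} = (r_{AB} - r_{AC} r_{BC}) / \sqrt{(1-r_{AC}^2)(1-r_{BC}^2)}},
#' with the permutation scheme of [mantel_test()] applied to `dB` and the
#' partial statistic recomputed each draw (`r_AC` is unchanged by the
#' permutation).
#'
#' @inheritParams mantel_test
#' @param dC conditioning distance matrix.
#' @return a `mantel_result` with `partial = TRUE`.
#' @export
partial_mantel_test <- function(dA, dB, dC, method = c("spearman", "pearson"),
                                permutations = 999, seed = 42) {
  method <- match.arg(method)
  if (permutations < 99) stop("permutations must be >= 99", call. = FALSE)
  pr <- .mantel_prep(dA, dB, "partial mantel")
  pr2 <- .mantel_prep(dA, dC, "partial mantel")
  n <- pr$n
  ut <- upper.tri(pr$A)
  idx <- which(ut, arr.ind = TRUE)
  a <- pr$A[ut]; b <- pr$B[ut]; cc <- pr2$B[ut]
  if (method == "spearman") { a <- rank(a); b <- rank(b); cc <- rank(cc) }
  r_ac <- stats::cor(a, cc)
  if (abs(r_ac) >= 1 - 1e-12)
    stop("degenerate: |r_AC| = 1", call. = FALSE)
  partial_r <- function(bv) {
    r_ab <- stats::cor(a, bv); r_bc <- stats::cor(bv, cc)
    if (abs(r_bc) >= 1 - 1e-12) {
      # dB == dC: 0/0 whose limit is 0 when r_AB == r_AC; else undefined
      if (abs(r_ab - r_ac * r_bc) < 1e-9) return(0)
      stop("degenerate: |r_BC| = 1", call. = FALSE)
    }
    (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2) * (1 - r_bc^2))
  }
  r_obs <- partial_r(b)
  BM <- .sym_from_ut(b, n)
  set.seed(seed)
  r_perm <- vapply(seq_len(permutations), function(k) {
    p <- sample.int(n)
    partial_r(BM[cbind(p[idx[, 1]], p[idx[, 2]])])
  }, numeric(1))
  structure(list(r = r_obs,
                 p_value = (1 + sum(r_perm >= r_obs)) / (permutations + 1),
                 permutations = permutations, method = method,
                 partial = TRUE),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%sMantel (%s): r = %.4f, p = %.4g (%d permutations)\n",
              if (x$partial) "Partial " else "", x$method, x$r, x$p_value,
              x$permutations))
  invisible(x)
}

#' Variation partitioning between two predictor blocks
#'
#' Partitions the variance of a Hellinger-transformed community matrix
#' between two explanatory blocks (e.g. soil physicochemical properties
#' vs heavy metals) by redundancy analysis with Ezekiel-adjusted R-squared:
#' unique fractions a and c, shared fraction b, and the unexplained
#' residual. Built on [vegan::rda()] / [vegan::RsquareAdj()].
#'
#' @param community samples x taxa abundance matrix.
#' @param X1,X2 predictor blocks (data frame or matrix), full column rank.
#' @return list with `fractions` (named: `a`, `b`, `c`, `residual`,
#'   summing to 1), `adj_r_squared` (named: `X1`, `X2`, `both`) and
#'   `adjusted = TRUE`.
#' @export
variation_partition <- function(community, X1, X2) {
  Y <- as.matrix(community)
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  p <- ncol(X1) + ncol(X2)
  if (nrow(Y) <= p + 1)
    stop("need n > combined predictor count + 1", call. = FALSE)
  for (nm in c("X1", "X2")) {
    X <- get(nm)
    if (qr(scale(X, scale = FALSE))$rank < ncol(X))
      stop("rank-deficient predictor block: ", nm, call. = FALSE)
  }
  H <- vegan::decostand(Y, method = "hellinger")
  adj <- function(X) vegan::RsquareAdj(vegan::rda(H, X))$adj.r.squared
  a1 <- adj(X1); a2 <- adj(X2); a12 <- adj(cbind(X1, X2))
  fr <- c(a = a12 - a2, b = a1 + a2 - a12, c = a12 - a1, residual = 1 - a12)
  list(fractions = fr, adj_r_squared = c(X1 = a1, X2 = a2, both = a12),
       adjusted = TRUE)
}

#' Random-forest importance of soil variables
#'
#' Regression random forest ([randomForest::randomForest()]) with
#' out-of-bag permutation importance (%IncMSE); higher values mean the
#' predictor matters more for the response (e.g. a diversity index).
#' Deterministic given `seed`.
#'
#' @param X samples x predictors data frame or matrix (n >= 10).
#' @param y numeric response, not constant.
#' @param trees number of trees (>= 100; default 500).
#' @param seed integer seed.
#' @param mtry predictors tried per split; default `ceiling(p/3)`.
#' @return data frame sorted by rank: `variable`, `importance` (%IncMSE),
#'   `rank`.
#' @export
forest_importance <- function(X, y, trees = 500, seed = 42,
                              mtry = ceiling(ncol(X) / 3)) {
  X <- as.data.frame(X)
  if (nrow(X) < 10) stop("need n >= 10", call. = FALSE)
  if (trees < 100) stop("need trees >= 100", call. = FALSE)
  if (stats::sd(y) == 0) stop("constant response", call. = FALSE)
  set.seed(seed)
  rf <- randomForest::randomForest(x = X, y = y, ntree = trees, mtry = mtry,
                                   importance = TRUE)
  imp <- randomForest::importance(rf, type = 1, scale = TRUE)[, 1]
  out <- data.frame(variable = names(imp), importance = unname(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
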