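# Alpha diversity (Sobs, Chao1, ACE, Shannon, Good's coverage),
# coefficient of variation, Bray-Curtis dissimilarity and NMDS ordination.

.alpha_one <- function(x, chao1 = c("bias_corrected", "classic")) {
  chao1 <- match.arg(chao1)
  if (any(x < 0) || any(abs(x - round(x)) > 1e-6))
    stop("alpha diversity needs non-negative integer counts", call. = FALSE)
  x <- round(x)
  if (sum(x) == 0) stop("all-zero count vector", call. = FALSE)
  pos <- x[x > 0]
  sobs <- length(pos)
  f1 <- sum(pos == 1); f2 <- sum(pos == 2)
  n <- sum(pos)
  est <- vegan::estimateR(matrix(as.integer(x), nrow = 1))
  ch <- if (chao1 == "bias_corrected") unname(est["S.chao1", 1])
        else sobs + if (f2 > 0) f1^2 / (2 * f2) else f1 * (f1 - 1) / 2
  p <- pos / n
  shannon <- -sum(p * log2(p))
  list(sobs = sobs, chao1 = ch, ace = unname(est["S.ACE", 1]),
       shannon = shannon, coverage = 1 - f1 / n)
}

#' Alpha-diversity profile
#'
#' Computes observed richness (Sobs), the bias-corrected Chao1 estimator
#' \eqn{S + F_1(F_1-1)/(2(F_2+1))}, ACE (abundance-based coverage
#' estimator, rare-abundance cutoff 10), the Shannon index in bits
#' (\eqn{-\sum p_i \log_2 p_i}) and Good's coverage \eqn{1 - F_1/N}.
#' Chao1 and ACE are delegated to [vegan::estimateR()], which implements
#' exactly these variants; Shannon uses log base 2 so values are
#' comparable with QIIME 1.x output.
#'
#' @param x a non-negative integer count vector (one sample), a samples x
#'   taxa count matrix, or an [otu_table].
#' @param chao1 `"bias_corrected"` (default) or `"classic"`
#'   (\eqn{S + F_1^2/(2F_2)}).
#' @return data frame with one row per sample: `sample_id`, `sobs`,
#'   `chao1`, `ace`, `shannon`, `coverage`.
#' @examples
#' alpha_diversity(c(1, 1, 2, 5))
#' @export
alpha_diversity <- function(x, chao1 = c("bias_corrected", "classic")) {
  chao1 <- match.arg(chao1)
  if (inherits(x, "otu_table")) x <- x$counts
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list("S1", NULL))
  rows <- lapply(seq_len(nrow(x)), function(i)
    as.data.frame(c(list(sample_id = rownames(x)[i]), .alpha_one(x[i, ], chao1))))
  do.call(rbind, rows)
}

#' Coefficient of variation
#'
#' 100 x sample standard deviation (n-1 denominator) over the mean.
#'
#' @param values numeric vector with non-zero mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  m <- mean(values)
  if (m == 0) stop("mean is zero; CV undefined", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(x,y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} on raw counts,
#' via [vegan::vegdist()].
#'
#' @param x an [otu_table] or a samples x taxa abundance matrix with at
#'   least two rows.
#' @return symmetric matrix with zero diagonal, entries in \[0, 1\], sample
#'   ids as dimnames.
#' @export
bray_curtis_matrix <- function(x) {
  if (inherits(x, "otu_table")) x <- x$counts
  if (nrow(x) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(rowSums(x) == 0))
    stop("sample with zero total; Bray-Curtis undefined", call. = FALSE)
  as.matrix(vegan::vegdist(x, method = "bray"))
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 NMDS ([vegan::monoMDS()], global monotone regression)
#' run from a classical-scaling start plus `restarts - 1` seeded random
#' starts; the lowest-stress solution is kept. Coordinates are centred.
#' The sign of each axis is statistically arbitrary; axis 1 is
#' canonicalised so that its Pearson correlation with the rank of `depth`
#' (per-sample read totals, when supplied) is non-negative, otherwise so
#' that the sample with the largest absolute score is positive.
#'
#' @param d distance matrix (symmetric matrix or `dist`).
#' @param k number of ordination axes (>= 1).
#' @param restarts number of starts (>= 1; default 20).
#' @param seed integer seed; the run is deterministic given it.
#' @param depth optional per-sample read totals used for sign
#'   canonicalisation.
#' @return list with `coordinates` (samples x k, centred), `stress`
#'   (Kruskal stress-1 in \[0, 1\]), `seed`.
#' @export
nmds <- function(d, k = 2, restarts = 20, seed = 42, depth = NULL) {
  if (k < 1 || restarts < 1) stop("k and restarts must be >= 1", call. = FALSE)
  dm <- as.matrix(d)
  if (any(!is.finite(dm))) stop("non-finite distances", call. = FALSE)
  dd <- stats::as.dist(dm)
  n <- nrow(dm)
  set.seed(seed)
  best <- NULL
  starts <- vector("list", restarts)
  cmds <- suppressWarnings(stats::cmdscale(dd, k = k))
  if (ncol(cmds) < k) cmds <- cbind(cmds, matrix(0, n, k - ncol(cmds)))
  starts[[1]] <- cmds
  if (restarts > 1)
    for (i in 2:restarts) starts[[i]] <- matrix(rnorm(n * k), n, k)
  for (st in starts) {
    fit <- vegan::monoMDS(dd, y = st, k = k, model = "global")
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  coords <- scale(best$points, center = TRUE, scale = FALSE)
  colnames(coords) <- paste0("NMDS", seq_len(k))
  rownames(coords) <- rownames(dm)
  flip <- if (!is.null(depth)) {
    stats::cor(coords[, 1], rank(depth)) < 0
  } else coords[which.max(abs(coords[, 1])), 1] < 0
  if (isTRUE(flip)) coords[, 1] <- -coords[, 1]
  list(coordinates = coords, stress = best$stress, seed = seed)
}
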