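# Random-matrix-theory threshold selection for co-occurrence networks.
#
# The eigenvalue nearest-neighbour spacing distribution (NNSD) of a noisy
# correlation matrix follows the Gaussian orthogonal ensemble (GOE,
# Wigner surmise); once weak correlations are removed the surviving
# modular structure gives Poisson spacings. The threshold is the smallest
# cutoff at which the NNSD becomes Poisson.

# Unfold a sorted eigenvalue spectrum so spacings have mean 1: a monotone
# cubic spline with `nknots` knots (at evenly spaced quantiles) is fitted
# to the empirical cumulative eigenvalue density and spacings are taken on
# the transformed scale. Near-duplicate eigenvalues (gap < dup_tol) are
# dropped first.
unfolded_spacings <- function(eigenvalues, dup_tol = 1e-8, nknots = 10) {
  ev <- sort(eigenvalues)
  ev <- ev[c(TRUE, diff(ev) >= dup_tol)]
  n <- length(ev)
  if (n < 5) return(numeric(0))
  nk <- min(nknots, n)
  ki <- unique(round(seq(1, n, length.out = nk)))
  kx <- ev[ki]
  ky <- ki / n
  keep <- c(TRUE, diff(kx) > 0)
  fcum <- stats::splinefun(kx[keep], ky[keep], method = "hyman")
  unf <- n * fcum(ev)
  sp <- diff(unf)
  sp <- sp[sp > 0]
  if (!length(sp)) return(numeric(0))
  sp / mean(sp)
}

#' Chi-square distance of a spacing distribution to Poisson and GOE
#'
#' Histograms unit-mean nearest-neighbour spacings on \[0, 3\] (bin width
#' 0.1) and measures the chi-square distance of the observed counts to the
#' Poisson law \eqn{e^{-d}} and to the GOE Wigner surmise
#' \eqn{(\pi d/2) e^{-\pi d^2/4}} (both renormalised to \[0, 3\]).
#' The chi-square sum runs over occupied bins (observed count > 0).
#'
#' @param spacings numeric vector of unfolded spacings (mean ~ 1).
#' @return list: `chi2_poisson`, `chi2_goe`, `n_occupied`, `n_spacings`.
#' @examples
#' set.seed(1)
#' nnsd_distance(rexp(500))          # Poisson-like
#' @export
nnsd_distance <- function(spacings) {
  breaks <- seq(0, 3, by = 0.1)
  sp <- spacings[spacings <= 3 & spacings >= 0]
  if (length(sp) < 10)
    return(list(chi2_poisson = NA_real_, chi2_goe = NA_real_,
                n_occupied = 0L, n_spacings = length(sp)))
  obs <- graphics::hist(sp, breaks = breaks, plot = FALSE)$counts
  a <- breaks[-length(breaks)]; b <- breaks[-1]
  p_pois <- (exp(-a) - exp(-b)) / (1 - exp(-3))
  p_goe <- (exp(-pi * a^2 / 4) - exp(-pi * b^2 / 4)) / (1 - exp(-pi * 9 / 4))
  n <- length(sp)
  occ <- obs > 0
  chi2 <- function(p) sum((obs[occ] - n * p[occ])^2 / (n * p[occ]))
  list(chi2_poisson = chi2(p_pois), chi2_goe = chi2(p_goe),
       n_occupied = sum(occ), n_spacings = n)
}

#' RMT-based threshold scan of a correlation matrix
#'
#' For each candidate cutoff t (ascending), off-diagonal entries with
#' |r| < t are zeroed, rows with no surviving off-diagonal entry are
#' dropped, and the NNSD of the unfolded eigenvalue spectrum of the
#' retained submatrix is compared to the Poisson and GOE laws
#' ([nnsd_distance()]). The selected threshold St is the smallest t at
#' which the spectrum is Poisson -- `chi2_poisson < chi2_goe` and
#' `chi2_poisson` below the 0.95 chi-square critical value for the
#' occupied bins -- sustained over `stability_run` consecutive candidates.
#' The default run length of 3 guards against transient mid-scan windows
#' where the chi-square statistic of a still-mixed spectrum dips below the
#' critical value for a couple of candidates before rising again. The scan
#' stops when fewer than 10 nodes are retained; if no transition was found
#' by then, an error is raised.
#'
#' @param corr symmetric correlation matrix (unit diagonal); fewer than 50
#'   nodes triggers a warning (spectra get unstable).
#' @param t_min,t_max,step scan grid (defaults 0.30 to 0.99 by 0.01).
#' @param stability_run consecutive Poisson-like candidates required
#'   (default 3).
#' @return a `threshold_scan` list: `st` (selected threshold),
#'   `candidates` (data frame: `threshold`, `n_retained`, `chi2_poisson`,
#'   `chi2_goe`, `poisson_like`).
#' @export
rmt_threshold <- function(corr, t_min = 0.3, t_max = 0.99, step = 0.01,
                          stability_run = 3) {
  corr <- as.matrix(corr)
  if (nrow(corr) < 50)
    warning("correlation matrix has < 50 nodes; spectra may be unstable",
            call. = FALSE)
  cand <- seq(t_min, t_max, by = step)
  rows <- vector("list", length(cand))
  stopped_early <- FALSE
  for (i in seq_along(cand)) {
    t <- cand[i]
    M <- corr
    M[abs(M) < t] <- 0
    diag(M) <- 1
    deg <- rowSums(M != 0) - 1
    keep <- deg >= 1
    n_ret <- sum(keep)
    if (n_ret < 10) {
      stopped_early <- TRUE
      rows[[i]] <- data.frame(threshold = t, n_retained = n_ret,
                              chi2_poisson = NA_real_, chi2_goe = NA_real_,
                              poisson_like = FALSE)
      break
    }
    ev <- eigen(M[keep, keep], symmetric = TRUE, only.values = TRUE)$values
    d <- nnsd_distance(unfolded_spacings(ev))
    ok <- is.finite(d$chi2_poisson) && is.finite(d$chi2_goe) &&
      d$chi2_poisson < d$chi2_goe &&
      d$chi2_poisson < stats::qchisq(0.95, df = max(d$n_occupied, 1))
    rows[[i]] <- data.frame(threshold = t, n_retained = n_ret,
                            chi2_poisson = d$chi2_poisson,
                            chi2_goe = d$chi2_goe, poisson_like = ok)
  }
  scan <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  pass <- scan$poisson_like
  st <- NA_real_
  if (length(pass) >= stability_run)
    for (i in seq_len(length(pass) - stability_run + 1))
      if (all(pass[i:(i + stability_run - 1)])) { st <- scan$threshold[i]; break }
  if (is.na(st))
    stop("no RMT transition in scan range",
         if (stopped_early) " (retained submatrix fell below 10 nodes)" else "",
         call. = FALSE)
  structure(list(st = st, candidates = scan), class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("RMT threshold scan: %d candidates, selected St = %.2f (%d nodes retained)\n",
              nrow(x$candidates), x$st,
              x$candidates$n_retained[match(x$st, x$candidates$threshold)]))
  invisible(x)
}
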