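# Synthetic survey generator: OTU, soil and metal tables with known
# ground truth (planted co-occurrence modules, a pH-like latent gradient,
# metal covariates, realistic sequencing depths) so every pipeline stage
# can be checked against a recoverable truth.

#' Parameters of the synthetic survey generator
#'
#' Defaults emulate the downstream shape of a 45-field paddy survey:
#' 45 samples, 2000 taxa, 8 planted co-occurrence modules of 20-100 OTUs,
#' read depths of 110,000-128,000 per sample, and a truncated-normal
#' pH-like gradient centred at 5.4 (sd 0.3, clipped to 4.5-6.5) that
#' drives soil covariates and part of the community.
#'
#' @param n_samples number of samples.
#' @param n_taxa number of OTUs.
#' @param n_modules number of planted modules.
#' @param module_size_range inclusive range module sizes are drawn from.
#' @param gradient_mean,gradient_sd,gradient_range truncated-normal
#'   parameters of the pH-like gradient.
#' @param effect_scale sd of nonzero per-OTU gradient coefficients.
#' @param effect_prob probability an OTU responds to the gradient (the
#'   rest have coefficient 0, so regressions have signal but imperfect
#'   R-squared).
#' @param loading within-module latent-factor loading; 0 plants no
#'   co-occurrence structure.
#' @param module_abundance_shift amount subtracted from the baseline
#'   log-abundance of planted-module OTUs. Module members are placed in
#'   the rare-to-moderate abundance range, mirroring the observation that
#'   tightly co-occurring and keystone taxa tend to be low-abundance; it
#'   also keeps the planted modules from dominating total reads, which
#'   would couple every taxon through compositional closure.
#' @param noise_sd sd of the per-cell log-intensity noise.
#' @param baseline_sd sd of per-OTU baseline log-abundances (controls the
#'   abundance skew).
#' @param depth_range per-sample read totals are drawn uniformly from this
#'   range.
#' @param seed integer seed; generation is deterministic given it.
#' @return a `generator_params` list.
#' @export
generator_params <- function(n_samples = 45, n_taxa = 2000, n_modules = 8,
                             module_size_range = c(20, 100),
                             gradient_mean = 5.4, gradient_sd = 0.3,
                             gradient_range = c(4.5, 6.5),
                             effect_scale = 0.9, effect_prob = 0.3,
                             loading = 1.0, noise_sd = 0.5,
                             baseline_sd = 1.2, module_abundance_shift = 1.5,
                             depth_range = c(110000, 128000), seed = 7) {
  p <- as.list(environment())
  stopifnot(n_samples > 0, n_taxa > 0, n_modules >= 0,
            module_size_range[1] <= module_size_range[2],
            depth_range[1] <= depth_range[2], noise_sd >= 0, loading >= 0)
  structure(p, class = "generator_params")
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- rnorm(n, mean, sd)
  bad <- out < lo | out > hi
  while (any(bad)) {
    out[bad] <- rnorm(sum(bad), mean, sd)
    bad <- out < lo | out > hi
  }
  out
}

.synthetic_phyla <- c(Proteobacteria = 0.28, Acidobacteria = 0.19,
                      Chloroflexi = 0.10, Planctomycetes = 0.07,
                      Actinobacteria = 0.06, Gemmatimonadetes = 0.05,
                      Patescibacteria = 0.05, Verrucomicrobia = 0.04,
                      Bacteroidetes = 0.04, Nitrospirae = 0.03,
                      Firmicutes = 0.03, Other = 0.06)

#' Generate a synthetic survey bundle
#'
#' Per sample j a latent gradient \eqn{g_j} (pH-like) is drawn; soil
#' covariates are linear functions of \eqn{g_j} plus noise (CEC, TN, AP,
#' AK, clay and silt increase with the gradient, sand decreases); metal
#' totals are log-normal with Beta-distributed DTPA fractions. Per OTU i
#' the log-intensity in sample j is
#' \deqn{baseline_i + \beta_i (g_j - \bar g) + \lambda_i u_{m(i),j} +
#'   \epsilon_{ij}}
#' with a standard-normal module factor \eqn{u_{m,j}} shared within each
#' planted module (loading \eqn{\lambda_i = 0} for unplanted OTUs) and
#' Gaussian noise. Counts are multinomial draws over the softmax of the
#' intensities at a uniform random depth, so taxa compete for reads the
#' way compositional 16S data does. One member per module gets a boosted
#' baseline and loading and is recorded as the planted hub.
#'
#' @param params a [generator_params] list.
#' @return a `synthetic_bundle` list: `otu` ([otu_table]), `soil`
#'   (`soil_profile_table`), `metals` (`metal_table`), and `truth` with
#'   `module_of` (0 = unplanted), `gradient`, `effect`, `loading`,
#'   `hub_otus`.
#' @examples
#' b <- generate_dataset(generator_params(n_taxa = 50, seed = 7))
#' range(rowSums(b$otu$counts))
#' @export
generate_dataset <- function(params = generator_params()) {
  p <- params
  set.seed(p$seed)
  n <- p$n_samples; nt <- p$n_taxa
  sizes <- if (p$n_modules > 0)
    sample(seq(p$module_size_range[1], p$module_size_range[2]),
           p$n_modules, replace = TRUE) else integer(0)
  if (sum(sizes) > nt)
    stop("infeasible module sizes: planted OTUs (", sum(sizes),
         ") exceed n_taxa (", nt, ")", call. = FALSE)
  module_of <- integer(nt)
  if (length(sizes)) module_of[seq_len(sum(sizes))] <- rep(seq_along(sizes), sizes)
  sample_ids <- sprintf("S_%d", seq_len(n))
  otu_ids <- sprintf("OTU_%d", seq_len(nt))

  g <- .rtruncnorm(n, p$gradient_mean, p$gradient_sd,
                   p$gradient_range[1], p$gradient_range[2])

  # soil covariates: linear in the gradient + noise, clamped to plausible
  # positive ranges; texture closes to exactly 100
  clamp <- function(x, lo) pmax(x, lo)
  clay <- clamp(16 + 1.3 * g + rnorm(n, 0, 1.3), 5)
  silt <- clamp(26 + 1.2 * g + rnorm(n, 0, 1.0), 5)
  soil <- data.frame(
    sample_id = sample_ids,
    som = clamp(36.5 + rnorm(n, 0, 6), 5),
    ph = g,
    cec = clamp(-10 + 3.5 * g + rnorm(n, 0, 1.2), 0.5),
    ec = clamp(130 + rnorm(n, 0, 35), 10),
    clay = clay, silt = silt, sand = 100 - clay - silt,
    tn = clamp(-1.8 + 0.7 * g + rnorm(n, 0, 0.35), 0.2),
    an = clamp(140 + rnorm(n, 0, 20), 20),
    ap = clamp(-200 + 55 * g + rnorm(n, 0, 25), 5),
    ak = clamp(-65 + 29 * g + rnorm(n, 0, 10), 10),
    stringsAsFactors = FALSE)
  soil <- validate_soil_table(soil)

  meta_spec <- list(Cd = c(log(0.8), 0.9), Cu = c(log(12), 0.3),
                    Pb = c(log(39), 0.2), Zn = c(log(55), 0.25))
  metals <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  for (me in names(meta_spec)) {
    tot <- rlnorm(n, meta_spec[[me]][1], meta_spec[[me]][2])
    metals[[paste0("total_", me)]] <- tot
    metals[[paste0("dtpa_", me)]] <- tot * rbeta(n, 4, 6)
  }
  attr(metals, "metals") <- names(meta_spec)
  class(metals) <- c("metal_table", "data.frame")

  baseline <- rnorm(nt, 0, p$baseline_sd)
  baseline[module_of > 0] <- baseline[module_of > 0] - p$module_abundance_shift
  beta <- ifelse(rbinom(nt, 1, p$effect_prob) == 1,
                 rnorm(nt, 0, p$effect_scale), 0)
  # members couple to their module factor with heterogeneous strength
  # (scaled loading); the planted hub of each module couples at full
  # strength with reduced noise, so it emerges as the best-connected node
  lambda <- ifelse(module_of > 0, p$loading * runif(nt, 0.5, 1), 0)
  hub_otus <- character(0)
  noise_sd_i <- rep(p$noise_sd, nt)
  if (length(sizes)) {
    hub_idx <- cumsum(c(1, utils::head(sizes, -1)))  # first member of each module
    baseline[hub_idx] <- baseline[hub_idx] + p$module_abundance_shift
    lambda[hub_idx] <- p$loading
    noise_sd_i[hub_idx] <- p$noise_sd / 2
    hub_otus <- otu_ids[hub_idx]
  }
  u <- matrix(rnorm(max(length(sizes), 1) * n), nrow = n)  # sample x module
  eps <- matrix(rnorm(n * nt), n, nt) * matrix(noise_sd_i, n, nt, byrow = TRUE)
  gc_ <- g - p$gradient_mean
  intensity <- matrix(baseline, n, nt, byrow = TRUE) +
    outer(gc_, beta) + eps
  planted <- module_of > 0
  if (any(planted))
    intensity[, planted] <- intensity[, planted] +
      u[, module_of[planted], drop = FALSE] *
      matrix(lambda[planted], n, sum(planted), byrow = TRUE)

  depth <- floor(runif(n, p$depth_range[1], p$depth_range[2] + 1))
  counts <- matrix(0L, n, nt, dimnames = list(sample_ids, otu_ids))
  for (j in seq_len(n)) {
    w <- exp(intensity[j, ] - max(intensity[j, ]))
    counts[j, ] <- as.integer(rmultinom(1, depth[j], w / sum(w)))
  }

  phy_pool <- names(.synthetic_phyla)
  mod_phylum <- if (length(sizes))
    sample(phy_pool, length(sizes), replace = TRUE, prob = .synthetic_phyla)
  else character(0)
  phylum <- sample(phy_pool, nt, replace = TRUE, prob = .synthetic_phyla)
  if (any(planted)) {
    biased <- planted & rbinom(nt, 1, 0.6) == 1
    phylum[biased] <- mod_phylum[module_of[biased]]
  }
  taxonomy <- stats::setNames(
    paste("Bacteria", phylum, "Unclassified", "Unclassified",
          "Unclassified", "Unclassified", sep = ";"), otu_ids)

  structure(list(
    otu = otu_table(counts, taxonomy),
    soil = soil, metals = metals,
    truth = list(module_of = stats::setNames(module_of, otu_ids),
                 gradient = stats::setNames(g, sample_ids),
                 effect = stats::setNames(beta, otu_ids),
                 loading = stats::setNames(lambda, otu_ids),
                 hub_otus = hub_otus),
    params = p), class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf("Synthetic bundle: %d samples x %d taxa, %d planted modules (seed %d)\n",
              nrow(x$otu$counts), ncol(x$otu$counts),
              max(x$truth$module_of), x$params$seed))
  invisible(x)
}

#' Write a synthetic bundle to a directory
#'
#' Writes `otu.tsv` (taxa rows + taxonomy column), `soil.tsv`,
#' `metals.tsv` (T-/A- headers) and `truth.json`.
#'
#' @param bundle a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_otu_table(bundle$otu, file.path(dir, "otu.tsv"))
  write_soil_table(bundle$soil, file.path(dir, "soil.tsv"))
  met <- as.data.frame(bundle$metals)
  names(met) <- sub("^total_", "T-", names(met))
  names(met) <- sub("^dtpa_", "A-", names(met))
  .write_table(met, file.path(dir, "metals.tsv"))
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}
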