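# shared builders for tests; everything is generated in code

toy_counts <- function() {
  m <- matrix(c(5, 0, 3, 2,
                1, 4, 0, 7,
                2, 2, 2, 2), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("S", 1:3), paste0("OTU_", 1:4)))
  m
}

# block correlation matrix with planted modules: within-block |r| drawn
# from `within`, between-block |r| from `between`, random signs
planted_corr <- function(n_blocks = 5, block_size = 20,
                         within = c(0.85, 0.95), between = c(0, 0.4),
                         seed = 3) {
  set.seed(seed)
  n <- n_blocks * block_size
  blk <- rep(seq_len(n_blocks), each = block_size)
  R <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    rng <- if (blk[i] == blk[j]) within else between
    R[i, j] <- R[j, i] <- runif(1, rng[1], rng[2]) * sample(c(-1, 1), 1)
  }
  diag(R) <- 1
  dimnames(R) <- list(paste0("OTU_", seq_len(n)), paste0("OTU_", seq_len(n)))
  attr(R, "block") <- stats::setNames(blk, rownames(R))
  R
}

write_tsv_text <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# small soil table text with controllable cells
soil_lines <- function(clay = 20, silt = 30, sand = "50") {
  c("sample_id\tSOM\tpH\tCEC\tEC\tClay\tSilt\tSand\tTN\tAN\tAP\tAK",
    paste("A", 30, 5.5, 8, 100, clay, silt, sand, 2, 120, 80, 90, sep = "\t"))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
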