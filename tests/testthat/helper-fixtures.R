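# Shared fixture builders. Everything is generated in code; no files.

tiny_layout <- function() genome_layout(c("chrA", "chrB"), c(2e6, 1e6))

# Small GRanges from 0-based half-open triples
gr3 <- function(chrom, start, end, ...) {
  suppressWarnings(region_set(chrom, start, end, ...))
}

# Brute-force any-overlap flags for half-open intervals (quadratic oracle)
brute_overlap <- function(rc, rs, re, dc, ds, de) {
  vapply(seq_along(rs), function(i) {
    any(dc == rc[i] & ds < re[i] & de > rs[i])
  }, logical(1))
}

# Direct O(n*w) convolution oracle for the Gaussian bin smoother
oracle_smooth <- function(x, window_bins = 20, tails = 2.5) {
  h <- floor(window_bins / 2)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0; den <- 0
    for (j in -h:h) {
      k <- i + j
      if (k >= 1 && k <= n) {
        w <- exp(-0.5 * (tails * j / (window_bins / 2))^2)
        num <- num + w * x[k]
        den <- den + w
      }
    }
    out[i] <- num / den
  }
  out
}

# Cell table + binary matrix with explicit per-group accessibility probs:
# ages is a vector, p a matrix n_peaks x length(ages)
bernoulli_cells <- function(n_per_age, ages, p, seed = 1) {
  set.seed(seed)
  n_peaks <- nrow(p)
  cells <- data.frame(
    cell_id = sprintf("c%05d", seq_len(n_per_age * length(ages))),
    age = rep(ages, each = n_per_age),
    stringsAsFactors = FALSE
  )
  m <- do.call(rbind, lapply(seq_along(ages), function(a) {
    matrix(rbinom(n_per_age * n_peaks, 1, rep(p[, a], each = n_per_age)),
           nrow = n_per_age)
  }))
  dimnames(m) <- list(cells$cell_id, sprintf("p%04d", seq_len(n_peaks)))
  list(cells = cells, matrix = Matrix::Matrix(m, sparse = TRUE))
}
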