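test_that("genome binning respects chromosome boundaries", {
  tr <- bin_genome(genome_layout("c1", 1e6), 1e5)
  expect_equal(nrow(tr$bins), 10)
  tr2 <- bin_genome(genome_layout("c1", 1.05e6), 1e5)
  expect_equal(nrow(tr2$bins), 11)
  expect_equal(tr2$bins$end[11] - tr2$bins$start[11], 5e4)
  tr3 <- bin_genome(tiny_layout(), 1e5)
  expect_equal(sum(tr3$bins$chrom == "chrA"), 20)
  expect_equal(sum(tr3$bins$chrom == "chrB"), 10)
  expect_true(all(tr3$bins$value == 0))
})

test_that("DAR counting uses the midpoint rule and filters", {
  lay <- genome_layout("c1", 1e6)
  tr <- bin_genome(lay, 1e5)
  # spans the 1e5 boundary; midpoint 99,000 lies in bin 1
  d <- data.frame(chrom = "c1", start = 98000, end = 100001,
                  log2_fold_change = 2, p_value = 1e-4, direction = "up")
  ct <- count_dars_per_bin(d, tr)
  expect_equal(ct$bins$value, c(1, rep(0, 9)))
  # fails |lfc| > 1 (strict) and p < 0.01
  d2 <- rbind(d, data.frame(chrom = "c1", start = 5e5, end = 5.005e5,
                            log2_fold_change = 1, p_value = 1e-4,
                            direction = "up"),
              data.frame(chrom = "c1", start = 7e5, end = 7.005e5,
                         log2_fold_change = 3, p_value = 0.02,
                         direction = "down"))
  expect_equal(sum(count_dars_per_bin(d2, tr)$bins$value), 1)
  expect_equal(sum(count_dars_per_bin(d2, tr, lfc_min = 0.5,
                                      p_max = 0.5)$bins$value), 3)
  expect_equal(sum(count_dars_per_bin(d2, tr, direction = "down",
                                      lfc_min = 0.5, p_max = 0.5)$bins$value), 1)
  expect_error(count_dars_per_bin(data.frame(chrom = "cX", start = 1,
                                             end = 501), tr),
               "absent from the genome layout")
})

test_that("bin counts equal a brute-force interval scan", {
  set.seed(44)
  lay <- genome_layout(c("c1", "c2"), c(3e6, 2e6))
  tr <- bin_genome(lay, 1e5)
  n <- 10000
  ch <- sample(c("c1", "c2"), n, replace = TRUE, prob = c(3, 2))
  start <- floor(runif(n, 0, ifelse(ch == "c1", 3e6, 2e6) - 500))
  d <- data.frame(chrom = ch, start = start, end = start + 500,
                  log2_fold_change = 2, p_value = 1e-4, direction = "up")
  got <- count_dars_per_bin(d, tr)$bins$value
  mid <- floor((d$start + d$end) / 2)
  brute <- vapply(seq_len(nrow(tr$bins)), function(i) {
    b <- tr$bins[i, ]
    sum(d$chrom == b$chrom & mid >= b$start & mid < b$end)
  }, numeric(1))
  expect_equal(got, brute, ignore_attr = TRUE)
})

test_that("smoother matches the direct convolution oracle", {
  set.seed(55)
  lay <- genome_layout("c1", 5e7)
  tr <- bin_genome(lay, 1e5)   # 500 bins
  tr$bins$value <- rpois(500, 3)
  sm <- gaussian_smooth(tr, window_bins = 20, tails = 2.5)
  expect_lt(max(abs(sm$bins$value - oracle_smooth(tr$bins$value))), 1e-9)
  # other window/tails combinations
  for (wb in c(4, 10)) {
    sm2 <- gaussian_smooth(tr, window_bins = wb, tails = 3)
    expect_lt(max(abs(sm2$bins$value -
                        oracle_smooth(tr$bins$value, wb, 3))), 1e-9)
  }
})

test_that("smoothing identities: constant, impulse, mass, shift, monotone", {
  lay <- genome_layout("c1", 5e6)
  tr <- bin_genome(lay, 1e5)   # 50 bins
  tr$bins$value <- rep(3.7, 50)
  expect_equal(gaussian_smooth(tr)$bins$value, rep(3.7, 50), tolerance = 1e-12)

  tr$bins$value <- 0; tr$bins$value[25] <- 1
  sm <- gaussian_smooth(tr)$bins$value
  expect_equal(which.max(sm), 25)
  expect_equal(sm[25 + 1:10], sm[25 - 1:10], tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-9)  # interior impulse conserves mass

  # mass conservation for signal whose kernel support stays interior
  set.seed(7)
  tr$bins$value <- 0; tr$bins$value[21:29] <- rpois(9, 5)
  expect_equal(sum(gaussian_smooth(tr)$bins$value), sum(tr$bins$value),
               tolerance = 1e-9)

  # translation equivariance away from edges
  tr$bins$value <- 0; tr$bins$value[20:24] <- c(2, 5, 9, 5, 2)
  s1 <- gaussian_smooth(tr)$bins$value
  tr$bins$value <- 0; tr$bins$value[21:25] <- c(2, 5, 9, 5, 2)
  s2 <- gaussian_smooth(tr)$bins$value
  expect_equal(s2[13:35], s1[12:34], tolerance = 1e-12)

  # monotonicity: adding a DAR never decreases any smoothed value
  tr$bins$value <- rpois(50, 2)
  base <- gaussian_smooth(tr)$bins$value
  tr$bins$value[30] <- tr$bins$value[30] + 1
  expect_true(all(gaussian_smooth(tr)$bins$value >= base - 1e-12))
})

test_that("smoothing is per-chromosome and warns on short chromosomes", {
  lay <- genome_layout(c("c1", "c2"), c(2e6, 2e6))
  tr <- bin_genome(lay, 1e5)  # 20 + 20 bins
  tr$bins$value[20] <- 10     # last bin of c1
  sm <- suppressWarnings(gaussian_smooth(tr))$bins$value
  expect_true(all(sm[21:30] == 0))  # no bleed into c2
  short <- bin_genome(genome_layout("c1", 5e5), 1e5)  # 5 bins < window
  expect_warning(gaussian_smooth(short, window_bins = 20), "truncated")
})

test_that("hotspot calls obey the strict top-quantile rule and merge", {
  lay <- genome_layout("c1", 1e8)
  tr <- bin_genome(lay, 1e5)  # 1000 bins
  tr$bins$value <- 0
  tr$bins$value[101:110] <- 1   # 10 contiguous hot bins
  hs <- call_hotspots(tr, quantile = 0.99)
  expect_equal(nrow(hs), 1)
  expect_equal(hs$n_bins, 10)
  expect_equal(hs$end - hs$start, 10 * 1e5)
  expect_equal(hs$peak_score, 1)

  tr$bins$value <- rep(2, 1000)
  expect_warning(hs0 <- call_hotspots(tr, 0.99), "constant")
  expect_equal(nrow(hs0), 0)
})

test_that("planted DAR clusters are recovered as hotspots", {
  ph <- data.frame(chrom = paste0("chr", 1:5), center_bp = 1e7,
                   span_bp = 5e5, n_dars = 50)
  cfg <- sim_config(seed = 1, n_background_dars = 30000,
                    planted_hotspots = ph)
  g <- simulate_genome(cfg)
  dars <- simulate_dars(g$layout, g$domains, cfg)
  raw <- count_dars_per_bin(dars, bin_genome(g$layout, 1e5))
  hs <- call_hotspots(gaussian_smooth(raw, 20), quantile = 0.99,
                      domains = g$domains, raw_track = raw)
  spans <- gr3(ph$chrom, ph$center_bp - ph$span_bp / 2,
               ph$center_bp + ph$span_bp / 2)
  calls <- gr3(hs$chrom, hs$start, hs$end)
  recovered <- sum(GenomicRanges::countOverlaps(spans, calls) > 0)
  spurious <- sum(GenomicRanges::countOverlaps(calls, spans) == 0)
  expect_gte(recovered, 4)
  expect_lte(spurious, 1)
  expect_true(all(hs$peak_score > attr(hs, "threshold")))
  expect_true(all(hs$n_dars >= 1))
})
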