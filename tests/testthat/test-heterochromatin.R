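test_that("overlap flags use half-open semantics and report bp", {
  r <- gr3(c("c1", "c1"), c(100, 100), c(200, 200))
  d1 <- gr3("c1", 200, 300)
  d2 <- gr3("c1", 150, 300)
  expect_false(overlap_flags(r[1], d1)$overlaps)
  o <- overlap_flags(r[1], d2)
  expect_true(o$overlaps)
  expect_equal(o$overlap_bp, 50)
  expect_error(overlap_flags(gr3("c1", 0, 10), gr3("1", 0, 10)),
               "namespaces")
})

test_that("overlap flags agree with a quadratic brute-force scan", {
  set.seed(66)
  n <- 10000
  rc <- sample(c("c1", "c2"), n, replace = TRUE)
  rs <- floor(runif(n, 0, 1e6)); re <- rs + sample(100:2000, n, replace = TRUE)
  dc <- sample(c("c1", "c2"), 50, replace = TRUE)
  ds <- floor(runif(50, 0, 1e6)); de <- ds + sample(5000:50000, 50, replace = TRUE)
  got <- overlap_flags(gr3(rc, rs, re), gr3(dc, ds, de))$overlaps
  expect_identical(got, brute_overlap(rc, rs, re, dc, ds, de))
})

test_that("the fast permutation interval test matches GRanges overlap", {
  set.seed(10)
  lay <- genome_layout("c1", 1e6)
  ds <- sort(sample(seq(0, 9e5, by = 5e4), 8)); de <- ds + 2e4
  s <- floor(runif(500, 0, 1e6 - 500))
  fast <- chromaging:::interval_hits_sorted(s, rep(500, 500), ds, de)
  slow <- brute_overlap(rep("c1", 500), s, s + 500,
                        rep("c1", 8), ds, de)
  expect_identical(fast, slow)
})

test_that("enrichment closed forms and undefined case", {
  lay <- genome_layout("c1", 1e6)
  domains <- gr3("c1", 0, 1e5)       # 10% coverage
  regions <- gr3(rep("c1", 100), seq(0, 99) * 1000, seq(0, 99) * 1000 + 500)
  res <- domain_enrichment(regions, domains, lay, n_permutations = 0)
  expect_equal(res$n_overlapping, 100)
  expect_equal(res$enrichment_ratio, 10)
  expect_equal(res$binomial_p, 0.1^100)

  empty <- domain_enrichment(regions, GenomicRanges::GRanges(), lay,
                             n_permutations = 0)
  expect_true(empty$undefined)
  expect_true(is.na(empty$enrichment_ratio))
})

test_that("uniform regions give null-like enrichment", {
  set.seed(3)
  lay <- genome_layout("c1", 2e6)
  domains <- gr3("c1", c(0, 1e6), c(5e5, 1.5e6))  # 50% coverage
  s <- floor(runif(4000, 0, 2e6 - 500))
  res <- domain_enrichment(gr3(rep("c1", 4000), s, s + 500), domains, lay,
                           n_permutations = 200, seed = 5)
  expect_lt(abs(res$enrichment_ratio - 1), 0.05)
  expect_gt(res$binomial_p, 0.01)
  expect_gt(res$permutation_p, 0.01)
})

test_that("planted 15x enrichment at 3% coverage is recovered", {
  cfg <- sim_config(seed = 12, n_background_dars = 5000,
                    domain_coverage_fraction = 0.03,
                    domain_dar_enrichment = 15)
  g <- simulate_genome(cfg)
  dars <- simulate_dars(g$layout, g$domains, cfg)
  res <- domain_enrichment(dars_to_regions(dars), g$domains, g$layout,
                           n_permutations = 200, seed = 13)
  expect_gte(res$enrichment_ratio, 12)
  expect_lte(res$enrichment_ratio, 18)
  expect_lt(res$permutation_p, 0.01)
  expect_lt(res$binomial_p, 1e-10)
})

test_that("permutation p-values are uniform under the null", {
  lay <- genome_layout("c1", 2e6)
  set.seed(99)
  dstart <- sort(sample(seq(0, 1.9e6, by = 1e5), 6)); domains <- gr3(rep("c1", 6), dstart, dstart + 1e4)
  ps <- vapply(1:200, function(i) {
    s <- floor(runif(300, 0, 2e6 - 500))
    domain_enrichment(gr3(rep("c1", 300), s, s + 500), domains, lay,
                      n_permutations = 99, seed = 7000 + i)$permutation_p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("enrichment ratio is invariant to splitting domains", {
  lay <- genome_layout("c1", 1e6)
  whole <- gr3("c1", 2e5, 4e5)
  split2 <- gr3(c("c1", "c1"), c(2e5, 3e5), c(3e5, 4e5))
  set.seed(1)
  s <- floor(runif(500, 0, 1e6 - 500))
  r <- gr3(rep("c1", 500), s, s + 500)
  e1 <- domain_enrichment(r, whole, lay, n_permutations = 0)
  e2 <- domain_enrichment(r, split2, lay, n_permutations = 0)
  expect_equal(e1$enrichment_ratio, e2$enrichment_ratio)
  expect_equal(e1$n_overlapping, e2$n_overlapping)
})

test_that("own exact 2x2 test matches fisher.test", {
  cases <- rbind(c(90, 10, 50, 50), c(3, 7, 9, 1), c(0, 10, 0, 10),
                 c(12, 2, 3, 15), c(5, 5, 5, 5), c(1, 0, 0, 1))
  for (i in seq_len(nrow(cases))) {
    x <- cases[i, ]
    ours <- fisher_exact_2x2(x[1], x[2], x[3], x[4])
    ref <- stats::fisher.test(matrix(x, 2, byrow = TRUE))$p.value
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("direction split: counts, fractions and conservation", {
  domains <- gr3("c1", 0, 1e5)
  # 90 up + 10 down inside, 50 up + 50 down outside
  dars <- data.frame(
    chrom = "c1",
    start = c(seq(0, by = 500, length.out = 100),
              seq(2e5, by = 500, length.out = 100)),
    direction = c(rep("up", 90), rep("down", 10),
                  rep("up", 50), rep("down", 50)))
  dars$end <- dars$start + 400
  sp <- direction_split(dars, domains)
  expect_equal(sp$up_in, 90); expect_equal(sp$down_in, 10)
  expect_equal(sp$up_fraction_in, 0.9)
  expect_equal(sp$up_fraction_out, 0.5)
  expect_equal(sp$up_in + sp$down_in + sp$up_out + sp$down_out, nrow(dars))
  expect_lt(sp$fisher_p, 1e-8)
  # order invariance
  sp2 <- direction_split(dars[sample(nrow(dars)), ], domains)
  expect_equal(sp, sp2)
  # all outside
  sp3 <- direction_split(dars, gr3("c1", 9e5, 9.5e5))
  expect_equal(sp3$up_in + sp3$down_in, 0)
})

test_that("simulated domain-forced upregulation is recovered", {
  cfg <- sim_config(seed = 14, n_background_dars = 2000,
                    domain_coverage_fraction = 0.1,
                    domain_dar_enrichment = 5, domain_up_prob = 0.85)
  g <- simulate_genome(cfg)
  dars <- simulate_dars(g$layout, g$domains, cfg)
  sp <- direction_split(dars, g$domains)
  expect_gt(sp$up_in + sp$down_in, 500)
  expect_lt(abs(sp$up_fraction_in - 0.85), 0.05)
  expect_lt(abs(sp$up_fraction_out - 0.5), 0.05)
})

test_that("biotype composition of top genes", {
  set.seed(8)
  n <- 500
  genes <- data.frame(
    gene_id = sprintf("g%04d", 1:n),
    direction = rep(c("up", "down"), each = n / 2),
    adjusted_p = runif(n), log2_fold_change = rnorm(n))
  bio <- data.frame(gene_id = genes$gene_id, biotype = "protein_coding")
  # plant 55 lncRNA/pseudogene among the top 100 up genes
  up <- genes[genes$direction == "up", ]
  top_up <- up$gene_id[order(up$adjusted_p)][1:100]
  bio$biotype[match(top_up[1:30], bio$gene_id)] <- "lncRNA"
  bio$biotype[match(top_up[31:55], bio$gene_id)] <- "pseudogene"
  res <- biotype_top_composition(genes, bio, top_n = 100)
  expect_equal(res$summary$repressed_fraction[res$summary$direction == "up"],
               0.55)
  expect_equal(res$summary$repressed_fraction[res$summary$direction == "down"],
               0)
  brk <- res$breakdown
  expect_equal(brk$count[brk$direction == "up" & brk$biotype == "lncRNA"], 30)
  expect_error(biotype_top_composition(genes, bio, top_n = 1000), "exceeds")
  # unknown genes reported
  res2 <- biotype_top_composition(genes, bio[-(1:5), ], top_n = 100)
  expect_true("unknown" %in% res2$breakdown$biotype ||
                all(res2$breakdown$count > 0))
})
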