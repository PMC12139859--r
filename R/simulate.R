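#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator into a single
#' validated object. One global integer `seed` is split deterministically
#' into independent streams per sub-generator, so adding a generator never
#' perturbs the draws of another.
#'
#' Defaults encode the study conditions the downstream statistics assume:
#' three age groups (2, 9 and 18 months), two biological replicates per
#' age, repressive domains covering ~3% of the genome as 250 kb blocks,
#' 500 bp differential peaks, and a progenitor-like cell type declining
#' from ~3% of cells at 2 months to 0.01% at 18 months.
#'
#' @param seed integer master seed.
#' @param n_chroms,chrom_length_bp genome shape: number of chromosomes and
#'   length of each (bp).
#' @param n_peaks number of accessibility peaks to place.
#' @param peak_width_bp,dar_width_bp widths (bp) of peaks and of simulated
#'   differential regions.
#' @param n_background_dars number of background DARs placed outside
#'   planted hotspot spans.
#' @param planted_hotspots data frame with columns `chrom`, `center_bp`,
#'   `span_bp`, `n_dars` describing planted DAR clusters, or `NULL`.
#' @param domain_coverage_fraction fraction of the genome covered by
#'   repressive (heterochromatin-like) domains, in `[0, 1)`.
#' @param domain_block_bp fixed length of each domain block (bp).
#' @param domain_dar_enrichment multiplier (>= 0) on the probability that a
#'   background DAR falls inside a domain, renormalized; 1 = uniform,
#'   0 = never inside.
#' @param bg_lfc_base,bg_lfc_rate background DAR effect sizes:
#'   `|log2FC| = bg_lfc_base + Exp(bg_lfc_rate)`. The defaults (0.25 + an
#'   exponential tail of rate 6) put most background DARs just above the
#'   differential-calling threshold with ~1% exceeding the hotspot
#'   counting cutoff of 1, reproducing the sparse counted-DAR density at
#'   which genome-wide hotspot scoring operates.
#' @param planted_lfc_base,planted_lfc_rate planted (hotspot) DAR effect
#'   sizes, `|log2FC| = planted_lfc_base + Exp(planted_lfc_rate)`;
#'   defaults make every planted DAR a strong change (>= 1).
#' @param up_prob probability a DAR outside domains is called "up".
#' @param domain_up_prob probability a DAR inside a domain is called "up";
#'   raise towards 1 to emulate the predominance of upregulation inside
#'   heterochromatin.
#' @param composition_spec data frame `cell_type`, `age`, `proportion`;
#'   proportions must sum to 1 within each age.
#' @param ages integer ages in months.
#' @param n_replicates biological replicates per age.
#' @param cells_per_replicate nuclei drawn per replicate.
#' @param regions,sexes character vectors cycled over replicates.
#' @param accessibility_spec numeric matrix of per-peak Bernoulli
#'   accessibility probabilities with one column per age (column names =
#'   ages), or `NULL` to draw a shared baseline per peak.
#' @param n_te_subfamilies,te_base_mean_range,te_dispersion TE count model:
#'   number of subfamilies, range of per-cell Poisson means (log-uniform),
#'   and gamma over-dispersion of replicate-level rates.
#' @param te_planted data frame `subfamily_index`, `log2fc` of subfamilies
#'   whose old-age rate is shifted, or `NULL`.
#' @param n_genes,gene_width_bp,gene_biotype_probs gene annotation model;
#'   biotype probabilities must include `lncRNA` and `pseudogene`.
#' @param n_clusters,n_profile_genes,noise_sd,confusion_rate cluster
#'   expression-profile model for label-transfer simulations.
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 5L,
                       chrom_length_bp = 2e7,
                       n_peaks = 2000L,
                       peak_width_bp = 500L,
                       dar_width_bp = 500L,
                       n_background_dars = 10000L,
                       planted_hotspots = NULL,
                       domain_coverage_fraction = 0.03,
                       domain_block_bp = 250000L,
                       domain_dar_enrichment = 1,
                       bg_lfc_base = 0.25,
                       bg_lfc_rate = 6,
                       planted_lfc_base = 1,
                       planted_lfc_rate = 2,
                       up_prob = 0.5,
                       domain_up_prob = up_prob,
                       composition_spec = default_composition_spec(),
                       ages = c(2L, 9L, 18L),
                       n_replicates = 2L,
                       cells_per_replicate = 1000L,
                       regions = "FC",
                       sexes = "M",
                       accessibility_spec = NULL,
                       n_te_subfamilies = 500L,
                       te_base_mean_range = c(0.1, 2),
                       te_dispersion = 0.05,
                       te_planted = NULL,
                       n_genes = 500L,
                       gene_width_bp = 10000L,
                       gene_biotype_probs = c(protein_coding = 0.60,
                                              lncRNA = 0.25,
                                              pseudogene = 0.15),
                       n_clusters = 20L,
                       n_profile_genes = 200L,
                       noise_sd = 0.1,
                       confusion_rate = 0) {
  cfg <- as.list(environment())
  class(cfg) <- "SimConfig"
  validate_sim_config(cfg)
  cfg
}

#' Default cell-type composition across ages
#'
#' Five cell types per age: a dentate-gyrus-progenitor-like population
#' declining from 3% to 0.01%, an immature-oligodendrocyte-like population
#' declining from 2% to 0.1%, an immature-neuron-like population declining
#' from 4% to 1%, and two abundant mature populations absorbing the rest.
#'
#' @return A data frame with columns `cell_type`, `age`, `proportion`.
#' @export
default_composition_spec <- function() {
  prog <- c(`2` = 0.03, `9` = 0.005, `18` = 0.0001)
  iol <- c(`2` = 0.02, `9` = 0.005, `18` = 0.001)
  imn <- c(`2` = 0.04, `9` = 0.02, `18` = 0.01)
  ages <- c(2L, 9L, 18L)
  out <- do.call(rbind, lapply(seq_along(ages), function(i) {
    rest <- 1 - prog[i] - iol[i] - imn[i]
    data.frame(
      cell_type = c("DG_progenitor", "IOL", "Inh_IMN", "Oligo", "DG_glut"),
      age = ages[i],
      proportion = c(prog[i], iol[i], imn[i], rest * 0.45, rest * 0.55)
    )
  }))
  rownames(out) <- NULL
  out
}

validate_sim_config <- function(cfg) {
  if (cfg$domain_coverage_fraction < 0 || cfg$domain_coverage_fraction >= 1) {
    stop_invalid_config("domain_coverage_fraction must lie in [0, 1)")
  }
  if (cfg$domain_dar_enrichment < 0) {
    stop_invalid_config("domain_dar_enrichment must be >= 0")
  }
  if (cfg$up_prob < 0 || cfg$up_prob > 1 ||
      cfg$domain_up_prob < 0 || cfg$domain_up_prob > 1) {
    stop_invalid_config("direction probabilities must lie in [0, 1]")
  }
  if (cfg$confusion_rate < 0 || cfg$confusion_rate > 1) {
    stop_invalid_config("confusion_rate must lie in [0, 1]")
  }
  cs <- cfg$composition_spec
  assert_columns(cs, c("cell_type", "age", "proportion"), "composition_spec")
  if (any(cs$proportion < 0 | cs$proportion > 1)) {
    stop_invalid_config("composition proportions must lie in [0, 1]")
  }
  sums <- tapply(cs$proportion, cs$age, sum)
  if (any(abs(sums - 1) > 1e-8)) {
    stop_invalid_config("composition proportions must sum to 1 within each age")
  }
  if (!is.null(cfg$accessibility_spec)) {
    a <- cfg$accessibility_spec
    if (any(a < 0 | a > 1)) {
      stop_invalid_config("accessibility probabilities must lie in [0, 1]")
    }
  }
  if (!is.null(cfg$planted_hotspots)) {
    ph <- cfg$planted_hotspots
    assert_columns(ph, c("chrom", "center_bp", "span_bp", "n_dars"),
                   "planted_hotspots")
    if (any(ph$center_bp - ph$span_bp / 2 < 0) ||
        any(ph$center_bp + ph$span_bp / 2 > cfg$chrom_length_bp)) {
      stop_invalid_config("planted hotspot spans must fit within chromosomes")
    }
    if (any(ph$n_dars > floor(ph$span_bp / cfg$dar_width_bp))) {
      stop_invalid_config(
        "planted n_dars exceeds span capacity at minimum spacing ",
        "(span_bp / dar_width_bp)")
    }
  }
  invisible(cfg)
}

#' Simulate a genome: layout, repressive domains, TEs, genes and peaks
#'
#' Domains are drawn as fixed-length non-overlapping blocks placed
#' uniformly per chromosome, the block count chosen so that total domain
#' length approximates `domain_coverage_fraction` of the genome (exact up
#' to rounding to whole blocks). TE copies carry subfamily labels and
#' genes carry biotype labels (including `lncRNA` and `pseudogene`).
#' Identical configuration (including seed) gives identical output.
#'
#' @param config a [sim_config()].
#' @return A list with elements `layout` ([genome_layout()]), `domains`,
#'   `tes`, `peaks` (all `GRanges`) and `genes` (data frame with `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `biotype`).
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  layout <- genome_layout(paste0("chr", seq_len(config$n_chroms)),
                          rep(config$chrom_length_bp, config$n_chroms))
  domains <- with_seed(sub_seed(config$seed, 1L),
                       place_domain_blocks(layout,
                                           config$domain_coverage_fraction,
                                           config$domain_block_bp))
  tes <- with_seed(sub_seed(config$seed, 2L), simulate_te_annotation(layout, config))
  genes <- with_seed(sub_seed(config$seed, 3L), simulate_gene_annotation(layout, config))
  peaks <- with_seed(sub_seed(config$seed, 4L),
                     uniform_intervals(layout, config$n_peaks,
                                       config$peak_width_bp,
                                       id_prefix = "peak"))
  list(layout = layout, domains = domains, tes = tes, genes = genes,
       peaks = peaks)
}

## Non-overlapping fixed-length blocks, uniform per chromosome: draw k
## starts in [0, L - k*block] and spread them by cumulative block offsets
## (the classic uniform non-overlap construction).
place_domain_blocks <- function(layout, coverage, block_bp) {
  total_blocks <- round(coverage * genome_length(layout) / block_bp)
  if (total_blocks == 0) {
    return(region_set(character(0), numeric(0), numeric(0), layout = layout,
                      domain_id = character(0)))
  }
  ## largest-remainder allocation proportional to chromosome length
  quota <- total_blocks * layout$length / genome_length(layout)
  k <- floor(quota)
  rem <- total_blocks - sum(k)
  if (rem > 0) {
    k[order(quota - k, decreasing = TRUE)[seq_len(rem)]] <- k[order(quota - k, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  chrom <- character(0); start <- numeric(0)
  for (i in seq_len(nrow(layout))) {
    ki <- k[i]
    if (ki == 0) next
    L <- layout$length[i]
    if (ki * block_bp > L) {
      stop_invalid_config("domain blocks do not fit on ", layout$chrom[i])
    }
    gaps <- sort(floor(runif(ki, 0, L - ki * block_bp + 1)))
    starts <- gaps + (seq_len(ki) - 1) * block_bp
    chrom <- c(chrom, rep(layout$chrom[i], ki))
    start <- c(start, starts)
  }
  region_set(chrom, start, start + block_bp, layout = layout,
             domain_id = sprintf("domain_%04d", seq_along(start)))
}

uniform_intervals <- function(layout, n, width, id_prefix = "iv") {
  if (n == 0) {
    return(region_set(character(0), numeric(0), numeric(0), layout = layout))
  }
  ci <- sample.int(nrow(layout), n, replace = TRUE,
                   prob = layout$length / genome_length(layout))
  start <- floor(runif(n, 0, layout$length[ci] - width))
  gr <- region_set(layout$chrom[ci], start, start + width, layout = layout)
  gr$name <- sprintf("%s_%06d", id_prefix, seq_len(n))
  GenomicRanges::sort(gr)
}

simulate_te_annotation <- function(layout, config, te_width = 300) {
  n <- 4L * config$n_te_subfamilies  # a few copies per subfamily
  gr <- uniform_intervals(layout, n, te_width, id_prefix = "te")
  gr$subfamily <- sample(sprintf("subfam_%03d", seq_len(config$n_te_subfamilies)),
                         n, replace = TRUE)
  gr
}

simulate_gene_annotation <- function(layout, config) {
  n <- config$n_genes
  probs <- config$gene_biotype_probs
  if (!all(c("lncRNA", "pseudogene") %in% names(probs))) {
    stop_invalid_config("gene_biotype_probs must include lncRNA and pseudogene")
  }
  ci <- sample.int(nrow(layout), n, replace = TRUE,
                   prob = layout$length / genome_length(layout))
  start <- floor(runif(n, 0, layout$length[ci] - config$gene_width_bp))
  data.frame(
    gene_id = sprintf("gene_%05d", seq_len(n)),
    chrom = layout$chrom[ci],
    start = start,
    end = start + config$gene_width_bp,
    strand = sample(c("+", "-"), n, replace = TRUE),
    biotype = sample(names(probs), n, replace = TRUE, prob = probs),
    stringsAsFactors = FALSE
  )
}

#' Simulate differentially accessible regions with planted hotspots
#'
#' Background DARs are placed uniformly along the genome, except that the
#' probability of landing inside a repressive domain is
#' `domain_dar_enrichment` times the domain coverage (the excess mass is
#' taken uniformly from outside the domains), so the background set's
#' observed-over-coverage enrichment ratio converges to the configured
#' multiplier. Each planted hotspot
#' contributes exactly its `n_dars` additional intervals uniformly within
#' its span, on top of the background rate, so planted spans are regions
#' of *excess* DAR density (the signal the hotspot statistic detects).
#' The `planted` column records which rows are the planted contribution.
#'
#' Every DAR receives a direction: `"up"` with probability
#' `domain_up_prob` inside domains and `up_prob` outside. Effect-size
#' magnitudes are base-plus-exponential: background DARs mostly sit just
#' above the differential-calling threshold (few exceed the hotspot
#' counting cutoff of |log2FC| > 1), while planted DARs are strong
#' changes that all qualify. All simulated p-values are < 0.01 (these
#' are called DARs, not a significance null); effect-size nulls are
#' exercised through [simulate_cells()] and the differential test.
#'
#' @param layout a [genome_layout()].
#' @param domains `GRanges` of repressive domains (may be empty).
#' @param config a [sim_config()].
#' @return A `DARTable` data frame: `peak_id`, `chrom`, `start`, `end`,
#'   `log2_fold_change`, `p_value`, `adjusted_p`, `direction`, `planted`.
#' @export
simulate_dars <- function(layout, domains, config) {
  validate_sim_config(config)
  w <- config$dar_width_bp
  ph <- config$planted_hotspots
  with_seed(sub_seed(config$seed, 5L), {
    bg_mid <- sample_background_midpoints(layout, domains,
                                          config$n_background_dars,
                                          config$domain_dar_enrichment, w)
    pl <- planted_dar_midpoints(ph, w)
    chrom <- c(bg_mid$chrom, pl$chrom)
    mid <- c(bg_mid$mid, pl$mid)
    planted <- c(rep(FALSE, length(bg_mid$mid)), rep(TRUE, length(pl$mid)))
    n <- length(mid)
    if (n == 0) {
      empty_dar_table()
    } else {
    chrom_len <- layout$length[match(chrom, layout$chrom)]
    start <- pmin(pmax(0, round(mid - w / 2)), chrom_len - w)
    gr <- region_set(chrom, start, start + w, layout = layout)
    in_dom <- if (length(domains)) {
      GenomicRanges::countOverlaps(midpoints_gr(gr), domains) > 0
    } else rep(FALSE, n)
    p_up <- ifelse(in_dom, config$domain_up_prob, config$up_prob)
    up <- runif(n) < p_up
    mag <- ifelse(planted,
                  config$planted_lfc_base + rexp(n, config$planted_lfc_rate),
                  config$bg_lfc_base + rexp(n, config$bg_lfc_rate))
    lfc <- mag * ifelse(up, 1, -1)
    pval <- runif(n, 0, 0.001)
    out <- data.frame(
      peak_id = sprintf("dar_%06d", seq_len(n)),
      chrom = as.character(GenomeInfoDb::seqnames(gr)),
      start = bed_start(gr),
      end = bed_end(gr),
      log2_fold_change = lfc,
      p_value = pval,
      adjusted_p = pmin(1, pval * 5),
      direction = ifelse(up, "up", "down"),
      planted = planted,
      stringsAsFactors = FALSE
    )
    out <- out[order(match(out$chrom, layout$chrom), out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
    }
  })
}

empty_dar_table <- function() {
  data.frame(peak_id = character(0), chrom = character(0),
             start = numeric(0), end = numeric(0),
             log2_fold_change = numeric(0), p_value = numeric(0),
             adjusted_p = numeric(0), direction = character(0),
             planted = logical(0), stringsAsFactors = FALSE)
}

midpoints_gr <- function(gr) {
  mid <- floor((bed_start(gr) + bed_end(gr)) / 2)
  GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                         IRanges::IRanges(mid + 1, mid + 1))
}

## Sample background DAR midpoints. A midpoint lands inside domains with
## probability enrichment * coverage (uniform within domains), otherwise
## uniformly outside — so the observed-over-coverage enrichment ratio of
## the background set converges to `enrichment` itself.
sample_background_midpoints <- function(layout, domains, n,
                                        enrichment, width) {
  if (n == 0) return(list(chrom = character(0), mid = numeric(0)))
  genome <- region_set(layout$chrom, rep(0, nrow(layout)), layout$length,
                       layout = layout)
  dom_seg <- GenomicRanges::reduce(domains)
  non_seg <- GenomicRanges::setdiff(genome, dom_seg)
  coverage <- sum(as.numeric(GenomicRanges::width(dom_seg))) /
    genome_length(layout)
  p_dom <- enrichment * coverage
  if (p_dom > 1) {
    stop_invalid_config("domain_dar_enrichment x coverage exceeds 1 (",
                        signif(p_dom, 3), "); cannot renormalize")
  }
  in_dom <- runif(n) < p_dom
  draw_from <- function(seg, k) {
    wlen <- as.numeric(GenomicRanges::width(seg))
    pick <- sample.int(length(seg), k, replace = TRUE, prob = wlen)
    list(chrom = as.character(GenomeInfoDb::seqnames(seg))[pick],
         mid = bed_start(seg)[pick] + floor(runif(k, 0, wlen[pick])))
  }
  chrom <- character(n); mid <- numeric(n)
  if (any(in_dom)) {
    d <- draw_from(dom_seg, sum(in_dom))
    chrom[in_dom] <- d$chrom; mid[in_dom] <- d$mid
  }
  if (any(!in_dom)) {
    d <- draw_from(non_seg, sum(!in_dom))
    chrom[!in_dom] <- d$chrom; mid[!in_dom] <- d$mid
  }
  list(chrom = chrom, mid = mid)
}

planted_dar_midpoints <- function(ph, width) {
  if (is.null(ph) || nrow(ph) == 0) {
    return(list(chrom = character(0), mid = numeric(0)))
  }
  chrom <- character(0); mid <- numeric(0)
  for (i in seq_len(nrow(ph))) {
    lo <- ph$center_bp[i] - ph$span_bp[i] / 2 + width / 2
    hi <- ph$center_bp[i] + ph$span_bp[i] / 2 - width / 2
    chrom <- c(chrom, rep(ph$chrom[i], ph$n_dars[i]))
    mid <- c(mid, floor(runif(ph$n_dars[i], lo, hi)))
  }
  list(chrom = chrom, mid = mid)
}

#' Simulate per-cell metadata and a binary accessibility matrix
#'
#' Cells are drawn per age and replicate with multinomial cell-type
#' composition taken from `config$composition_spec`; matrix entries are
#' independent Bernoulli draws with the configured per-peak, per-age
#' accessibility probability. Identical configuration gives identical
#' output.
#'
#' @param layout a [genome_layout()] (carried through, not used for draws).
#' @param peaks `GRanges` of peaks (column space of the matrix) or an
#'   integer peak count.
#' @param config a [sim_config()].
#' @return A list with `cells` (data frame: `cell_id`, `cell_type`, `age`,
#'   `sex`, `region`, `replicate`) and `matrix` (sparse binary
#'   `dgCMatrix`, cells x peaks).
#' @export
simulate_cells <- function(layout, peaks, config) {
  validate_sim_config(config)
  n_peaks <- if (is.numeric(peaks)) as.integer(peaks) else length(peaks)
  peak_ids <- if (is.numeric(peaks)) sprintf("peak_%06d", seq_len(n_peaks))
              else peaks$name %||% sprintf("peak_%06d", seq_len(n_peaks))
  cs <- config$composition_spec
  with_seed(sub_seed(config$seed, 6L), {
    probs <- config$accessibility_spec
    if (is.null(probs)) {
      base <- runif(n_peaks, 0.01, 0.3)
      probs <- matrix(base, nrow = n_peaks, ncol = length(config$ages),
                      dimnames = list(NULL, as.character(config$ages)))
    }
    if (nrow(probs) != n_peaks) {
      stop_invalid_config("accessibility_spec must have one row per peak")
    }
    cells <- list(); mats <- list()
    cell_counter <- 0L
    for (age in config$ages) {
      spec <- cs[cs$age == age, ]
      page <- probs[, as.character(age)]
      for (rep_i in seq_len(config$n_replicates)) {
        n_cells <- config$cells_per_replicate
        counts <- as.vector(rmultinom(1, n_cells, spec$proportion))
        ct <- rep(spec$cell_type, counts)
        ids <- sprintf("cell_%07d", cell_counter + seq_len(n_cells))
        cell_counter <- cell_counter + n_cells
        cells[[length(cells) + 1L]] <- data.frame(
          cell_id = ids, cell_type = ct, age = age,
          sex = config$sexes[(rep_i - 1L) %% length(config$sexes) + 1L],
          region = config$regions[(rep_i - 1L) %% length(config$regions) + 1L],
          replicate = rep_i, stringsAsFactors = FALSE)
        ## Bernoulli draws, sparse assembly column-wise
        m <- matrix(rbinom(n_cells * n_peaks, 1L, rep(page, each = n_cells)),
                    nrow = n_cells, ncol = n_peaks)
        mats[[length(mats) + 1L]] <- Matrix::Matrix(m, sparse = TRUE)
      }
    }
    cells <- do.call(rbind, cells)
    mat <- do.call(rbind, mats)
    dimnames(mat) <- list(cells$cell_id, peak_ids)
    list(cells = cells, matrix = mat)
  })
}

#' Simulate a cell-by-TE-subfamily count matrix
#'
#' Counts are Poisson with a per-(subfamily, sample) rate: a subfamily
#' baseline drawn log-uniformly over `te_base_mean_range`, multiplied by a
#' gamma replicate effect (mean 1, variance `te_dispersion`) and, for
#' planted subfamilies at the oldest age, by `2^log2fc`.
#'
#' @param cells cell metadata as returned by [simulate_cells()].
#' @param config a [sim_config()].
#' @return Sparse `dgCMatrix` of counts, cells x subfamilies.
#' @export
simulate_te_matrix <- function(cells, config) {
  validate_sim_config(config)
  nf <- config$n_te_subfamilies
  feats <- sprintf("subfam_%03d", seq_len(nf))
  old_age <- max(config$ages)
  with_seed(sub_seed(config$seed, 7L), {
    base <- exp(runif(nf, log(config$te_base_mean_range[1]),
                      log(config$te_base_mean_range[2])))
    sample_key <- interaction(cells$age, cells$replicate, cells$region,
                              cells$sex, drop = TRUE)
    disp <- config$te_dispersion
    cols <- vector("list", nf)
    lfc <- rep(0, nf)
    if (!is.null(config$te_planted)) {
      lfc[config$te_planted$subfamily_index] <- config$te_planted$log2fc
    }
    n <- nrow(cells)
    counts <- matrix(0L, nrow = n, ncol = nf)
    for (s in levels(sample_key)) {
      idx <- which(sample_key == s)
      is_old <- cells$age[idx[1]] == old_age
      rate <- base * rgamma(nf, shape = 1 / disp, scale = disp)
      if (is_old) rate <- rate * 2^lfc
      counts[idx, ] <- matrix(rpois(length(idx) * nf,
                                    rep(rate, each = length(idx))),
                              nrow = length(idx))
    }
    dimnames(counts) <- list(cells$cell_id, feats)
    Matrix::Matrix(counts, sparse = TRUE)
  })
}

#' Simulate reference and query cluster expression profiles
#'
#' Reference profiles are i.i.d. standard normal per (cluster, gene).
#' Each query profile equals a reference profile plus Gaussian noise with
#' standard deviation `noise_sd`; with probability `confusion_rate` the
#' query cluster is generated from a *different* (uniformly chosen)
#' reference cluster. The true query-to-reference mapping is returned.
#'
#' @param config a [sim_config()] (`n_clusters`, `n_profile_genes`,
#'   `noise_sd`, `confusion_rate`).
#' @return A list with `reference` and `query` (matrices, clusters x
#'   genes, rownames = cluster ids) and `true_map` (named character
#'   vector: query cluster -> source reference cluster).
#' @export
simulate_label_profiles <- function(config) {
  validate_sim_config(config)
  k <- config$n_clusters; g <- config$n_profile_genes
  if (k < 2 || g < 2) stop_invalid_config("need >= 2 clusters and >= 2 genes")
  with_seed(sub_seed(config$seed, 8L), {
    genes <- sprintf("g%04d", seq_len(g))
    ref_ids <- sprintf("ref_%02d", seq_len(k))
    qry_ids <- sprintf("query_%02d", seq_len(k))
    reference <- matrix(rnorm(k * g), nrow = k,
                        dimnames = list(ref_ids, genes))
    source <- seq_len(k)
    confused <- runif(k) < config$confusion_rate
    for (i in which(confused)) {
      pool <- setdiff(seq_len(k), i)
      source[i] <- pool[sample.int(length(pool), 1)]
    }
    query <- reference[source, , drop = FALSE] +
      matrix(rnorm(k * g, sd = config$noise_sd), nrow = k)
    rownames(query) <- qry_ids
    list(reference = reference, query = query,
         true_map = setNames(ref_ids[source], qry_ids))
  })
}
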