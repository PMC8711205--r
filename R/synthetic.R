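# Seeded generators for every input the pipeline consumes, with truth
# manifests for recovery testing. Each generator draws from its own
# pseudo-random stream derived from the master seed by a fixed offset, so
# adding a generator never perturbs existing outputs.

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483647)
}

#' Default chromatogram simulation settings
#'
#' Gaussian elution peaks for the six mouse H1 subtypes and H2B on a
#' linear baseline with additive detector noise. Three molar-amount
#' profiles are available: `control` and `treated` reproduce total
#' H1/nucleosome stoichiometries of 0.58 and 0.67 with subtype shifts in
#' the directions seen during induced differentiation (H1a/H1b/H1e/H1.0
#' up, H1d down, H1c flat, H1.0 nearly absent in control); `balanced`
#' gives every subtype a comfortably sized peak and is meant for
#' per-subtype recovery checks.
#'
#' @param profile One of `"control"`, `"treated"`, `"balanced"`.
#' @param noise_sd Detector noise SD (mAU); default 0.2, typical of UV
#'   absorbency traces.
#' @param baseline_intercept,baseline_slope Linear baseline (mAU,
#'   mAU/min).
#' @param sigma Gaussian peak SD (minutes).
#' @param dt Time-grid step (minutes).
#' @return A list of chromatogram settings for [sim_config()].
#' @export
chromatogram_spec <- function(profile = c("control", "treated", "balanced"),
                              noise_sd = 0.2, baseline_intercept = 2,
                              baseline_slope = 0.1, sigma = 0.25,
                              dt = 0.01) {
  profile <- match.arg(profile)
  amounts <- switch(profile,
    control  = c(H1a = 0.06, H1b = 0.05, H1c = 0.15, H1d = 0.19,
                 H1e = 0.11, H1.0 = 0.02, H2B = 2.00),
    treated  = c(H1a = 0.09, H1b = 0.08, H1c = 0.15, H1d = 0.14,
                 H1e = 0.16, H1.0 = 0.05, H2B = 2.00),
    balanced = c(H1a = 0.10, H1b = 0.12, H1c = 0.15, H1d = 0.18,
                 H1e = 0.12, H1.0 = 0.08, H2B = 2.00))
  list(profile = profile,
       amounts = amounts,
       # peptide bonds = residues - 1 (approximate mouse residue counts)
       bonds = c(H1a = 212, H1b = 221, H1c = 210, H1d = 220,
                 H1e = 217, H1.0 = 193, H2B = 125),
       centers = c(H1a = 51, H1b = 54, H1c = 57, H1d = 60,
                   H1e = 63, H1.0 = 48, H2B = 40),
       sigma = sigma, noise_sd = noise_sd,
       baseline_intercept = baseline_intercept,
       baseline_slope = baseline_slope,
       dt = dt, t_min = 35, t_max = 70)
}

#' Simulation configuration
#'
#' Defines the synthetic study: genome shape, annotation density, planted
#' CUT&RUN enrichment, the negative-binomial ATAC count model with
#' planted fold changes, the planted integration categories, and the
#' chromatogram model.
#'
#' @param seed Master seed (all generator streams derive from it).
#' @param n_chroms,chrom_length Genome shape (default 2 x 2 Mb).
#' @param bin_width bedGraph bin width in bp (default 10).
#' @param n_genes,n_tes Annotation density (defaults 200 / 300).
#' @param n_planted_enriched Condition-shared enriched CUT&RUN blocks
#'   (default 60).
#' @param enrichment_fold Signal multiple of enriched blocks over
#'   background (default 8).
#' @param background_rate Mean background bedGraph value per bin
#'   (default 1).
#' @param block_width Planted block width in bp (default 500).
#' @param n_regions Random ATAC regions (default 2000), in addition to
#'   one region per planted category gene.
#' @param depth_mean Mean counts per region per sample (default 50).
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); default 0.001, i.e. near-Poisson counting
#'   noise.
#' @param n_planted_diff Planted differential regions outside category
#'   genes (default 100, half up / half down).
#' @param planted_fc Linear fold change of planted regions (default 8).
#' @param planted_categories Named integer vector of genes per
#'   integration category (default `c(I = 11, II = 73, III = 5)`).
#' @param chromatogram A [chromatogram_spec()] list.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_chroms = 2, chrom_length = 2e6,
                       bin_width = 10, n_genes = 200, n_tes = 300,
                       n_planted_enriched = 60, enrichment_fold = 8,
                       background_rate = 1, block_width = 500,
                       n_regions = 2000, depth_mean = 50,
                       nb_dispersion = 0.001, n_planted_diff = 100,
                       planted_fc = 8,
                       planted_categories = c(I = 11, II = 73, III = 5),
                       chromatogram = chromatogram_spec()) {
  if (enrichment_fold <= 1 && enrichment_fold != 1)
    stop("enrichment_fold must be >= 1")
  if (chrom_length %% bin_width != 0)
    stop("chrom_length must be a multiple of bin_width")
  stopifnot(n_genes >= 0, n_tes >= 0, n_planted_enriched >= 0,
            n_regions >= 0, n_planted_diff >= 0, planted_fc > 0)
  if (sum(planted_categories) + n_planted_enriched > n_genes)
    stop("planted genes exceed n_genes")
  structure(list(seed = seed, n_chroms = n_chroms,
                 chrom_length = chrom_length, bin_width = bin_width,
                 n_genes = n_genes, n_tes = n_tes,
                 n_planted_enriched = n_planted_enriched,
                 enrichment_fold = enrichment_fold,
                 background_rate = background_rate,
                 block_width = block_width, n_regions = n_regions,
                 depth_mean = depth_mean, nb_dispersion = nb_dispersion,
                 n_planted_diff = n_planted_diff, planted_fc = planted_fc,
                 planted_categories = planted_categories,
                 chromatogram = chromatogram),
            class = "sim_config")
}

#' Generate a synthetic gene and TE annotation
#'
#' Genes are placed one per equal-width slot so that bodies (2-8 kb) and
#' their TSS windows never overlap; strands are random. TEs (200-6000 bp,
#' classes LTR/SINE/LINE/DNA) are placed uniformly and may overlap genes
#' and each other, as real repeats do. Genes are also assigned simulation
#' roles: the planted integration categories (I/II/III), `shared`
#' (condition-shared CUT&RUN enrichment) or `none`.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `genes`, `tes` and `roles` (data.frame
#'   `gene_id`, `role`).
#' @export
make_annotation <- function(cfg) {
  set.seed(derive_seed(cfg$seed, 1L))
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  per <- rep(cfg$n_genes %/% cfg$n_chroms, cfg$n_chroms)
  if (cfg$n_genes %% cfg$n_chroms > 0)
    per[seq_len(cfg$n_genes %% cfg$n_chroms)] <-
      per[seq_len(cfg$n_genes %% cfg$n_chroms)] + 1L
  genes <- NULL
  if (cfg$n_genes > 0) {
    gl <- lapply(seq_len(cfg$n_chroms), function(ci) {
      n <- per[ci]
      if (n == 0L) return(NULL)
      slot <- floor(cfg$chrom_length / n)
      if (slot < 20000)
        stop("infeasible packing: need >= 20 kb of chromosome per gene")
      slot_start <- (seq_len(n) - 1L) * slot
      len <- round(runif(n, 2000, 8000))
      start <- slot_start + 6000
      data.frame(chrom = chroms[ci], start = start, end = start + len,
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    genes <- do.call(rbind, gl)
    genes$gene_id <- sprintf("g%04d", seq_len(nrow(genes)))
    rownames(genes) <- NULL
  } else {
    genes <- data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), strand = character(0),
                        gene_id = character(0))
  }
  tes <- if (cfg$n_tes > 0) {
    ch <- sample(chroms, cfg$n_tes, replace = TRUE)
    len <- round(runif(cfg$n_tes, 200, 6000))
    start <- floor(runif(cfg$n_tes, 0, cfg$chrom_length - len))
    data.frame(chrom = ch, start = start, end = start + len,
               te_class = sample(c("LTR", "SINE", "LINE", "DNA"),
                                 cfg$n_tes, replace = TRUE),
               stringsAsFactors = FALSE)[order(ch, start), ]
  } else {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               te_class = character(0))
  }
  rownames(tes) <- NULL
  # simulation roles: category genes first, then shared-enrichment genes
  roles <- data.frame(gene_id = genes$gene_id,
                      role = rep("none", nrow(genes)),
                      stringsAsFactors = FALSE)
  n_cat <- sum(cfg$planted_categories)
  n_pick <- n_cat + cfg$n_planted_enriched
  if (n_pick > 0 && nrow(genes) > 0) {
    picked <- sample(nrow(genes), n_pick)
    lab <- c(rep(names(cfg$planted_categories), cfg$planted_categories),
             rep("shared", cfg$n_planted_enriched))
    roles$role[picked] <- lab
  }
  list(genes = genes, tes = tes, roles = roles)
}

# Planted CUT&RUN block coordinates for one condition, snapped to the bin
# grid: shared blocks in both conditions, gain blocks (categories I, III)
# in treated only, loss blocks (category II) in control only.
planted_blocks_for <- function(cfg, ann, condition) {
  role <- ann$roles$role
  want <- switch(condition,
                 treated = role %in% c("shared", "I", "III"),
                 control = role %in% c("shared", "II"))
  g <- ann$genes[want, , drop = FALSE]
  if (nrow(g) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), gene_id = character(0)))
  tss <- gene_tss(g)
  bw <- cfg$bin_width
  bs <- pmax(0, floor((tss - cfg$block_width / 2) / bw) * bw)
  be <- pmin(cfg$chrom_length, bs + ceiling(cfg$block_width / bw) * bw)
  out <- data.frame(chrom = g$chrom, start = bs, end = be,
                    gene_id = g$gene_id, stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Simulate a CUT&RUN bedGraph coverage track
#'
#' Poisson background (`background_rate` per `bin_width` bp bin) with
#' planted enriched blocks at `background_rate * enrichment_fold`.
#' Shared blocks appear in both conditions; category I/III gene blocks in
#' treated only; category II blocks in control only. Replicates share
#' block locations with independent noise.
#'
#' @param cfg A [sim_config()].
#' @param ann Annotation from [make_annotation()].
#' @param condition `"control"` or `"treated"`.
#' @param replicate Replicate number (1 or 2).
#' @return A list: `track` (bedGraph data.frame of nonzero records) and
#'   `blocks` (planted block manifest for this condition).
#' @export
simulate_bedgraph <- function(cfg, ann, condition = c("control", "treated"),
                              replicate = 1L) {
  condition <- match.arg(condition)
  cond_idx <- if (condition == "control") 0L else 1L
  set.seed(derive_seed(cfg$seed, 10L + 4L * cond_idx + replicate))
  blocks <- planted_blocks_for(cfg, ann, condition)
  bw <- cfg$bin_width
  nbins <- cfg$chrom_length %/% bw
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  recs <- lapply(chroms, function(ch) {
    v <- rpois(nbins, cfg$background_rate)
    b <- blocks[blocks$chrom == ch, , drop = FALSE]
    # on a zero background the fold acts as the absolute enriched rate
    enriched_rate <- if (cfg$background_rate > 0)
      cfg$background_rate * cfg$enrichment_fold else cfg$enrichment_fold
    for (i in seq_len(nrow(b))) {
      idx <- (b$start[i] / bw + 1L):(b$end[i] / bw)
      v[idx] <- rpois(length(idx), enriched_rate)
    }
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values > 0
    data.frame(chrom = ch, start = starts[keep] * bw,
               end = ends[keep] * bw, value = r$values[keep],
               stringsAsFactors = FALSE)
  })
  list(track = do.call(rbind, recs), blocks = blocks)
}

#' Simulate an ATAC region count table
#'
#' Negative-binomial counts (mean `depth_mean`, variance
#' `mu + nb_dispersion * mu^2`) for 2 control and 2 treated samples over
#' `n_regions` random regions plus one 500 bp region centred at each
#' planted category gene's TSS. Planted regions multiply (up) or divide
#' (down) the treated mean by `planted_fc`: category I genes are planted
#' up, categories II and III down, and `n_planted_diff` additional
#' regions away from category TSS windows are planted half up, half down.
#' Library sizes are the column sums.
#'
#' @param cfg A [sim_config()].
#' @param ann Annotation from [make_annotation()].
#' @return A list: `table` (a [region_counts()]) and `planted`
#'   (data.frame `chrom`, `start`, `end`, `region_index`, `direction`,
#'   `gene_id`).
#' @export
simulate_counts <- function(cfg, ann) {
  set.seed(derive_seed(cfg$seed, 2L))
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  len <- round(runif(cfg$n_regions, 200, 1000))
  start <- floor(runif(cfg$n_regions, 0, cfg$chrom_length - len))
  regions <- data.frame(chrom = sample(chroms, cfg$n_regions, replace = TRUE),
                        start = start, end = start + len,
                        stringsAsFactors = FALSE)
  cat_genes <- ann$genes[ann$roles$role %in% c("I", "II", "III"), ,
                         drop = FALSE]
  cat_roles <- ann$roles$role[ann$roles$role %in% c("I", "II", "III")]
  if (nrow(cat_genes) > 0) {
    tss <- gene_tss(cat_genes)
    cat_regions <- data.frame(chrom = cat_genes$chrom,
                              start = pmax(0, tss - 250),
                              end = tss + 250, stringsAsFactors = FALSE)
    regions <- rbind(regions, cat_regions)
  }
  n_tot <- nrow(regions)
  n_cat <- nrow(cat_genes)
  planted <- data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), region_index = integer(0),
                        direction = character(0), gene_id = character(0),
                        stringsAsFactors = FALSE)
  if (n_cat > 0) {
    idx <- (n_tot - n_cat + 1L):n_tot
    planted <- rbind(planted, data.frame(
      chrom = regions$chrom[idx], start = regions$start[idx],
      end = regions$end[idx], region_index = idx,
      direction = ifelse(cat_roles == "I", "up", "down"),
      gene_id = cat_genes$gene_id, stringsAsFactors = FALSE))
  }
  if (cfg$n_planted_diff > 0 && cfg$n_regions > 0) {
    # keep generic planted effects away from category TSS windows so the
    # planted category directions stay unambiguous
    eligible <- seq_len(cfg$n_regions)
    if (n_cat > 0) {
      win <- tss_window(cat_genes)
      bad <- S4Vectors::queryHits(
        IRanges::findOverlaps(as_granges(regions[eligible, ]),
                              as_granges(win)))
      eligible <- setdiff(eligible, eligible[unique(bad)])
    }
    n_up <- min(cfg$n_planted_diff, length(eligible)) %/% 2
    n_dn <- min(cfg$n_planted_diff, length(eligible)) - n_up
    pick <- sample(eligible, n_up + n_dn)
    planted <- rbind(planted, data.frame(
      chrom = regions$chrom[pick], start = regions$start[pick],
      end = regions$end[pick], region_index = pick,
      direction = rep(c("up", "down"), c(n_up, n_dn)),
      gene_id = NA_character_, stringsAsFactors = FALSE))
  }
  samples <- data.frame(
    sample = c("control_1", "control_2", "treated_1", "treated_2"),
    condition = rep(c("control", "treated"), each = 2L),
    replicate = rep(c("1", "2"), 2L), stringsAsFactors = FALSE)
  mu <- matrix(cfg$depth_mean, n_tot, 4L)
  if (nrow(planted) > 0) {
    fc <- ifelse(planted$direction == "up", cfg$planted_fc,
                 1 / cfg$planted_fc)
    mu[planted$region_index, 3:4] <- cfg$depth_mean * fc
  }
  counts <- matrix(0L, n_tot, 4L)
  for (j in 1:4) {
    counts[, j] <- if (cfg$nb_dispersion > 0)
      rnbinom(n_tot, mu = mu[, j], size = 1 / cfg$nb_dispersion)
    else rpois(n_tot, mu[, j])
  }
  samples$library_size <- colSums(counts)
  list(table = region_counts(regions, samples, counts), planted = planted)
}

#' Simulate an RP-HPLC chromatogram
#'
#' Sum of Gaussian elution peaks (one per subtype) whose analytic areas
#' equal `amount * peptide_bonds`, so that peptide-bond-adjusted areas
#' recover molar amounts, plus a linear baseline and Gaussian detector
#' noise. Integration windows are centred at the peak means with +/- 5
#' sigma half-width; peak centres must be separated by at least 4 sigma.
#'
#' @param cfg A [sim_config()] (its `chromatogram` entry is used, with
#'   `profile` overriding the configured amount profile).
#' @param profile `"control"`, `"treated"` or `"balanced"`; defaults to
#'   the configured profile.
#' @return A list: `chromatogram`, `windows`, `subtypes` (label,
#'   residues, n_peptide_bonds), `true_areas` (raw Gaussian areas),
#'   `true_amounts`, `true_total_ratio`.
#' @export
simulate_chromatogram <- function(cfg, profile = NULL) {
  cs <- cfg$chromatogram
  if (!is.null(profile)) {
    cs <- chromatogram_spec(profile, noise_sd = cs$noise_sd,
                            baseline_intercept = cs$baseline_intercept,
                            baseline_slope = cs$baseline_slope,
                            sigma = cs$sigma, dt = cs$dt)
  }
  prof_idx <- match(cs$profile, c("control", "treated", "balanced"))
  set.seed(derive_seed(cfg$seed, 30L + prof_idx))
  labels <- names(cs$amounts)
  centers <- cs$centers[labels]
  if (any(diff(sort(centers)) < 4 * cs$sigma))
    stop("peak centres must be separated by >= 4 sigma")
  windows <- data.frame(label = labels,
                        t_start = centers - 5 * cs$sigma,
                        t_end = centers + 5 * cs$sigma,
                        stringsAsFactors = FALSE)
  validate_windows(windows)
  areas <- cs$amounts * cs$bonds[labels]
  t <- seq(cs$t_min, cs$t_max, by = cs$dt)
  sig <- cs$baseline_intercept + cs$baseline_slope * (t - cs$t_min)
  for (i in seq_along(labels))
    sig <- sig + areas[[i]] / (cs$sigma * sqrt(2 * pi)) *
      exp(-(t - centers[[i]])^2 / (2 * cs$sigma^2))
  if (cs$noise_sd > 0) sig <- sig + rnorm(length(t), 0, cs$noise_sd)
  h1 <- setdiff(labels, "H2B")
  list(chromatogram = chromatogram(t, sig),
       windows = windows,
       subtypes = data.frame(label = labels,
                             residues = as.integer(cs$bonds[labels] + 1),
                             n_peptide_bonds = as.integer(cs$bonds[labels]),
                             stringsAsFactors = FALSE),
       true_areas = areas,
       true_amounts = cs$amounts,
       true_total_ratio = sum(cs$amounts[h1]) / (cs$amounts[["H2B"]] / 2))
}

#' Write a complete synthetic input bundle
#'
#' Emits every pipeline input to `outdir`: gene and TE tables, four
#' CUT&RUN bedGraph tracks (2 conditions x 2 replicates), the ATAC count
#' table and sample sheet, control and treated chromatograms with window
#' and subtype tables, and the truth manifest (TSV + JSON).
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths) and
#'   `manifest` (annotation roles, planted blocks and regions, true
#'   chromatogram areas).
#' @export
simulate_bundle <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  ann <- make_annotation(cfg)
  paths <- list(genes = p("genes.tsv"), tes = p("te.tsv"),
                counts = p("atac_counts.tsv"), samples = p("samples.tsv"),
                windows = p("h1_windows.tsv"),
                subtypes = p("h1_subtypes.tsv"))
  write_tsv(ann$genes, paths$genes)
  write_tsv(ann$tes, paths$tes)

  blocks <- list()
  paths$bedgraph <- list()
  for (cond in c("control", "treated")) {
    paths$bedgraph[[cond]] <- list()
    for (rep_i in 1:2) {
      sim <- simulate_bedgraph(cfg, ann, cond, rep_i)
      f <- p(sprintf("cutrun_%s_rep%d.bedgraph", cond, rep_i))
      write_bedgraph(sim$track, f)
      paths$bedgraph[[cond]][[rep_i]] <- f
      blocks[[cond]] <- sim$blocks
    }
  }
  blocks_df <- do.call(rbind, lapply(names(blocks), function(cond)
    data.frame(blocks[[cond]], condition = cond,
               stringsAsFactors = FALSE)))
  write_tsv(blocks_df, p("truth_planted_blocks.tsv"))

  cts <- simulate_counts(cfg, ann)
  counts_df <- data.frame(cts$table$regions,
                          as.data.frame(cts$table$counts))
  write_tsv(counts_df, paths$counts)
  write_tsv(cts$table$samples, paths$samples)
  write_tsv(cts$planted, p("truth_planted_regions.tsv"))
  write_tsv(ann$roles, p("truth_gene_roles.tsv"))

  paths$chromatogram <- list()
  chrom_truth <- list()
  for (prof in c("control", "treated")) {
    sim <- simulate_chromatogram(cfg, profile = prof)
    f <- p(sprintf("chromatogram_%s.tsv", prof))
    write_tsv(as.data.frame(sim$chromatogram), f)
    paths$chromatogram[[prof]] <- f
    chrom_truth[[prof]] <- list(true_areas = as.list(sim$true_areas),
                                true_amounts = as.list(sim$true_amounts),
                                true_total_ratio = sim$true_total_ratio)
    if (prof == "control") {
      write_tsv(sim$windows, paths$windows)
      write_tsv(sim$subtypes[, c("label", "residues")], paths$subtypes)
    }
  }
  manifest <- list(seed = cfg$seed, roles = ann$roles,
                   planted_blocks = blocks_df,
                   planted_regions = cts$planted,
                   chromatograms = chrom_truth)
  jsonlite::write_json(manifest, p("truth_manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  paths$manifest <- p("truth_manifest.json")
  invisible(list(paths = paths, manifest = manifest))
}
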