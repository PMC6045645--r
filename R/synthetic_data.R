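#' Default synthetic-study configuration
#'
#' The standard fixture emulates a 3-vs-3 RRBS comparison on one
#' desk-scale pseudo-chromosome: 5000 CpGs on 1 Mb, 20 hypermethylated and
#' 10 hypomethylated implanted regions of at least 5 CpGs with methylation
#' shift 0.4, ~30x mean CpG coverage, beta-binomial replicate noise with
#' precision 10, 200 genes, and the 2:1 hyper:hypo asymmetry of a
#' hypermethylation phenotype.
#'
#' @param ... Overrides for any default field.
#' @return Named list of generator parameters.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_chroms = 1L, chrom_len = 1000000L, n_cpgs = 5000L,
    n_dmrs_hyper = 20L, n_dmrs_hypo = 10L,
    dmr_min_cpgs = 5L, dmr_max_cpgs = 8L, delta_pi = 0.4,
    n_genes = 200L, n_per_group = 3L,
    coverage_mean = 30, coverage_size = 5, dispersion_phi = 10,
    expr_size = 10, expr_meanlog = log(200), expr_sdlog = 1,
    background_prob = 0.15, enrichment_multiplier = 3
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  cfg
}

#' Simulate the ground truth of a synthetic methylation study
#'
#' Draws CpG positions (sorted, minimum spacing 2 so dinucleotides never
#' collide), bimodal baseline methylation levels
#' (0.7 Beta(1,10) + 0.3 Beta(10,1): mostly unmethylated CpG-island-like
#' sites plus a methylated tail), disjoint affected regions of consecutive
#' CpGs that receive a +/- delta_pi methylation shift in the mutant group
#' (their baseline is drawn direction-coherently -- low for
#' hypermethylation targets, high for hypomethylation targets -- so the
#' shift survives the clip of methylation levels to [0.02, 0.98]),
#' and genes: one gene TSS is planted within 1 kb of each affected region
#' with an expression fold-change of sign opposite to the methylation
#' shift; the remaining genes are placed uniformly, most of them null.
#'
#' @param config List from \code{\link{sim_config}}.
#' @param seed Integer seed; identical (config, seed) gives identical truth.
#' @return Object of class \code{sim_truth}: list with config, seed, cpgs
#'   (data.frame chrom, pos, baseline_pi, mu_mut, region_id), regions
#'   (data.frame chrom, start, end, delta_pi, direction, n_cpgs), genes
#'   (data.frame gene_id, chrom, tss, strand, log2fc, promoter_linked,
#'   region_id).
#' @export
simulate_truth <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  n_dmrs <- config$n_dmrs_hyper + config$n_dmrs_hypo
  if (n_dmrs * (config$dmr_max_cpgs + 2L) > config$n_cpgs) {
    stop("infeasible config: affected regions would need more CpGs than exist")
  }
  chroms <- paste0("chrS", seq_len(config$n_chroms))
  per_chrom <- diff(round(seq(0L, config$n_cpgs, length.out = config$n_chroms + 1L)))
  cpg_list <- lapply(seq_len(config$n_chroms), function(i) {
    pos <- sort(sample.int(config$chrom_len %/% 2L, per_chrom[i])) * 2L
    data.frame(chrom = chroms[i], pos = pos, stringsAsFactors = FALSE)
  })
  cpgs <- do.call(rbind, cpg_list)
  n <- nrow(cpgs)
  comp <- stats::runif(n) < 0.7
  cpgs$baseline_pi <- ifelse(comp, stats::rbeta(n, 1, 10), stats::rbeta(n, 10, 1))
  cpgs$baseline_pi <- pmin(pmax(cpgs$baseline_pi, 0.02), 0.98)
  cpgs$region_id <- NA_integer_

  # pick disjoint runs of consecutive CpGs (2-CpG buffer between runs)
  len_choices <- seq(config$dmr_min_cpgs, config$dmr_max_cpgs)
  run_len <- len_choices[sample.int(length(len_choices), n_dmrs, replace = TRUE)]
  taken <- rep(FALSE, n)
  starts <- integer(n_dmrs)
  for (r in seq_len(n_dmrs)) {
    placed <- FALSE
    for (attempt in seq_len(10000L)) {
      s <- sample.int(n - run_len[r] + 1L, 1L)
      span <- max(1L, s - 2L):min(n, s + run_len[r] + 1L)
      same_chrom <- cpgs$chrom[s] == cpgs$chrom[s + run_len[r] - 1L]
      if (same_chrom && !any(taken[span])) {
        taken[s:(s + run_len[r] - 1L)] <- TRUE
        starts[r] <- s
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place affected region ", r, "; config too dense")
  }
  direction <- c(rep("hyper", config$n_dmrs_hyper),
                 rep("hypo", config$n_dmrs_hypo))
  delta <- ifelse(direction == "hyper", config$delta_pi, -config$delta_pi)
  regions <- data.frame(
    chrom = cpgs$chrom[starts],
    start = cpgs$pos[starts],
    end = cpgs$pos[starts + run_len - 1L] + 2L,
    delta_pi = delta, direction = direction, n_cpgs = run_len,
    stringsAsFactors = FALSE)
  for (r in seq_len(n_dmrs)) {
    member <- starts[r]:(starts[r] + run_len[r] - 1L)
    cpgs$region_id[member] <- r
    # affected regions get a direction-coherent baseline so the implanted
    # shift has headroom: hypermethylation targets lowly methylated
    # promoter-like CpGs, hypomethylation targets methylated ones
    cpgs$baseline_pi[member] <- if (direction[r] == "hyper") {
      stats::rbeta(run_len[r], 1, 10)
    } else {
      stats::rbeta(run_len[r], 10, 1)
    }
  }
  cpgs$baseline_pi <- pmin(pmax(cpgs$baseline_pi, 0.02), 0.98)
  shift <- ifelse(is.na(cpgs$region_id), 0, delta[cpgs$region_id])
  cpgs$mu_mut <- pmin(pmax(cpgs$baseline_pi + shift, 0.02), 0.98)

  # genes: one planted promoter per affected region, the rest uniform
  n_linked <- min(n_dmrs, config$n_genes)
  gene_id <- sprintf("gene_%04d", seq_len(config$n_genes))
  chrom <- character(config$n_genes); tss <- integer(config$n_genes)
  log2fc <- numeric(config$n_genes)
  linked <- rep(FALSE, config$n_genes)
  region_id <- rep(NA_integer_, config$n_genes)
  if (n_linked > 0L) {
    idx <- seq_len(n_linked)
    chrom[idx] <- regions$chrom[idx]
    tss[idx] <- pmax(regions$start[idx] - sample(50:800, n_linked, replace = TRUE), 0L)
    log2fc[idx] <- -sign(regions$delta_pi[idx]) *
      abs(stats::rnorm(n_linked, mean = 1.5, sd = 0.5))
    linked[idx] <- TRUE
    region_id[idx] <- idx
  }
  if (config$n_genes > n_linked) {
    idx <- (n_linked + 1L):config$n_genes
    ch_i <- sample.int(config$n_chroms, length(idx), replace = TRUE)
    chrom[idx] <- chroms[ch_i]
    tss[idx] <- sample.int(config$chrom_len, length(idx))
    de <- stats::runif(length(idx)) < 0.2
    log2fc[idx] <- ifelse(de, stats::rnorm(length(idx), 0, 1), 0)
  }
  genes <- data.frame(gene_id = gene_id, chrom = chrom, tss = tss,
                      strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
                      log2fc = log2fc, promoter_linked = linked,
                      region_id = region_id, stringsAsFactors = FALSE)
  structure(list(config = config, seed = seed, cpgs = cpgs,
                 regions = regions, genes = genes),
            class = "sim_truth")
}

#' Simulate strand-level RRBS cytosine counts
#'
#' Per CpG, sample and strand: coverage is negative-binomial (mean half the
#' CpG coverage, size \code{coverage_size}); the replicate's methylation
#' probability p is drawn once per (CpG, sample) from
#' Beta(mu phi, (1-mu) phi) with mu the group's true level, and shared by
#' the two strands; methylated reads are Binomial(N, p). Zero-coverage
#' strand records are omitted (absent = not profiled). The mismatched-noise
#' switch \code{p_model = "logitnorm"} replaces the Beta draw with a
#' logit-normal of sd 1/sqrt(phi) to probe robustness to model
#' misspecification.
#'
#' @param truth \code{sim_truth} object.
#' @param n_per_group Replicates per group (default from truth config).
#' @param coverage_mean Mean total CpG coverage (both strands).
#' @param dispersion_phi Beta precision of between-replicate noise.
#' @param seed Integer seed.
#' @param p_model "beta" (default) or "logitnorm".
#' @return List with \code{records} (named list of per-sample strand-level
#'   count data.frames in \code{read_cytosine_counts} layout) and
#'   \code{design} (named vector sample -> group, groups "wt"/"mut").
#' @export
simulate_meth_counts <- function(truth, n_per_group = NULL,
                                 coverage_mean = NULL, dispersion_phi = NULL,
                                 seed = 1L, p_model = "beta") {
  cfg <- truth$config
  if (is.null(n_per_group)) n_per_group <- cfg$n_per_group
  if (is.null(coverage_mean)) coverage_mean <- cfg$coverage_mean
  if (is.null(dispersion_phi)) dispersion_phi <- cfg$dispersion_phi
  if (coverage_mean <= 0) stop("coverage_mean must be > 0")
  set.seed(seed)
  samples <- c(paste0("wt_", seq_len(n_per_group)),
               paste0("mut_", seq_len(n_per_group)))
  design <- stats::setNames(rep(c("wt", "mut"), each = n_per_group), samples)
  n <- nrow(truth$cpgs)
  records <- list()
  for (s in samples) {
    mu <- if (design[[s]] == "mut") truth$cpgs$mu_mut else truth$cpgs$baseline_pi
    p <- if (p_model == "beta") {
      stats::rbeta(n, mu * dispersion_phi, (1 - mu) * dispersion_phi)
    } else if (p_model == "logitnorm") {
      stats::plogis(stats::qlogis(mu) + stats::rnorm(n, 0, 1 / sqrt(dispersion_phi)))
    } else {
      stop("p_model must be 'beta' or 'logitnorm'")
    }
    n_fwd <- stats::rnbinom(n, mu = coverage_mean / 2, size = cfg$coverage_size)
    n_rev <- stats::rnbinom(n, mu = coverage_mean / 2, size = cfg$coverage_size)
    k_fwd <- stats::rbinom(n, n_fwd, p)
    k_rev <- stats::rbinom(n, n_rev, p)
    fwd <- data.frame(chrom = truth$cpgs$chrom, pos = truth$cpgs$pos,
                      strand = "+", context = "CpG", meth_reads = k_fwd,
                      total_reads = n_fwd, stringsAsFactors = FALSE)
    rev_ <- data.frame(chrom = truth$cpgs$chrom, pos = truth$cpgs$pos + 1L,
                       strand = "-", context = "CpG", meth_reads = k_rev,
                       total_reads = n_rev, stringsAsFactors = FALSE)
    rec <- rbind(fwd[fwd$total_reads > 0L, ], rev_[rev_$total_reads > 0L, ])
    rec <- rec[order(rec$chrom, rec$pos, method = "radix"), , drop = FALSE]
    rownames(rec) <- NULL
    records[[s]] <- rec
  }
  list(records = records, design = design)
}

#' Simulate feature interval sets with controlled enrichment
#'
#' Builds one "enriched" set whose intervals cover CpGs inside affected
#' regions with probability multiplier x background_prob (capped at 1) and
#' all other CpGs with the background probability, plus two neutral sets
#' drawn at the background probability everywhere. Each interval covers
#' exactly one CpG dinucleotide ([pos, pos+2)), so realized coverage ratios
#' are directly interpretable.
#'
#' @param truth \code{sim_truth} object.
#' @param enrichment_multiplier Coverage multiplier for affected CpGs
#'   (>= 1).
#' @param background_prob Per-CpG background coverage probability.
#' @param seed Integer seed.
#' @return Named list of interval data.frames: enriched, neutral_a,
#'   neutral_b.
#' @export
simulate_features <- function(truth, enrichment_multiplier = NULL,
                              background_prob = NULL, seed = 1L) {
  cfg <- truth$config
  if (is.null(enrichment_multiplier)) enrichment_multiplier <- cfg$enrichment_multiplier
  if (is.null(background_prob)) background_prob <- cfg$background_prob
  if (enrichment_multiplier < 1) stop("enrichment_multiplier must be >= 1")
  set.seed(seed)
  affected <- !is.na(truth$cpgs$region_id)
  p_cover <- ifelse(affected, pmin(enrichment_multiplier * background_prob, 1),
                    background_prob)
  pick <- function(prob) {
    sel <- stats::runif(nrow(truth$cpgs)) < prob
    data.frame(chrom = truth$cpgs$chrom[sel], start = truth$cpgs$pos[sel],
               end = truth$cpgs$pos[sel] + 2L, stringsAsFactors = FALSE)
  }
  list(enriched = pick(p_cover),
       neutral_a = pick(background_prob),
       neutral_b = pick(background_prob))
}

#' Simulate a gene expression count matrix
#'
#' Per gene, counts are negative binomial with mean
#' basemean x size_factor_s x 2^(+/- log2fc/2) (plus sign in the mutant
#' group) and size \code{expr_size}; base means are log-normal and sample
#' size factors mildly variable (log-normal sd 0.15), so the
#' median-of-ratios normalization has something to recover.
#'
#' @param truth \code{sim_truth} object.
#' @param n_per_group Replicates per group.
#' @param seed Integer seed.
#' @return List with \code{counts} (integer matrix genes x samples),
#'   \code{design} (named vector sample -> group), and
#'   \code{true_size_factors}.
#' @export
simulate_expression <- function(truth, n_per_group = NULL, seed = 1L) {
  cfg <- truth$config
  if (is.null(n_per_group)) n_per_group <- cfg$n_per_group
  set.seed(seed)
  samples <- c(paste0("wt_", seq_len(n_per_group)),
               paste0("mut_", seq_len(n_per_group)))
  design <- stats::setNames(rep(c("wt", "mut"), each = n_per_group), samples)
  n_genes <- nrow(truth$genes)
  basemean <- stats::rlnorm(n_genes, cfg$expr_meanlog, cfg$expr_sdlog)
  sf <- stats::rlnorm(length(samples), 0, 0.15)
  counts <- matrix(0L, n_genes, length(samples),
                   dimnames = list(truth$genes$gene_id, samples))
  for (j in seq_along(samples)) {
    sign_ <- if (design[[j]] == "mut") 1 else -1
    mu <- basemean * sf[j] * 2^(sign_ * truth$genes$log2fc / 2)
    counts[, j] <- stats::rnbinom(n_genes, mu = mu, size = cfg$expr_size)
  }
  list(counts = counts, design = design, true_size_factors = sf)
}

#' Simulate an array-style beta-value matrix
#'
#' One probe per CpG: beta = clip(baseline + global_shift in the mutant
#' group + Normal(0, noise_sd), 0, 1). Emulates the probe-level group
#' structure of 450K-style data for the whole-array group comparison.
#'
#' @param truth \code{sim_truth} object.
#' @param n_mut,n_wt Samples per group.
#' @param global_shift Methylation shift added to every mutant probe.
#' @param noise_sd Per-cell Gaussian noise sd.
#' @param seed Integer seed.
#' @return \code{beta_matrix} object (see \code{\link{read_beta_matrix}}).
#' @export
simulate_beta_matrix <- function(truth, n_mut = 2L, n_wt = 2L,
                                 global_shift = 0.05, noise_sd = 0.05,
                                 seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  n <- nrow(truth$cpgs)
  samples <- c(paste0("wt_a", seq_len(n_wt)), paste0("mut_a", seq_len(n_mut)))
  groups <- rep(c("wt", "mut"), c(n_wt, n_mut))
  values <- matrix(NA_real_, n, length(samples),
                   dimnames = list(sprintf("probe_%05d", seq_len(n)), samples))
  for (j in seq_along(samples)) {
    shift <- if (groups[j] == "mut") global_shift else 0
    values[, j] <- pmin(pmax(truth$cpgs$baseline_pi + shift +
                               stats::rnorm(n, 0, noise_sd), 0), 1)
  }
  structure(list(values = values, probe_ids = rownames(values),
                 sample_ids = samples, group_labels = groups),
            class = "beta_matrix")
}

#' Generate and write a complete synthetic dataset
#'
#' Runs every generator off one master seed (sub-seeds derived by small
#' offsets) and writes the full input layout the pipeline consumes:
#' counts/<sample>.tsv, features/<name>.bed, tss.tsv, expression.tsv,
#' groups.tsv, beta.csv, beta_groups.tsv and truth.json.
#'
#' @param out_dir Output directory (created).
#' @param config List from \code{\link{sim_config}}.
#' @param seed Master integer seed.
#' @return Invisibly, a list with the truth object and all in-memory pieces.
#' @export
simulate_dataset <- function(out_dir, config = sim_config(), seed = 1L) {
  truth <- simulate_truth(config, seed = seed)
  meth <- simulate_meth_counts(truth, seed = seed + 1L)
  feats <- simulate_features(truth, seed = seed + 2L)
  expr <- simulate_expression(truth, seed = seed + 3L)
  beta <- simulate_beta_matrix(truth, seed = seed + 4L)

  dir.create(file.path(out_dir, "counts"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "features"), showWarnings = FALSE)
  for (s in names(meth$records)) {
    write_cytosine_counts(meth$records[[s]],
                          file.path(out_dir, "counts", paste0(s, ".tsv")))
  }
  for (f in names(feats)) {
    write_bed(feats[[f]], file.path(out_dir, "features", paste0(f, ".bed")))
  }
  utils::write.table(truth$genes[, c("gene_id", "chrom", "tss", "strand")],
                     file.path(out_dir, "tss.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_count_matrix(expr$counts, file.path(out_dir, "expression.tsv"))
  utils::write.table(data.frame(names(meth$design), unname(meth$design)),
                     file.path(out_dir, "groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_beta_matrix(beta, file.path(out_dir, "beta.csv"))
  utils::write.table(data.frame(beta$sample_ids, beta$group_labels),
                     file.path(out_dir, "beta_groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, config = truth$config,
         regions = truth$regions, genes = truth$genes,
         n_cpgs = nrow(truth$cpgs)),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(truth = truth, meth = meth, features = feats,
                 expression = expr, beta = beta))
}
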