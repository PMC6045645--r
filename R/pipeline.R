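.CONFIG_DEFAULTS <- list(
  counts_dir = NA_character_,   # required
  design = NA_character_,       # required
  out_dir = NA_character_,      # required
  features = NA_character_,     # optional: BED directory or BED4 file
  tss = NA_character_,          # optional: TSS table
  expression = NA_character_,   # optional: gene count matrix
  expr_design = NA_character_,  # defaults to design
  case_group = "mut",
  control_group = "wt",
  window_bp = 200,
  fdr_threshold = 0.01,
  min_delta = 0.1,
  df_mode = "full",
  max_gap_bp = 1000,
  min_cpgs = 3,
  max_dist_bp = 1000,
  seed = 1
)

#' Parse and validate a pipeline configuration file
#'
#' Plain-text \code{key = value} lines (\code{#} comments allowed). Required
#' keys: counts_dir, design, out_dir. Optional inputs: features, tss,
#' expression, expr_design. Parameters default to: window_bp 200,
#' fdr_threshold 0.01, min_delta 0.1, df_mode full, max_gap_bp 1000,
#' min_cpgs 3, max_dist_bp 1000, case_group mut, control_group wt, seed 1.
#' Unknown keys, missing required paths and out-of-range thresholds are
#' errors.
#'
#' @param path Path to the config file.
#' @return Validated config list.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- .CONFIG_DEFAULTS
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (!key %in% names(cfg)) stop("unknown config key: '", key, "'")
    cfg[[key]] <- if (is.numeric(.CONFIG_DEFAULTS[[key]])) {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) stop("config key '", key, "' needs a number, got '", val, "'")
      num
    } else {
      val
    }
  }
  for (key in c("counts_dir", "design", "out_dir")) {
    if (is.na(cfg[[key]])) stop("missing required config key: '", key, "'")
  }
  for (key in c("counts_dir", "design", "features", "tss", "expression",
                "expr_design")) {
    p <- cfg[[key]]
    if (!is.na(p) && !file.exists(p)) {
      stop("config key '", key, "' points to a missing path: ", p)
    }
  }
  if (is.na(cfg$expr_design)) cfg$expr_design <- cfg$design
  if (cfg$fdr_threshold <= 0 || cfg$fdr_threshold > 1) {
    stop("fdr_threshold out of range (0, 1]: ", cfg$fdr_threshold)
  }
  if (cfg$min_delta < 0 || cfg$min_delta > 1) {
    stop("min_delta out of range [0, 1]: ", cfg$min_delta)
  }
  if (cfg$window_bp < 0 || cfg$max_gap_bp < 0 || cfg$max_dist_bp < 0) {
    stop("window_bp, max_gap_bp and max_dist_bp must be >= 0")
  }
  if (cfg$min_cpgs < 1) stop("min_cpgs must be >= 1")
  if (!cfg$df_mode %in% c("full", "shared_dispersion")) {
    stop("df_mode must be 'full' or 'shared_dispersion'")
  }
  cfg
}

#' Run the full differential-methylation pipeline
#'
#' Chains every stage over on-disk inputs: read and strand-merge per-sample
#' cytosine counts, per-CpG beta-binomial testing with neighbor p-value
#' combination and BH FDR, DMR calling, TSS association, feature-set
#' enrichment, the simplified differential-expression stage, and the
#' promoter-methylation/expression join. Writes, under \code{out_dir}:
#' sites.tsv, dmrs.bed + dmrs.tsv, tss_associations.tsv, enrichment.tsv,
#' de.tsv, dmr_expression.tsv and manifest.json (config echo, seed and
#' per-output row counts; no timestamps, so reruns are byte-identical).
#' Stages whose inputs are not configured are skipped and recorded as such
#' in the manifest.
#'
#' @param config Validated config list from \code{\link{validate_config}},
#'   or a path to a config file.
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = config[order(names(config))], rows = list())
  log_lines <- character()
  say <- function(...) {
    msg <- paste0(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  design <- read_design(config$design)
  count_files <- sort(list.files(config$counts_dir, pattern = "\\.tsv$",
                                 full.names = TRUE))
  if (!length(count_files)) stop("no count files in ", config$counts_dir)
  merged <- lapply(count_files, function(f) merge_strands(read_cytosine_counts(f)))
  names(merged) <- tools::file_path_sans_ext(basename(count_files))
  say("diffmeth: ", length(merged), " samples")
  sites <- assemble_sites(merged, design)
  if (!any(sites$testable)) stop("no testable sites in input counts")
  results <- diffmeth_chain(sites, case = config$case_group,
                            control = config$control_group,
                            window_bp = config$window_bp,
                            fdr_threshold = config$fdr_threshold,
                            min_delta = config$min_delta,
                            df_mode = config$df_mode)
  write_site_table(results, sites, file.path(out, "sites.tsv"))
  dirsum <- direction_summary(results)
  manifest$rows$sites <- nrow(results)
  manifest$direction_summary <- dirsum
  say("diffmeth: ", nrow(results), " sites (", dirsum$n_hyper, " hyper, ",
      dirsum$n_hypo, " hypo)")

  dmrs <- call_dmrs(results, max_gap_bp = config$max_gap_bp,
                    min_cpgs = config$min_cpgs)
  write_dmrs(dmrs, file.path(out, "dmrs.bed"), file.path(out, "dmrs.tsv"))
  manifest$rows$dmrs <- nrow(dmrs)
  manifest$dmr_summary <- dmr_summary(dmrs)
  say("dmr: ", nrow(dmrs), " regions")

  assoc <- NULL; tss <- NULL
  if (!is.na(config$tss)) {
    tss <- read_tss(config$tss)
    assoc <- associate_tss(dmrs, tss, max_dist_bp = config$max_dist_bp)
    assoc_out <- cbind(dmr = if (nrow(assoc)) paste0("DMR_", assoc$dmr_row) else character(),
                       assoc)
    utils::write.table(assoc_out, file.path(out, "tss_associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$rows$tss_associations <- nrow(assoc)
    say("features: ", nrow(assoc), " DMR-TSS associations")
  }

  enrich <- NULL
  if (!is.na(config$features)) {
    feature_sets <- load_feature_sets(config$features)
    enrich <- enrichment_fractions(results, feature_sets)
    write_enrichment(enrich, file.path(out, "enrichment.tsv"))
    manifest$rows$enrichment <- nrow(enrich)
    say("features: enrichment over ", nrow(enrich), " sets")
  }

  de <- NULL
  if (!is.na(config$expression)) {
    cm <- read_count_matrix(config$expression, config$expr_design)
    de <- nb_test(cm$counts, cm$group_labels, case = config$case_group,
                  control = config$control_group)
    utils::write.table(format(de, digits = 15, trim = TRUE),
                       file.path(out, "de.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$rows$de <- nrow(de)
    say("expression: ", nrow(de), " genes tested")
  }

  joined <- NULL
  if (!is.null(assoc) && !is.null(de)) {
    joined <- join_dmr_expression(assoc, dmrs, de)
    utils::write.table(format(joined, digits = 15, trim = TRUE),
                       file.path(out, "dmr_expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$rows$dmr_expression <- nrow(joined)
    manifest$spearman_rho <- attr(joined, "spearman_rho")
    say("integration: ", nrow(joined), " DMR-gene pairs, Spearman rho = ",
        round(attr(joined, "spearman_rho"), 3))
  }

  manifest$package_version <- as.character(utils::packageVersion("betameth"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  writeLines(log_lines, file.path(out, "run.log"))
  invisible(list(sites = sites, results = results, dmrs = dmrs,
                 associations = assoc, enrichment = enrich, de = de,
                 joined = joined, manifest = manifest))
}
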