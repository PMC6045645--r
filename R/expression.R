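#' Median-of-ratios size factors
#'
#' The reference expression of each gene is its geometric mean across
#' samples, computed over genes with all-positive counts; a sample's size
#' factor is the median across those genes of count/reference.
#'
#' @param counts Integer matrix, genes x samples.
#' @return Positive numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  all_pos <- rowSums(counts <= 0) == 0
  if (!any(all_pos)) stop("no gene with all-positive counts")
  cc <- counts[all_pos, , drop = FALSE]
  log_ref <- rowMeans(log(cc))
  sf <- apply(cc, 2L, function(col) exp(stats::median(log(col) - log_ref)))
  stats::setNames(sf, colnames(counts))
}

#' Per-gene negative-binomial differential expression test
#'
#' A deliberately simple two-group test on size-factor-normalized counts:
#' the per-gene NB dispersion is estimated by method of moments from the
#' within-group variability of normalized counts (pooled across groups,
#' floored at 1e-8) and group means are compared with a Wald test on the
#' log scale (delta-method variance, pseudocount 0.5 keeping zero-mean
#' groups finite). log2fc is log2 of the (pseudocounted) case/control
#' normalized-mean ratio.
#'
#' @param counts Integer matrix, genes x samples.
#' @param groups Per-sample group labels (two levels).
#' @param sf Size factors; computed with \code{\link{size_factors}} when
#'   omitted.
#' @param case,control Group labels; defaults: sorted labels, second as
#'   case.
#' @return data.frame with gene_id, base_mean, log2fc, p, fdr.
#' @export
nb_test <- function(counts, groups, sf = NULL, case = NULL, control = NULL) {
  levels <- sort(unique(groups))
  if (length(levels) != 2L) stop("need exactly two groups")
  if (is.null(case)) case <- levels[2L]
  if (is.null(control)) control <- levels[1L]
  if (length(groups) != ncol(counts)) stop("groups/sample mismatch")
  if (length(groups) < 2L) stop("need at least two samples")
  if (is.null(sf)) sf <- size_factors(counts)
  q <- sweep(counts, 2L, sf, "/")
  qc <- q[, groups == case, drop = FALSE]
  qw <- q[, groups == control, drop = FALSE]
  nc <- ncol(qc); nw <- ncol(qw)
  mc <- rowMeans(qc); mw <- rowMeans(qw)
  base_mean <- rowMeans(q)

  # pooled within-group method-of-moments NB dispersion:
  # Var(q) = mu + disp * mu^2  =>  disp = (s2 - mu) / mu^2
  ssq <- function(m) if (ncol(m) > 1L) rowSums((m - rowMeans(m))^2) else rep(0, nrow(m))
  df <- max(nc - 1L, 0L) + max(nw - 1L, 0L)
  s2 <- if (df > 0) (ssq(qc) + ssq(qw)) / df else rep(0, nrow(q))
  mu_pool <- (nc * mc + nw * mw) / (nc + nw)
  disp <- pmax((s2 - mu_pool) / pmax(mu_pool, 1e-8)^2, 1e-8)

  eps <- 0.5
  log2fc <- log2((mc + eps) / (mw + eps))
  # delta method: Var(log mean_g) ~= Var(mean_g) / mean_g^2 with
  # Var(q_s) = mu + disp mu^2 per sample
  v_log <- function(m, n) (m + disp * m^2) / n / (m + eps)^2
  wald <- (log(mc + eps) - log(mw + eps)) /
    sqrt(v_log(mc, nc) + v_log(mw, nw))
  p <- 2 * stats::pnorm(-abs(wald))
  p[mc == 0 & mw == 0] <- 1
  log2fc[mc == 0 & mw == 0] <- 0
  data.frame(gene_id = rownames(counts), base_mean = base_mean,
             log2fc = log2fc, p = p, fdr = adjust_bh(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Join promoter DMR methylation changes with expression changes
#'
#' Inner join of TSS associations (gene per DMR) with the differential
#' expression table; a gene near several DMRs contributes one row per DMR.
#' The Spearman correlation between the DMR methylation change and the
#' expression log2 fold-change is attached as attribute
#' \code{spearman_rho}.
#'
#' @param associations data.frame from \code{\link{associate_tss}}.
#' @param dmrs The DMR table the associations index into.
#' @param de data.frame from \code{\link{nb_test}}.
#' @return data.frame with gene_id, dmr_mean_delta, log2fc, fdr_meth
#'   (the DMR's best member FDR), fdr_expr; attribute spearman_rho.
#' @export
join_dmr_expression <- function(associations, dmrs, de) {
  idx <- match(associations$gene_id, de$gene_id)
  keep <- !is.na(idx)
  a <- associations[keep, , drop = FALSE]
  idx <- idx[keep]
  out <- data.frame(gene_id = a$gene_id,
                    dmr_mean_delta = dmrs$mean_delta[a$dmr_row],
                    log2fc = de$log2fc[idx],
                    fdr_meth = dmrs$best_fdr[a$dmr_row],
                    fdr_expr = de$fdr[idx],
                    stringsAsFactors = FALSE, row.names = NULL)
  rho <- if (nrow(out) >= 3L) {
    suppressWarnings(stats::cor(out$dmr_mean_delta, out$log2fc,
                                method = "spearman"))
  } else {
    NA_real_
  }
  attr(out, "spearman_rho") <- rho
  out
}

#' Join TF binding-site enrichment with the TF gene's expression change
#'
#' Per feature set, attaches the expression log2 fold-change and FDR of the
#' transcription factor gene the set belongs to; features without a mapping
#' keep missing expression fields.
#'
#' @param enrichment data.frame from \code{\link{enrichment_fractions}}.
#' @param de data.frame from \code{\link{nb_test}}.
#' @param tf_map Named character vector: feature name -> gene_id.
#' @return The enrichment table with log2fc and fdr_expr columns added.
#' @export
tf_site_expression_table <- function(enrichment, de, tf_map) {
  gene <- unname(tf_map[enrichment$feature_name])
  idx <- match(gene, de$gene_id)
  enrichment$log2fc <- de$log2fc[idx]
  enrichment$fdr_expr <- de$fdr[idx]
  enrichment
}
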