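#' Associate DMRs with nearby transcription start sites
#'
#' A region is associated with a gene when the gap between the region and
#' the gene's TSS is at most \code{max_dist_bp}: the gap is 0 when the TSS
#' lies inside [start, end), \code{start - tss} left of the region and
#' \code{tss - end} right of it (the count of bases separating the TSS from
#' the region). Associations are many-to-many.
#'
#' @param dmrs data.frame with chrom, start, end (plus any extra columns,
#'   carried through by row index in the \code{dmr_row} column).
#' @param tss data.frame with gene_id, chrom, tss.
#' @param max_dist_bp Maximum gap in bp (default 1000).
#' @return data.frame with dmr_row (row index into \code{dmrs}), gene_id,
#'   distance.
#' @export
associate_tss <- function(dmrs, tss, max_dist_bp = 1000) {
  out <- list()
  for (i in seq_len(nrow(dmrs))) {
    same <- tss[tss$chrom == dmrs$chrom[i], , drop = FALSE]
    if (!nrow(same)) next
    gap <- ifelse(same$tss < dmrs$start[i], dmrs$start[i] - same$tss,
                  ifelse(same$tss >= dmrs$end[i], same$tss - dmrs$end[i], 0L))
    hit <- gap <= max_dist_bp
    if (any(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        dmr_row = i, gene_id = same$gene_id[hit],
        distance = as.integer(gap[hit]), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(dmr_row = integer(), gene_id = character(),
                      distance = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Test sorted positions for membership in an interval set
#'
#' Sorted-sweep membership: intervals are merged into disjoint runs, then
#' each position is located with a single binary search. Positions are on
#' one chromosome; intervals are 0-based half-open, so a position equal to
#' an interval end is outside.
#'
#' @param positions Sorted integer vector (one chromosome).
#' @param intervals data.frame with start, end columns (same chromosome).
#' @return Logical vector: TRUE where the position falls in any interval.
#' @export
interval_membership <- function(positions, intervals) {
  if (is.unsorted(positions)) stop("positions must be sorted")
  n <- length(positions)
  if (!nrow(intervals)) return(rep(FALSE, n))
  o <- order(intervals$start, intervals$end, method = "radix")
  start <- intervals$start[o]; end <- intervals$end[o]
  # merge overlapping/adjacent intervals into disjoint runs
  ms <- me <- numeric(length(start)); j <- 0L
  cs <- start[1L]; ce <- end[1L]
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= ce) {
      ce <- max(ce, end[i])
    } else {
      j <- j + 1L; ms[j] <- cs; me[j] <- ce
      cs <- start[i]; ce <- end[i]
    }
  }
  j <- j + 1L; ms[j] <- cs; me[j] <- ce
  ms <- ms[seq_len(j)]; me <- me[seq_len(j)]
  idx <- findInterval(positions, ms)
  idx > 0L & positions < me[pmax(idx, 1L)]
}

#' Fractions of hyper-/hypomethylated CpGs within feature interval sets
#'
#' For each named interval set, counts the profiled CpGs (sites with a test
#' result) lying within any interval of the set, and the hyper-/hypo-labeled
#' CpGs among them; membership, not multiplicity (a CpG in two overlapping
#' intervals of one set counts once). Fractions are relative to the
#' profiled CpGs of the set, mirroring how methylation changes are
#' attributed to chromatin states or TF binding-site sets.
#'
#' @param results Labeled site results (chrom, pos, p_raw, label).
#' @param feature_sets Named list of interval data.frames (chrom, start,
#'   end).
#' @return data.frame with feature_name, n_profiled, n_hyper, n_hypo,
#'   frac_hyper, frac_hypo (fractions NA when n_profiled = 0).
#' @export
enrichment_fractions <- function(results, feature_sets) {
  profiled <- results[!is.na(results$p_raw), , drop = FALSE]
  profiled <- profiled[order(profiled$chrom, profiled$pos, method = "radix"), , drop = FALSE]
  rows <- lapply(names(feature_sets), function(fname) {
    iv <- feature_sets[[fname]]
    member <- rep(FALSE, nrow(profiled))
    for (chr in unique(profiled$chrom)) {
      in_chr <- profiled$chrom == chr
      member[in_chr] <- interval_membership(
        profiled$pos[in_chr], iv[iv$chrom == chr, , drop = FALSE])
    }
    n_prof <- sum(member)
    n_hyper <- sum(member & profiled$label == "hyper")
    n_hypo <- sum(member & profiled$label == "hypo")
    data.frame(feature_name = fname, n_profiled = n_prof,
               n_hyper = n_hyper, n_hypo = n_hypo,
               frac_hyper = if (n_prof) n_hyper / n_prof else NA_real_,
               frac_hypo = if (n_prof) n_hypo / n_prof else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Load feature sets from a directory of BED files or one BED4 file
#'
#' A directory yields one set per *.bed file (set name = file stem); a
#' single BED4 file groups intervals by the name column.
#'
#' @param path Directory or BED4 file path.
#' @return Named list of interval data.frames.
#' @export
load_feature_sets <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.bed$", full.names = TRUE))
    if (!length(files)) stop("no .bed files in ", path)
    sets <- lapply(files, read_bed)
    names(sets) <- tools::file_path_sans_ext(basename(files))
    sets
  } else {
    bed <- read_bed(path)
    if (all(is.na(bed$name))) stop("single-file feature sets need a name column")
    split(bed[, c("chrom", "start", "end")], bed$name)
  }
}

.BASES <- c("A", "C", "G", "T")

#' Scan a nucleotide sequence with a position weight matrix
#'
#' Scores every window of motif length on both strands: the forward score
#' sums the log-odds weight of the base at each motif position; the reverse
#' score applies the motif to the window's reverse complement. Windows
#' containing N are skipped. Hits are windows scoring at least
#' \code{score_threshold}, reported by the window's 0-based offset on the
#' forward strand.
#'
#' @param sequence Character scalar over A,C,G,T,N.
#' @param pwm \code{pwm} object (see \code{\link{read_pwm}}).
#' @param score_threshold Minimum log-odds score for a hit.
#' @return data.frame with offset (0-based), strand, score, ordered by
#'   offset then strand.
#' @export
pwm_scan <- function(sequence, pwm, score_threshold) {
  mat <- pwm$matrix
  L <- nrow(mat)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- !(chars %in% c(.BASES, "N"))
  if (any(bad)) stop("sequence contains non-ACGTN character: ", chars[which(bad)[1L]])
  n <- length(chars)
  empty <- data.frame(offset = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (n < L) return(empty)
  code <- match(chars, .BASES)  # NA for N
  n_win <- n - L + 1L
  # reverse-complement motif: scanning the forward sequence with it equals
  # scoring each window's reverse complement with the original motif
  rc_mat <- mat[rev(seq_len(L)), c("T", "G", "C", "A"), drop = FALSE]
  fwd <- rev_ <- rep(0, n_win)
  valid <- rep(TRUE, n_win)
  for (j in seq_len(L)) {
    cj <- code[j:(j + n_win - 1L)]
    valid <- valid & !is.na(cj)
    cj[is.na(cj)] <- 1L
    fwd <- fwd + mat[j, ][cj]
    rev_ <- rev_ + rc_mat[j, ][cj]
  }
  hits_f <- which(valid & fwd >= score_threshold)
  hits_r <- which(valid & rev_ >= score_threshold)
  out <- rbind(
    data.frame(offset = hits_f - 1L, strand = rep("+", length(hits_f)),
               score = fwd[hits_f], stringsAsFactors = FALSE),
    data.frame(offset = hits_r - 1L, strand = rep("-", length(hits_r)),
               score = rev_[hits_r], stringsAsFactors = FALSE))
  out <- out[order(out$offset, out$strand, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare beta-value groups (array-style methylation)
#'
#' Per probe, the difference of group means over non-missing entries (case
#' minus control); probes missing an entire group are excluded. The global
#' shift is the average per-probe difference, tested against zero with a
#' two-sided Wilcoxon signed-rank test (exact for 25 or fewer probes,
#' normal approximation above). This is the whole-array group comparison
#' used for 450K-style data.
#'
#' @param beta \code{beta_matrix} object (see \code{\link{read_beta_matrix}}).
#' @param case,control Group labels; defaults to the two labels sorted,
#'   second as case.
#' @return List with mean_delta, p_value, n_probes_used.
#' @export
compare_beta_groups <- function(beta, case = NULL, control = NULL) {
  groups <- beta$group_labels
  levels <- sort(unique(groups))
  if (length(levels) != 2L) stop("beta matrix must have exactly two groups")
  if (is.null(case)) case <- levels[2L]
  if (is.null(control)) control <- levels[1L]
  vc <- beta$values[, groups == case, drop = FALSE]
  vw <- beta$values[, groups == control, drop = FALSE]
  if (!ncol(vc) || !ncol(vw)) stop("each group needs at least one sample")
  mc <- rowMeans(vc, na.rm = TRUE)
  mw <- rowMeans(vw, na.rm = TRUE)
  diffs <- mc - mw
  use <- is.finite(diffs)
  diffs <- diffs[use]
  n <- length(diffs)
  if (!n) stop("no probe observed in both groups")
  p <- if (all(diffs == 0)) {
    1
  } else {
    suppressWarnings(
      stats::wilcox.test(diffs, mu = 0, alternative = "two.sided",
                         exact = n <= 25, correct = TRUE)$p.value)
  }
  list(mean_delta = mean(diffs), p_value = p, n_probes_used = n)
}

#' Write the enrichment table
#'
#' @param rows data.frame from \code{\link{enrichment_fractions}}.
#' @param path Output TSV path.
#' @export
write_enrichment <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
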