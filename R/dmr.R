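#' Call differentially methylated regions from labeled CpG sites
#'
#' Consecutive significant CpGs with the same direction label, on the same
#' chromosome and with inter-site distance at most \code{max_gap_bp}, are
#' merged into one region. Non-significant sites in between neither break a
#' run nor count toward its size; a significant site of the opposite
#' direction does break it (regions are directionally coherent). Runs with
#' fewer than \code{min_cpgs} members are discarded. A region spans from
#' the first member CpG to the last member CpG + 2, covering the final
#' dinucleotide, half-open.
#'
#' @param results Labeled site results sorted by (chrom, pos), with columns
#'   chrom, pos, label, delta, fdr.
#' @param max_gap_bp Maximum distance between consecutive member CpGs
#'   (default 1000).
#' @param min_cpgs Minimum member CpGs per region (default 3).
#' @return data.frame with columns chrom, start, end, n_cpgs, direction,
#'   mean_delta, best_fdr, sorted by (chrom, start).
#' @export
call_dmrs <- function(results, max_gap_bp = 1000, min_cpgs = 3) {
  check_sorted(results$chrom, results$pos)
  sig <- results[results$label %in% c("hyper", "hypo"), , drop = FALSE]
  out <- list()
  if (nrow(sig)) {
    # run id increments when chromosome, direction, or gap rule breaks
    new_run <- c(TRUE,
                 sig$chrom[-1L] != sig$chrom[-nrow(sig)] |
                   sig$label[-1L] != sig$label[-nrow(sig)] |
                   (sig$pos[-1L] - sig$pos[-nrow(sig)]) > max_gap_bp)
    run_id <- cumsum(new_run)
    for (id in unique(run_id)) {
      run <- sig[run_id == id, , drop = FALSE]
      if (nrow(run) < min_cpgs) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = run$chrom[1L],
        start = run$pos[1L],
        end = run$pos[nrow(run)] + 2L,
        n_cpgs = nrow(run),
        direction = run$label[1L],
        mean_delta = mean(run$delta),
        best_fdr = min(run$fdr),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpgs = integer(),
                      direction = character(), mean_delta = numeric(),
                      best_fdr = numeric(), stringsAsFactors = FALSE))
  }
  dmrs <- do.call(rbind, out)
  dmrs <- dmrs[order(dmrs$chrom, dmrs$start, method = "radix"), , drop = FALSE]
  rownames(dmrs) <- NULL
  dmrs
}

#' Count DMRs by direction
#'
#' @param dmrs data.frame from \code{\link{call_dmrs}}.
#' @return List with n_total, n_hyper, n_hypo.
#' @export
dmr_summary <- function(dmrs) {
  n_hyper <- sum(dmrs$direction == "hyper")
  n_hypo <- sum(dmrs$direction == "hypo")
  list(n_total = n_hyper + n_hypo, n_hyper = n_hyper, n_hypo = n_hypo)
}

#' Write DMRs as BED6 plus a detail table
#'
#' The BED score is round(-10 log10 best_fdr) capped at 1000; the side TSV
#' carries n_cpgs, direction and mean_delta per region.
#'
#' @param dmrs data.frame from \code{\link{call_dmrs}}.
#' @param bed_path,tsv_path Output paths.
#' @export
write_dmrs <- function(dmrs, bed_path, tsv_path) {
  n <- nrow(dmrs)
  name <- if (n) paste0("DMR_", seq_len(n)) else character()
  score <- if (n) pmin(round(-10 * log10(pmax(dmrs$best_fdr, 1e-100))), 1000L) else integer()
  bed <- if (n) {
    paste(dmrs$chrom, dmrs$start, dmrs$end, name, score, ".", sep = "\t")
  } else {
    character()
  }
  writeLines(bed, bed_path)
  tsv <- cbind(name = name, dmrs)
  con <- file(tsv_path, "w")
  on.exit(close(con))
  writeLines("# DMR details: coordinates 0-based half-open", con)
  utils::write.table(format(tsv, digits = 15, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
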