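# Independent brute-force oracles and random-fixture generators.
# Every oracle is a direct transcription of the operation's definition,
# deliberately O(n^2) or per-element, sharing no code with the package.

random_cytosine_records <- function(n, n_chrom = 2, span = 2000,
                                    paired_frac = 0.6) {
  chrom <- paste0("chr", sample.int(n_chrom, n, replace = TRUE))
  fwd_pos <- sample.int(span, n) * 2L
  strand <- rep("+", n)
  recs <- data.frame(chrom = chrom, pos = fwd_pos, strand = strand,
                     context = "CpG",
                     meth_reads = 0L, total_reads = 0L,
                     stringsAsFactors = FALSE)
  # add reverse-strand partners for a fraction, plus some reverse-only
  partner <- recs[runif(n) < paired_frac, , drop = FALSE]
  partner$pos <- partner$pos + 1L
  partner$strand <- "-"
  rev_only <- data.frame(chrom = paste0("chr", sample.int(n_chrom, 5, replace = TRUE)),
                         pos = sample.int(span, 5) * 2L + 1L,
                         strand = "-", context = "CpG",
                         meth_reads = 0L, total_reads = 0L,
                         stringsAsFactors = FALSE)
  out <- rbind(recs, partner, rev_only)
  out <- out[!duplicated(out[, c("chrom", "pos", "strand")]), , drop = FALSE]
  out$total_reads <- sample(1:50, nrow(out), replace = TRUE)
  out$meth_reads <- vapply(out$total_reads,
                           function(N) sample.int(N + 1L, 1L) - 1L, 1L)
  rownames(out) <- NULL
  out
}

# exhaustive pairing over all (record, record) position pairs
oracle_merge_strands <- function(records) {
  key_pos <- ifelse(records$strand == "+", records$pos, records$pos - 1L)
  keys <- unique(data.frame(chrom = records$chrom, pos = key_pos,
                            stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- logical(nrow(records))
    for (j in seq_len(nrow(records))) {
      sel[j] <- records$chrom[j] == keys$chrom[i] &&
        ((records$strand[j] == "+" && records$pos[j] == keys$pos[i]) ||
           (records$strand[j] == "-" && records$pos[j] == keys$pos[i] + 1L))
    }
    data.frame(chrom = keys$chrom[i], pos = keys$pos[i],
               meth = sum(records$meth_reads[sel]),
               total = sum(records$total_reads[sel]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# all-pairs window search Stouffer combination
oracle_combine_neighbors <- function(results, window_bp) {
  p_comb <- rep(NA_real_, nrow(results))
  for (i in seq_len(nrow(results))) {
    if (is.na(results$p_raw[i])) next
    zs <- c()
    for (j in seq_len(nrow(results))) {
      if (is.na(results$p_raw[j])) next
      if (results$chrom[j] == results$chrom[i] &&
          abs(results$pos[j] - results$pos[i]) <= window_bp) {
        pj <- min(max(results$p_raw[j], 1e-15), 1 - 1e-15)
        zs <- c(zs, qnorm(pj, lower.tail = FALSE))
      }
    }
    p_comb[i] <- pnorm(sum(zs) / sqrt(length(zs)), lower.tail = FALSE)
  }
  p_comb
}

# direct BH step-up formula: min over j >= i of m * p_(j) / j, clipped at 1
oracle_bh <- function(p) {
  ok <- which(!is.na(p))
  m <- length(ok)
  o <- order(p[ok])
  sorted <- p[ok][o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  }
  out <- rep(NA_real_, length(p))
  out[ok[o]] <- adj
  out
}

# per-position linear scan over every interval
oracle_membership <- function(positions, intervals) {
  vapply(positions, function(p) {
    any(p >= intervals$start & p < intervals$end)
  }, TRUE)
}

# run enumeration: try every (start, end) index pair of significant sites
oracle_call_dmrs <- function(results, max_gap_bp, min_cpgs) {
  sig_idx <- which(results$label %in% c("hyper", "hypo"))
  runs <- list()
  for (a in seq_along(sig_idx)) {
    for (b in a:length(sig_idx)) {
      idx <- sig_idx[a:b]
      if (length(idx) < min_cpgs) next
      sub <- results[idx, , drop = FALSE]
      if (length(unique(sub$chrom)) != 1L) next
      if (length(unique(sub$label)) != 1L) next
      if (length(idx) > 1L && any(diff(sub$pos) > max_gap_bp)) next
      # maximal: not extendable left or right
      left_ok <- a == 1L ||
        results$chrom[sig_idx[a - 1L]] != sub$chrom[1L] ||
        results$label[sig_idx[a - 1L]] != sub$label[1L] ||
        sub$pos[1L] - results$pos[sig_idx[a - 1L]] > max_gap_bp
      right_ok <- b == length(sig_idx) ||
        results$chrom[sig_idx[b + 1L]] != sub$chrom[1L] ||
        results$label[sig_idx[b + 1L]] != sub$label[1L] ||
        results$pos[sig_idx[b + 1L]] - sub$pos[nrow(sub)] > max_gap_bp
      if (!left_ok || !right_ok) next
      runs[[length(runs) + 1L]] <- data.frame(
        chrom = sub$chrom[1L], start = sub$pos[1L],
        end = sub$pos[nrow(sub)] + 2L, n_cpgs = nrow(sub),
        direction = sub$label[1L], mean_delta = mean(sub$delta),
        best_fdr = min(sub$fdr), stringsAsFactors = FALSE)
    }
  }
  if (!length(runs)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpgs = integer(),
                      direction = character(), mean_delta = numeric(),
                      best_fdr = numeric(), stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, runs))
  out <- out[order(out$chrom, out$start, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-window rescoring with string reverse complement
oracle_pwm_scan <- function(sequence, pwm, threshold) {
  mat <- pwm$matrix
  L <- nrow(mat)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  revcomp <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(unname(comp[x])), collapse = "")
  }
  score_window <- function(win) {
    sum(vapply(seq_len(L), function(j) mat[j, win[j]], 1.0))
  }
  rows <- list()
  for (off in 0:(length(chars) - L)) {
    win <- chars[(off + 1):(off + L)]
    if (any(win == "N")) next
    sf <- score_window(win)
    if (sf >= threshold) {
      rows[[length(rows) + 1L]] <- data.frame(offset = off, strand = "+",
                                              score = sf, stringsAsFactors = FALSE)
    }
    sr <- score_window(strsplit(revcomp(win), "")[[1L]])
    if (sr >= threshold) {
      rows[[length(rows) + 1L]] <- data.frame(offset = off, strand = "-",
                                              score = sr, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$offset, out$strand, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# all-pairs DMR-to-TSS distance scan
oracle_associate_tss <- function(dmrs, tss, max_dist_bp) {
  rows <- list()
  for (i in seq_len(nrow(dmrs))) {
    for (j in seq_len(nrow(tss))) {
      if (dmrs$chrom[i] != tss$chrom[j]) next
      t <- tss$tss[j]
      gap <- if (t >= dmrs$start[i] && t < dmrs$end[i]) {
        0L
      } else if (t < dmrs$start[i]) {
        dmrs$start[i] - t
      } else {
        t - dmrs$end[i]
      }
      if (gap <= max_dist_bp) {
        rows[[length(rows) + 1L]] <- data.frame(
          dmr_row = i, gene_id = tss$gene_id[j], distance = as.integer(gap),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(dmr_row = integer(), gene_id = character(),
                      distance = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

random_labeled_sites <- function(n, span = 20000) {
  pos <- sort(sample.int(span, n))
  label <- sample(c("hyper", "hypo", "ns"), n, replace = TRUE,
                  prob = c(0.25, 0.25, 0.5))
  delta <- ifelse(label == "hyper", runif(n, 0.1, 0.6),
                  ifelse(label == "hypo", runif(n, -0.6, -0.1),
                         runif(n, -0.09, 0.09)))
  data.frame(chrom = "chrT", pos = pos, delta = delta,
             fdr = runif(n), label = label, stringsAsFactors = FALSE)
}

random_pwm <- function(L) {
  mat <- matrix(rnorm(4 * L), L, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  structure(list(name = "random", matrix = mat), class = "pwm")
}
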