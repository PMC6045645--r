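#' Merge strand-specific CpG counts into per-dinucleotide counts
#'
#' RRBS callers report the two cytosines of a CpG dinucleotide separately:
#' the forward-strand C at position p and the reverse-strand C at p+1 (the
#' paired cytosine of the G). Counts are summed per dinucleotide, keyed at
#' the forward-C position; this discards apparent strand asymmetry that
#' would arise from a mutated CpG. Unpaired strands pass through with their
#' own counts (a reverse-only cytosine at q is keyed at q-1).
#'
#' @param records data.frame of strand-specific CpG-context cytosine counts
#'   for one sample (columns chrom, pos, strand, meth_reads, total_reads).
#' @return data.frame with columns chrom, pos, meth, total, sorted by
#'   (chrom, pos).
#' @export
merge_strands <- function(records) {
  if (!nrow(records)) {
    return(data.frame(chrom = character(), pos = integer(),
                      meth = integer(), total = integer(),
                      stringsAsFactors = FALSE))
  }
  dup <- duplicated(records[, c("chrom", "pos", "strand")])
  if (any(dup)) {
    d <- records[which(dup)[1L], ]
    stop("duplicate cytosine record at ", d$chrom, ":", d$pos, " strand ",
         d$strand)
  }
  key_pos <- ifelse(records$strand == "+", records$pos, records$pos - 1L)
  key <- paste(records$chrom, key_pos, sep = "\r")
  meth <- rowsum(records$meth_reads, key, reorder = FALSE)
  total <- rowsum(records$total_reads, key, reorder = FALSE)
  uk <- rownames(meth)
  split_at <- regexpr("\r", uk, fixed = TRUE)
  chrom <- substr(uk, 1L, split_at - 1L)
  pos <- as.integer(substring(uk, split_at + 1L))
  out <- data.frame(chrom = chrom, pos = pos, meth = as.integer(meth[, 1L]),
                    total = as.integer(total[, 1L]), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble strand-merged per-sample counts into a testable site set
#'
#' Builds the unit of differential testing: one row per CpG position
#' observed in at least one sample, with per-sample methylated (k) and total
#' (N) count matrices. Samples not covering a site get k = N = 0. A site is
#' testable when each of the two groups has at least one covered sample.
#'
#' @param merged Named list (one element per sample) of data.frames as
#'   returned by \code{\link{merge_strands}}.
#' @param design Named character vector mapping sample id to group label;
#'   exactly two distinct labels.
#' @return Object of class \code{meth_sites}: list with chrom, pos
#'   (per-site vectors sorted by chrom then pos), meth and total (integer
#'   matrices sites x samples), samples, groups (per-sample labels), and
#'   testable (logical per site).
#' @export
assemble_sites <- function(merged, design) {
  samples <- names(merged)
  unknown <- setdiff(samples, names(design))
  if (length(unknown)) {
    stop("design lacks samples: ", paste(unknown, collapse = ", "))
  }
  groups <- unname(design[samples])
  if (length(unique(groups)) != 2L) {
    stop("design must define exactly two groups, got: ",
         paste(unique(groups), collapse = ", "))
  }
  keys <- unique(do.call(rbind, lapply(merged, function(m) m[, c("chrom", "pos")])))
  keys <- keys[order(keys$chrom, keys$pos, method = "radix"), , drop = FALSE]
  key_str <- paste(keys$chrom, keys$pos, sep = "\r")
  n_sites <- nrow(keys)
  n_samp <- length(samples)
  meth <- matrix(0L, n_sites, n_samp, dimnames = list(NULL, samples))
  total <- matrix(0L, n_sites, n_samp, dimnames = list(NULL, samples))
  for (s in samples) {
    m <- merged[[s]]
    idx <- match(paste(m$chrom, m$pos, sep = "\r"), key_str)
    meth[idx, s] <- m$meth
    total[idx, s] <- m$total
  }
  gl <- sort(unique(groups))
  covered1 <- rowSums(total[, groups == gl[1L], drop = FALSE] > 0L) > 0L
  covered2 <- rowSums(total[, groups == gl[2L], drop = FALSE] > 0L) > 0L
  structure(list(chrom = keys$chrom, pos = keys$pos, meth = meth,
                 total = total, samples = samples, groups = groups,
                 testable = covered1 & covered2),
            class = "meth_sites")
}

#' Beta-binomial log pmf
#'
#' Log density of k methylated among N reads when the per-replicate
#' methylation probability p is Beta(alpha, beta) distributed:
#' log C(N,k) + log B(k+alpha, N-k+beta) - log B(alpha, beta).
#' An unobserved site (N = 0) contributes 0.
#'
#' @param k,N Non-negative integer vectors, 0 <= k <= N.
#' @param alpha,beta_ Positive Beta shape parameters.
#' @return Numeric vector of log probabilities (<= 0).
#' @export
betabinom_loglik <- function(k, N, alpha, beta_) {
  if (any(alpha <= 0) || any(beta_ <= 0)) stop("alpha and beta_ must be > 0")
  if (any(k < 0) || any(k > N)) stop("need 0 <= k <= N")
  ll <- lchoose(N, k) + lbeta(k + alpha, N - k + beta_) - lbeta(alpha, beta_)
  ll[N == 0] <- 0
  ll
}

# Bounds of the (mu, phi) parameterization: mu = alpha/(alpha+beta) is the
# mean methylation level, phi = alpha+beta the precision (low phi = high
# between-replicate variance).
.MU_MIN <- 1e-6
# The wide phi box keeps degenerate data identifiable while letting the
# likelihood express strong between-replicate variance. A consequence of
# the diffuse floor: a pooled null can partially absorb even complete group
# separation as U-shaped replicate noise, so single-CpG p-values are
# deliberately modest and regional evidence (neighbor combination) carries
# the discovery load.
.PHI_MIN <- 1e-2
.PHI_MAX <- 1e6

#' Fit a beta-binomial distribution by maximum likelihood
#'
#' Maximizes the summed \code{\link{betabinom_loglik}} over samples in the
#' unconstrained (logit mu, log phi) space with analytic gradients,
#' starting from method-of-moments estimates. mu is bounded away from 0/1
#' and phi capped so boundary data (e.g. all k = 0) stay identifiable.
#'
#' @param k,N Per-sample methylated and total counts; at least one N > 0.
#' @return List with alpha, beta_, mu, phi, loglik, converged.
#' @export
fit_betabinom <- function(k, N) {
  use <- N > 0
  if (!any(use)) stop("not fittable: all samples have zero coverage")
  k <- k[use]; N <- N[use]

  negll <- function(par) {
    mu <- stats::plogis(par[1L]); phi <- exp(par[2L])
    -sum(betabinom_loglik(k, N, mu * phi, (1 - mu) * phi))
  }
  neggr <- function(par) {
    mu <- stats::plogis(par[1L]); phi <- exp(par[2L])
    a <- mu * phi; b <- (1 - mu) * phi
    dA <- sum(digamma(k + a)) - length(k) * digamma(a)
    dB <- sum(digamma(N - k + b)) - length(k) * digamma(b)
    dC <- sum(digamma(N + a + b)) - length(k) * digamma(a + b)
    dl_da <- dA - dC
    dl_db <- dB - dC
    g1 <- (dl_da - dl_db) * phi * mu * (1 - mu)
    g2 <- dl_da * a + dl_db * b
    -c(g1, g2)
  }

  mu0 <- min(max(sum(k) / sum(N), .MU_MIN), 1 - .MU_MIN)
  phi0 <- 50
  if (length(k) >= 2L) {
    # moment-match the variance of the per-sample rates to seed phi
    rate_var <- stats::var(k / N)
    vmin <- mu0 * (1 - mu0) * mean(1 / N)
    vmax <- mu0 * (1 - mu0)
    if (is.finite(rate_var) && rate_var > vmin && vmax > vmin) {
      rho <- (rate_var - vmin) / (vmax - vmin)
      phi0 <- min(max(1 / rho - 1, .PHI_MIN), .PHI_MAX)
    } else {
      phi0 <- .PHI_MAX
    }
  }
  start <- c(stats::qlogis(mu0), log(phi0))
  lower <- c(stats::qlogis(.MU_MIN), log(.PHI_MIN))
  upper <- c(stats::qlogis(1 - .MU_MIN), log(.PHI_MAX))
  opt <- stats::optim(start, negll, neggr, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(factr = 1e5))
  if (opt$convergence != 0L) {
    # the profile in phi can be nearly flat, which aborts the line search;
    # polish with a derivative-free restart from the better point
    clamped <- function(par) pmin(pmax(par, lower), upper)
    nm <- stats::optim(clamped(opt$par), function(par) negll(clamped(par)),
                       method = "Nelder-Mead",
                       control = list(maxit = 500, reltol = 1e-10))
    if (nm$value <= opt$value) {
      opt <- list(par = clamped(nm$par), value = nm$value,
                  convergence = nm$convergence)
    } else {
      opt$convergence <- nm$convergence
    }
  }
  mu <- stats::plogis(opt$par[1L]); phi <- exp(opt$par[2L])
  list(alpha = mu * phi, beta_ = (1 - mu) * phi, mu = mu, phi = phi,
       loglik = -opt$value, converged = opt$convergence == 0L)
}

#' Per-CpG beta-binomial likelihood-ratio test
#'
#' Compares a pooled beta-binomial fit (one mean and one dispersion for all
#' samples) against per-group fits. With \code{df_mode = "full"} each group
#' gets its own (mean, dispersion) pair and the statistic is referred to a
#' chi-square with 2 df; \code{"shared_dispersion"} frees only the group
#' means (1 df). The effect size delta is the difference of the fitted
#' group mean methylation levels (case minus control).
#'
#' @param k,N Per-sample count vectors.
#' @param groups Per-sample group labels (two levels).
#' @param case,control Group labels; delta = pi(case) - pi(control).
#' @param df_mode "full" (default) or "shared_dispersion".
#' @return List with delta, p_raw, pi_case, pi_control, lrt, converged.
#' @export
lrt_site_test <- function(k, N, groups, case, control, df_mode = "full") {
  null_fit <- fit_betabinom(k, N)
  kc <- k[groups == case];    Nc <- N[groups == case]
  kw <- k[groups == control]; Nw <- N[groups == control]
  if (df_mode == "full") {
    fit_case <- fit_betabinom(kc, Nc)
    fit_ctrl <- fit_betabinom(kw, Nw)
    ll_alt <- fit_case$loglik + fit_ctrl$loglik
    pi_case <- fit_case$mu; pi_ctrl <- fit_ctrl$mu
    converged <- null_fit$converged && fit_case$converged && fit_ctrl$converged
    df <- 2L
  } else if (df_mode == "shared_dispersion") {
    alt <- fit_betabinom_shared(kc, Nc, kw, Nw)
    ll_alt <- alt$loglik
    pi_case <- alt$mu1; pi_ctrl <- alt$mu2
    converged <- null_fit$converged && alt$converged
    df <- 1L
  } else {
    stop("df_mode must be 'full' or 'shared_dispersion'")
  }
  lrt <- max(2 * (ll_alt - null_fit$loglik), 0)
  p_raw <- if (converged) {
    stats::pchisq(lrt, df = df, lower.tail = FALSE)
  } else {
    NA_real_
  }
  list(delta = pi_case - pi_ctrl, p_raw = p_raw, pi_case = pi_case,
       pi_control = pi_ctrl, lrt = lrt, converged = converged)
}

# Alternative model with free group means and a single shared dispersion.
fit_betabinom_shared <- function(k1, N1, k2, N2) {
  use1 <- N1 > 0; k1 <- k1[use1]; N1 <- N1[use1]
  use2 <- N2 > 0; k2 <- k2[use2]; N2 <- N2[use2]
  negll <- function(par) {
    mu1 <- stats::plogis(par[1L]); mu2 <- stats::plogis(par[2L])
    phi <- exp(par[3L])
    -(sum(betabinom_loglik(k1, N1, mu1 * phi, (1 - mu1) * phi)) +
        sum(betabinom_loglik(k2, N2, mu2 * phi, (1 - mu2) * phi)))
  }
  m1 <- min(max(sum(k1) / sum(N1), .MU_MIN), 1 - .MU_MIN)
  m2 <- min(max(sum(k2) / sum(N2), .MU_MIN), 1 - .MU_MIN)
  start <- c(stats::qlogis(m1), stats::qlogis(m2), log(50))
  lower <- c(rep(stats::qlogis(.MU_MIN), 2L), log(.PHI_MIN))
  upper <- c(rep(stats::qlogis(1 - .MU_MIN), 2L), log(.PHI_MAX))
  opt <- stats::optim(start, negll, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(factr = 1e5))
  if (opt$convergence != 0L) {
    clamped <- function(par) pmin(pmax(par, lower), upper)
    nm <- stats::optim(clamped(opt$par), function(par) negll(clamped(par)),
                       method = "Nelder-Mead",
                       control = list(maxit = 1000, reltol = 1e-10))
    if (nm$value <= opt$value) {
      opt <- list(par = clamped(nm$par), value = nm$value,
                  convergence = nm$convergence)
    } else {
      opt$convergence <- nm$convergence
    }
  }
  list(mu1 = stats::plogis(opt$par[1L]), mu2 = stats::plogis(opt$par[2L]),
       phi = exp(opt$par[3L]), loglik = -opt$value,
       converged = opt$convergence == 0L)
}

#' Run the per-CpG differential methylation test over a site set
#'
#' Applies \code{\link{lrt_site_test}} to every testable site of a
#' \code{meth_sites} object. Untestable sites are kept with missing test
#' fields so downstream bookkeeping (e.g. enrichment denominators) can
#' choose whether to count them.
#'
#' @param sites \code{meth_sites} object from \code{\link{assemble_sites}}.
#' @param case,control Group labels; delta = pi(case) - pi(control).
#' @param df_mode Passed to \code{\link{lrt_site_test}}.
#' @return data.frame with chrom, pos, testable, pi_control, pi_case,
#'   delta, p_raw (one row per site, input order preserved).
#' @export
test_sites <- function(sites, case, control, df_mode = "full") {
  stopifnot(inherits(sites, "meth_sites"))
  stopifnot(all(c(case, control) %in% sites$groups))
  n <- length(sites$pos)
  pi_ctrl <- pi_case <- delta <- p_raw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!sites$testable[i]) next
    r <- lrt_site_test(sites$meth[i, ], sites$total[i, ], sites$groups,
                       case = case, control = control, df_mode = df_mode)
    pi_ctrl[i] <- r$pi_control; pi_case[i] <- r$pi_case
    delta[i] <- r$delta; p_raw[i] <- r$p_raw
  }
  data.frame(chrom = sites$chrom, pos = sites$pos, testable = sites$testable,
             pi_control = pi_ctrl, pi_case = pi_case, delta = delta,
             p_raw = p_raw, stringsAsFactors = FALSE)
}

#' Combine p-values over a local window (Stouffer's method)
#'
#' For each site, the raw p-values of all sites on the same chromosome
#' within \code{window_bp} of it (itself included) are combined with equal
#' weights: Z = sum(z_j)/sqrt(m) with z_j the upper-tail normal quantile of
#' p_j, and p_comb the upper tail of Z. This borrows strength from
#' methylation changes that are locally coherent, the signal DMR callers
#' look for. Sites with missing p_raw are excluded from every window and
#' get a missing p_comb.
#'
#' @param results data.frame sorted by (chrom, pos) with columns chrom,
#'   pos, p_raw.
#' @param window_bp Window half-width in bp (default 200).
#' @return The input with a p_comb column added.
#' @export
combine_neighbors <- function(results, window_bp = 200) {
  check_sorted(results$chrom, results$pos)
  p_comb <- rep(NA_real_, nrow(results))
  for (chr in unique(results$chrom)) {
    in_chr <- which(results$chrom == chr)
    ok <- in_chr[!is.na(results$p_raw[in_chr])]
    if (!length(ok)) next
    pos_ok <- results$pos[ok]
    # clip so p of exactly 0 or 1 (LRT overflow/clamp) keeps z finite
    p_clip <- pmin(pmax(results$p_raw[ok], 1e-15), 1 - 1e-15)
    z <- stats::qnorm(p_clip, lower.tail = FALSE)
    cz <- c(0, cumsum(z))
    lo <- findInterval(pos_ok - window_bp - 0.5, pos_ok) + 1L
    hi <- findInterval(pos_ok + window_bp + 0.5, pos_ok)
    m <- hi - lo + 1L
    Z <- (cz[hi + 1L] - cz[lo]) / sqrt(m)
    p_comb[ok] <- stats::pnorm(Z, lower.tail = FALSE)
  }
  results$p_comb <- p_comb
  results
}

check_sorted <- function(chrom, pos) {
  if (length(pos) < 2L) return(invisible(TRUE))
  o <- order(chrom, pos, method = "radix")
  if (any(o != seq_along(o))) stop("sites must be sorted by (chrom, pos)")
  invisible(TRUE)
}

#' Benjamini-Hochberg adjustment with missing-value passthrough
#'
#' Standard BH step-up on the non-missing values (m = number of non-missing
#' tests); missing values stay missing and do not enter m.
#'
#' @param pvals Numeric vector in [0,1], NA allowed.
#' @return Adjusted values, input order preserved.
#' @export
adjust_bh <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values must be in [0,1]")
  out <- rep(NA_real_, length(pvals))
  out[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  out
}

#' Label sites as hyper-, hypo- or not significantly methylated
#'
#' A site is hyper when fdr < fdr_threshold and delta >= +min_delta, hypo
#' when fdr < fdr_threshold and delta <= -min_delta, otherwise ns.
#'
#' @param results data.frame with fdr and delta columns.
#' @param fdr_threshold FDR cutoff (default 0.01).
#' @param min_delta Minimum absolute methylation change (default 0.1).
#' @return The input with a label column ("hyper"/"hypo"/"ns"; untested
#'   sites get "ns").
#' @export
label_sites <- function(results, fdr_threshold = 0.01, min_delta = 0.1) {
  stopifnot(fdr_threshold > 0, fdr_threshold <= 1, min_delta >= 0)
  label <- rep("ns", nrow(results))
  sig <- !is.na(results$fdr) & results$fdr < fdr_threshold
  label[sig & results$delta >= min_delta] <- "hyper"
  label[sig & results$delta <= -min_delta] <- "hypo"
  results$label <- label
  results
}

#' Summarize the direction of significant methylation changes
#'
#' @param results Labeled site results.
#' @return List with n_hyper, n_hypo, n_ns and frac_hyper_among_sig
#'   (NA when nothing is significant).
#' @export
direction_summary <- function(results) {
  n_hyper <- sum(results$label == "hyper")
  n_hypo <- sum(results$label == "hypo")
  n_ns <- sum(results$label == "ns")
  frac <- if (n_hyper + n_hypo > 0) n_hyper / (n_hyper + n_hypo) else NA_real_
  list(n_hyper = n_hyper, n_hypo = n_hypo, n_ns = n_ns,
       frac_hyper_among_sig = frac)
}

#' Full per-site differential methylation chain
#'
#' test_sites -> combine_neighbors -> adjust_bh (on the combined p-values)
#' -> label_sites, with the defaults of each stage.
#'
#' @param sites \code{meth_sites} object.
#' @param case,control Group labels.
#' @param window_bp,fdr_threshold,min_delta,df_mode Stage parameters.
#' @return Labeled per-site results data.frame (columns chrom, pos,
#'   testable, pi_control, pi_case, delta, p_raw, p_comb, fdr, label).
#' @export
diffmeth_chain <- function(sites, case, control, window_bp = 200,
                           fdr_threshold = 0.01, min_delta = 0.1,
                           df_mode = "full") {
  res <- test_sites(sites, case = case, control = control, df_mode = df_mode)
  res <- combine_neighbors(res, window_bp = window_bp)
  res$fdr <- adjust_bh(res$p_comb)
  label_sites(res, fdr_threshold = fdr_threshold, min_delta = min_delta)
}

#' Write the per-site test table
#'
#' Tab-separated with a documented header: chrom, pos, then meth/total
#' counts per sample, pi_control, pi_case, delta, p_raw, p_comb, fdr,
#' label.
#'
#' @param results Labeled results from \code{\link{diffmeth_chain}}.
#' @param sites The \code{meth_sites} object the results came from.
#' @param path Output path.
#' @export
write_site_table <- function(results, sites, path) {
  meth <- sites$meth; total <- sites$total
  colnames(meth) <- paste0("meth.", sites$samples)
  colnames(total) <- paste0("total.", sites$samples)
  out <- cbind(results[, c("chrom", "pos")], meth, total,
               results[, c("pi_control", "pi_case", "delta", "p_raw",
                           "p_comb", "fdr", "label")])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# per-CpG beta-binomial differential methylation results (pos 0-based)",
             con)
  utils::write.table(format(out, digits = 15, trim = TRUE, scientific = NA),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
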