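make_records <- function(...) {
  rows <- list(...)
  data.frame(chrom = vapply(rows, `[[`, "", 1),
             pos = as.integer(vapply(rows, function(r) r[[2]], 1)),
             strand = vapply(rows, `[[`, "", 3),
             context = "CpG",
             meth_reads = as.integer(vapply(rows, function(r) r[[4]], 1)),
             total_reads = as.integer(vapply(rows, function(r) r[[5]], 1)),
             stringsAsFactors = FALSE)
}

test_that("strand merging sums dinucleotide pairs and passes singletons through", {
  paired <- make_records(list("chr1", 100, "+", 3, 10), list("chr1", 101, "-", 2, 5))
  expect_equal(merge_strands(paired),
               data.frame(chrom = "chr1", pos = 100L, meth = 5L, total = 15L))

  fwd_only <- make_records(list("chr1", 100, "+", 3, 10))
  expect_equal(merge_strands(fwd_only),
               data.frame(chrom = "chr1", pos = 100L, meth = 3L, total = 10L))

  # reverse-only cytosine keys at the forward-C position one base left
  rev_only <- make_records(list("chr1", 101, "-", 2, 5))
  expect_equal(merge_strands(rev_only)$pos, 100L)

  dup <- make_records(list("chr1", 100, "+", 3, 10), list("chr1", 100, "+", 1, 2))
  expect_error(merge_strands(dup), "duplicate")
})

test_that("strand merging matches the exhaustive pairing oracle", {
  set.seed(7)
  for (trial in 1:25) {
    recs <- random_cytosine_records(sample(20:120, 1))
    expect_equal(merge_strands(recs), oracle_merge_strands(recs))
  }
})

test_that("site assembly keys by merged position and flags testability", {
  merged <- list(
    a1 = data.frame(chrom = "chr1", pos = 100L, meth = 3L, total = 10L),
    a2 = data.frame(chrom = "chr1", pos = c(100L, 300L), meth = c(1L, 4L),
                    total = c(8L, 9L)),
    b1 = data.frame(chrom = "chr1", pos = 100L, meth = 7L, total = 12L))
  design <- c(a1 = "wt", a2 = "wt", b1 = "mut")
  sites <- assemble_sites(merged, design)
  expect_equal(length(sites$pos), 2L)             # distinct merged keys
  expect_equal(sites$testable, c(TRUE, FALSE))    # chr1:300 only in wt
  expect_equal(sites$total[1, ], c(a1 = 10L, a2 = 8L, b1 = 12L))
  expect_equal(sites$total[2, "b1"], c(b1 = 0L))  # uncovered sample gets 0

  expect_error(assemble_sites(merged, c(a1 = "wt", a2 = "wt")), "design lacks")
  expect_error(assemble_sites(merged, c(a1 = "wt", a2 = "wt", b1 = "wt")),
               "two groups")
})

test_that("site count equals the number of distinct merged keys", {
  set.seed(8)
  merged <- lapply(1:4, function(i) merge_strands(random_cytosine_records(80)))
  names(merged) <- paste0("s", 1:4)
  design <- c(s1 = "wt", s2 = "wt", s3 = "mut", s4 = "mut")
  sites <- assemble_sites(merged, design)
  keys <- unique(do.call(rbind, lapply(merged, function(m) m[, c("chrom", "pos")])))
  expect_equal(length(sites$pos), nrow(keys))
})

test_that("beta-binomial log pmf matches its limits and quadrature", {
  expect_equal(betabinom_loglik(0, 0, 2, 3), 0)
  expect_error(betabinom_loglik(3, 10, -1, 2), "> 0")
  expect_error(betabinom_loglik(11, 10, 1, 2), "k <= N")

  # concentration limit: Beta(pi*c, (1-pi)*c) with c -> infinity is binomial
  c_ <- 1e6; pi_ <- 0.3
  expect_equal(betabinom_loglik(3, 10, pi_ * c_, (1 - pi_) * c_),
               dbinom(3, 10, pi_, log = TRUE), tolerance = 1e-3)

  # quadrature oracle: integrate binomial pmf against the Beta density
  quad <- integrate(function(p) dbinom(2, 6, p) * dbeta(p, 2, 3), 0, 1,
                    rel.tol = 1e-12)$value
  expect_equal(betabinom_loglik(2, 6, 2, 3), log(quad), tolerance = 1e-9)

  # log of a pmf is never positive
  set.seed(9)
  for (trial in 1:50) {
    N <- sample(0:40, 1); k <- sample.int(N + 1, 1) - 1
    expect_lte(betabinom_loglik(k, N, runif(1, 0.1, 50), runif(1, 0.1, 50)), 0)
  }
})

test_that("beta-binomial MLE handles boundaries and beats a grid search", {
  f <- fit_betabinom(5, 10)
  expect_equal(f$mu, 0.5, tolerance = 1e-3)

  f0 <- fit_betabinom(c(0, 0, 0), c(10, 20, 15))
  expect_lt(f0$mu, 0.01)  # mean driven to the lower boundary cap
  expect_error(fit_betabinom(c(0, 0), c(0, 0)), "not fittable")

  set.seed(10)
  for (trial in 1:5) {
    N <- rep(200L, 6)
    k <- rbinom(6, N, rbeta(6, 4, 6))
    fit <- fit_betabinom(k, N)
    expect_true(fit$converged)
    grid <- exp(seq(log(1e-2), log(1e4), length.out = 120))
    best <- -Inf
    for (a in grid) {
      ll <- vapply(grid, function(b) sum(betabinom_loglik(k, N, a, b)), 1.0)
      best <- max(best, max(ll))
    }
    expect_gte(fit$loglik, best - 1e-3)
  }
})

test_that("pooled-fit mean recovers truth with deep aggregate coverage", {
  set.seed(11)
  for (pi_true in c(0.2, 0.5, 0.8)) {
    N <- rep(40L, 50)  # 2000 reads total over many replicates
    k <- rbinom(50, N, rbeta(50, pi_true * 30, (1 - pi_true) * 30))
    expect_lt(abs(fit_betabinom(k, N)$mu - pi_true), 0.02)
  }
})

test_that("likelihood-ratio test behaves at the null and at maximal separation", {
  groups <- rep(c("wt", "mut"), each = 3)
  same <- lrt_site_test(rep(5, 6), rep(10, 6), groups, "mut", "wt")
  expect_lt(same$lrt, 0.1)
  expect_gt(same$p_raw, 0.95)

  # complete separation: the largest possible effect size; the p-value
  # stays moderate because the pooled null with free dispersion can mimic
  # bimodal replicates (see the dispersion-box note in the vignette)
  sep <- lrt_site_test(c(0, 0, 0, 30, 30, 30), rep(30, 6), groups, "mut", "wt")
  expect_lt(sep$p_raw, 0.05)
  expect_equal(sep$delta, 1, tolerance = 1e-3)

  sep1 <- lrt_site_test(c(0, 0, 0, 30, 30, 30), rep(30, 6), groups, "mut", "wt",
                        df_mode = "shared_dispersion")
  expect_lt(sep1$p_raw, 0.05)

  # the alternative nests the null: statistic never meaningfully negative
  set.seed(12)
  for (trial in 1:30) {
    N <- rnbinom(6, mu = 25, size = 5) + 1L
    k <- rbinom(6, N, rbeta(6, 3, 7))
    expect_gte(lrt_site_test(k, N, groups, "mut", "wt")$lrt, -1e-6)
  }
})

test_that("neighbor combination follows Stouffer arithmetic and the oracle", {
  iso <- data.frame(chrom = "c1", pos = c(100L, 5000L), p_raw = c(0.01, 0.5))
  out <- combine_neighbors(iso, 200)
  expect_equal(out$p_comb, out$p_raw)  # m = 1 identity

  two <- data.frame(chrom = "c1", pos = c(100L, 150L), p_raw = c(0.05, 0.05))
  expect_true(all(abs(combine_neighbors(two, 200)$p_comb - 0.0100) < 5e-4))

  unsorted <- data.frame(chrom = "c1", pos = c(200L, 100L), p_raw = c(0.5, 0.5))
  expect_error(combine_neighbors(unsorted, 200), "sorted")

  set.seed(13)
  for (trial in 1:25) {
    n <- sample(10:150, 1)
    res <- data.frame(chrom = sample(c("c1", "c2"), n, replace = TRUE),
                      pos = sample.int(5000, n), p_raw = runif(n))
    res$p_raw[runif(n) < 0.1] <- NA
    res <- res[order(res$chrom, res$pos, method = "radix"), , drop = FALSE]
    w <- sample(c(50, 200, 1000), 1)
    expect_equal(combine_neighbors(res, w)$p_comb,
                 oracle_combine_neighbors(res, w), tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the step-up formula and keeps missing values", {
  expect_equal(adjust_bh(0.04), 0.04)
  expect_equal(adjust_bh(c(0.01, 0.04, 0.03, 0.02)), rep(0.04, 4))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0,1\\]")

  set.seed(14)
  for (trial in 1:25) {
    p <- runif(sample(5:200, 1))
    p[runif(length(p)) < 0.15] <- NA
    got <- adjust_bh(p)
    expect_equal(got, oracle_bh(p))
    expect_true(all(is.na(got) == is.na(p)))
    # monotone in the sorted order of raw p
    ok <- !is.na(p)
    expect_true(!is.unsorted(got[ok][order(p[ok])]))
  }
})

test_that("site labels apply the FDR and effect-size gates", {
  res <- data.frame(fdr = c(0.001, 0.5, 0.001, 0.001),
                    delta = c(0.3, 0.9, 0.05, -0.4))
  lab <- label_sites(res, fdr_threshold = 0.01, min_delta = 0.1)
  expect_equal(lab$label, c("hyper", "ns", "ns", "hypo"))
})

test_that("direction summary counts are consistent and permutation invariant", {
  res <- data.frame(label = c("hyper", "hyper", "hypo", "ns", "ns"))
  s <- direction_summary(res)
  expect_equal(s$n_hyper + s$n_hypo + s$n_ns, nrow(res))
  expect_equal(s$frac_hyper_among_sig, 2 / 3)
  set.seed(15)
  s2 <- direction_summary(res[sample(nrow(res)), , drop = FALSE])
  expect_equal(s2, s)

  none <- direction_summary(data.frame(label = rep("ns", 4)))
  expect_true(is.na(none$frac_hyper_among_sig))
  expect_equal(none$n_ns, 4L)
})
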