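test_that("TSS association uses edge distance with a 1 kb default", {
  dmrs <- data.frame(chrom = "chr1", start = 2000L, end = 2100L,
                     mean_delta = 0.3, best_fdr = 1e-4)
  tss <- data.frame(gene_id = c("near", "far", "inside"),
                    chrom = "chr1", tss = c(2900L, 3200L, 2050L),
                    strand = "+")
  assoc <- associate_tss(dmrs, tss, max_dist_bp = 1000)
  expect_setequal(assoc$gene_id, c("near", "inside"))
  expect_equal(assoc$distance[assoc$gene_id == "near"], 800L)
  expect_equal(assoc$distance[assoc$gene_id == "inside"], 0L)

  strict <- associate_tss(dmrs, tss, max_dist_bp = 0)
  expect_equal(strict$gene_id, "inside")
})

test_that("TSS association matches the all-pairs oracle", {
  set.seed(31)
  for (trial in 1:20) {
    nd <- sample(3:20, 1); nt <- sample(3:30, 1)
    start <- sample.int(50000, nd)
    dmrs <- data.frame(chrom = sample(c("c1", "c2"), nd, replace = TRUE),
                       start = start, end = start + sample(10:2000, nd, replace = TRUE))
    tss <- data.frame(gene_id = paste0("g", seq_len(nt)),
                      chrom = sample(c("c1", "c2"), nt, replace = TRUE),
                      tss = sample.int(55000, nt), strand = "+")
    md <- sample(c(0, 500, 1000, 5000), 1)
    got <- associate_tss(dmrs, tss, md)
    want <- oracle_associate_tss(dmrs, tss, md)
    o <- function(x) x[order(x$dmr_row, x$gene_id, method = "radix"), ,
                       drop = FALSE]
    got <- o(got); want <- o(want)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("interval membership is half-open and matches the linear scan", {
  iv <- data.frame(start = c(10L, 50L), end = c(20L, 60L))
  expect_equal(interval_membership(c(9L, 10L, 19L, 20L, 55L, 60L), iv),
               c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(interval_membership(c(1L, 2L), iv[0, ]), c(FALSE, FALSE))
  expect_error(interval_membership(c(5L, 1L), iv), "sorted")

  set.seed(32)
  for (trial in 1:25) {
    n_iv <- sample(1:40, 1)
    start <- sample.int(3000, n_iv)
    iv <- data.frame(start = start, end = start + sample(1:300, n_iv, replace = TRUE))
    pos <- sort(sample.int(3500, sample(10:200, 1)))
    expect_equal(interval_membership(pos, iv), oracle_membership(pos, iv))
  }
})

test_that("enrichment fractions follow their definition and the module contract", {
  res <- data.frame(chrom = "c1", pos = as.integer(10 * (1:12)),
                    p_raw = c(rep(0.5, 10), NA, 0.5),
                    label = c(rep("hyper", 3), "hypo", rep("ns", 8)),
                    stringsAsFactors = FALSE)
  sets <- list(all10 = data.frame(chrom = "c1", start = 0L, end = 101L),
               empty = data.frame(chrom = "c1", start = 5000L, end = 6000L))
  en <- enrichment_fractions(res, sets)
  expect_equal(en$n_profiled, c(10L, 0L))
  expect_equal(en$frac_hyper[1], 0.3)
  expect_equal(en$frac_hypo[1], 0.1)
  expect_true(is.na(en$frac_hyper[2]))

  # a set covering everything reproduces the direction summary exactly
  whole <- list(genome = data.frame(chrom = "c1", start = 0L, end = 10000L))
  en2 <- enrichment_fractions(res, whole)
  ds <- direction_summary(res[!is.na(res$p_raw), ])
  expect_equal(en2$n_hyper, ds$n_hyper)
  expect_equal(en2$n_hypo, ds$n_hypo)
  expect_equal(en2$n_profiled, sum(!is.na(res$p_raw)))
})

test_that("PWM scanning finds planted consensus sites on both strands", {
  mat <- matrix(-2, 4, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  mat[1, "A"] <- 2; mat[2, "C"] <- 2; mat[3, "G"] <- 2; mat[4, "T"] <- 2
  pwm <- structure(list(name = "cons", matrix = mat), class = "pwm")

  hits <- pwm_scan("GGACGTGG", pwm, 8)
  expect_equal(nrow(hits), 2L)          # ACGT is its own reverse complement
  expect_equal(unique(hits$offset), 2L)
  expect_equal(hits$score, c(8, 8))

  mat2 <- mat; mat2[4, ] <- c(2, -2, -2, -2)  # consensus ACGA
  pwm2 <- structure(list(name = "cons2", matrix = mat2), class = "pwm")
  fwd <- pwm_scan("TTACGATT", pwm2, 8)
  expect_equal(fwd$strand, "+")
  expect_equal(fwd$offset, 2L)
  rev_hit <- pwm_scan("TTTCGTTT", pwm2, 8)  # TCGT = revcomp(ACGA)
  expect_equal(rev_hit$strand, "-")

  expect_equal(nrow(pwm_scan("ACNGA", pwm2, -100)), 0L)  # N voids all windows
  expect_error(pwm_scan("ACGX", pwm2, 0), "non-ACGTN")
})

test_that("PWM scanning matches per-window rescoring and is strand symmetric", {
  set.seed(33)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (trial in 1:20) {
    L <- sample(3:8, 1)
    pwm <- random_pwm(L)
    seq_ <- paste(sample(c("A", "C", "G", "T"), sample(30:200, 1),
                         replace = TRUE), collapse = "")
    thr <- quantile(rnorm(50), 0.7)
    got <- pwm_scan(seq_, pwm, thr)
    expect_equal(got, oracle_pwm_scan(seq_, pwm, thr), tolerance = 1e-12)
    # reverse complementing the sequence preserves the number of hits
    rc <- paste(rev(unname(comp[strsplit(seq_, "")[[1]]])), collapse = "")
    expect_equal(nrow(pwm_scan(rc, pwm, thr)), nrow(got))
  }
})

test_that("beta-value group comparison recovers shifts and exact nulls", {
  set.seed(34)
  vals <- matrix(runif(400, 0.2, 0.8), 100, 4,
                 dimnames = list(paste0("p", 1:100), paste0("s", 1:4)))
  same <- structure(list(values = cbind(vals, vals),
                         probe_ids = rownames(vals),
                         sample_ids = paste0("s", 1:8),
                         group_labels = rep(c("wt", "mut"), each = 4)),
                    class = "beta_matrix")
  r <- compare_beta_groups(same, case = "mut", control = "wt")
  expect_equal(r$mean_delta, 0)
  expect_equal(r$p_value, 1)

  shifted <- same
  shifted$values[, 5:8] <- pmin(shifted$values[, 5:8] + 0.1, 1)
  r2 <- compare_beta_groups(shifted, case = "mut", control = "wt")
  expect_equal(r2$mean_delta, 0.1, tolerance = 1e-9)
  expect_lt(r2$p_value, 1e-10)

  # probes missing one whole group are excluded from the count
  holed <- shifted
  holed$values[1:3, 5:8] <- NA
  expect_equal(compare_beta_groups(holed, case = "mut", control = "wt")$n_probes_used,
               97L)

  # per-probe shift ~ Normal(0.05, 0.02) is recovered
  set.seed(35)
  n <- 2000
  base <- matrix(runif(n * 3, 0.2, 0.7), n, 3)
  shift <- rnorm(n, 0.05, 0.02)
  b <- structure(list(values = cbind(base, base + shift),
                      probe_ids = paste0("p", 1:n),
                      sample_ids = paste0("s", 1:6),
                      group_labels = rep(c("wt", "mut"), each = 3)),
                 class = "beta_matrix")
  r3 <- compare_beta_groups(b, case = "mut", control = "wt")
  expect_lt(abs(r3$mean_delta - 0.05), 0.01)
})

test_that("feature sets load from a BED directory or a grouped BED4 file", {
  dir_ <- withr::local_tempdir()
  write_bed(data.frame(chrom = "c1", start = 0L, end = 10L),
            file.path(dir_, "setA.bed"))
  write_bed(data.frame(chrom = "c1", start = 20L, end = 30L),
            file.path(dir_, "setB.bed"))
  sets <- load_feature_sets(dir_)
  expect_equal(names(sets), c("setA", "setB"))

  one <- file.path(dir_, "grouped.bed4")
  writeLines(c("c1\t0\t10\tx", "c1\t20\t30\ty", "c1\t40\t50\tx"), one)
  grouped <- load_feature_sets(one)
  expect_equal(sort(names(grouped)), c("x", "y"))
  expect_equal(nrow(grouped$x), 2L)
})
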