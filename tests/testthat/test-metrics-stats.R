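test_that("binarize follows the >= convention and is idempotent on binary maps", {
  half <- array(0.5, c(2, 2))
  expect_identical(binarize(half, 0.5), array(1, c(2, 2)))
  bin <- array(c(0, 1, 1, 0), c(2, 2))
  expect_identical(binarize(bin, 0.5), bin)
  expect_identical(as.numeric(binarize(c(0.6, 0.8), 0.7)), c(0, 1))
  expect_error(binarize(half, 0), "threshold")
})

test_that("confusion counts enumerate the four pixel classes", {
  pred <- array(c(1, 1, 0, 0), c(2, 2))
  targ <- array(c(1, 0, 1, 0), c(2, 2))
  cc <- confusion_counts(pred, targ)
  expect_identical(cc, c(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  expect_identical(confusion_counts(targ, targ)[c("fp", "fn")], c(fp = 0L, fn = 0L))
  comp <- 1 - targ
  expect_identical(confusion_counts(comp, targ)[c("tp", "tn")], c(tp = 0L, tn = 0L))
  set.seed(2)
  for (i in 1:20) {
    a <- matrix(rbinom(48, 1, 0.5), 6, 8)
    b <- matrix(rbinom(48, 1, 0.5), 6, 8)
    expect_identical(sum(confusion_counts(a, b)), 48L)
  }
  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("metrics match the count formulas and degenerate conventions", {
  pred <- array(c(1, 1, 0, 0), c(2, 2))
  targ <- array(c(1, 0, 1, 0), c(2, 2))
  r <- compute_metrics(pred, targ)
  expect_equal(r$dice, 0.5)
  expect_equal(r$iou, 1 / 3)
  expect_equal(r$precision, 0.5)
  expect_equal(r$recall, 0.5)
  perfect <- compute_metrics(targ, targ)
  expect_true(all(unlist(perfect[c("dice", "iou", "precision", "recall")]) == 1))
  # empty-empty: vacuously perfect; one-sided empties score 0 on the 0/0 metric
  e <- matrix(0, 3, 3)
  f <- matrix(c(1, rep(0, 8)), 3, 3)
  expect_true(all(unlist(compute_metrics(e, e)[-1]) == 1))
  expect_equal(compute_metrics(e, f)$precision, 0)
  expect_equal(compute_metrics(e, f)$recall, 0)
  expect_equal(compute_metrics(f, e)$precision, 0)
})

test_that("dice and IoU satisfy dice = 2 iou / (1 + iou) on random masks", {
  set.seed(4)
  for (i in 1:1000) {
    a <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8, 8)
    b <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8, 8)
    r <- compute_metrics(a, b)
    expect_equal(r$dice, 2 * r$iou / (1 + r$iou), tolerance = 1e-12)
  }
})

test_that("metrics are invariant under a simultaneous spatial permutation", {
  set.seed(6)
  a <- matrix(rbinom(36, 1, 0.4), 6, 6)
  b <- matrix(rbinom(36, 1, 0.4), 6, 6)
  perm <- sample(36)
  r1 <- compute_metrics(a, b)
  r2 <- compute_metrics(matrix(a[perm], 6, 6), matrix(b[perm], 6, 6))
  expect_equal(r1[-1], r2[-1])
})

test_that("summaries use per-image mean and n-1 standard deviation", {
  r1 <- compute_metrics(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 0, 1, 0), 2), "a")
  s1 <- summarize_metrics(r1)
  expect_identical(s1$n, rep(1L, 4))
  expect_identical(s1$sd, rep(0, 4))
  expect_equal(s1$mean[s1$metric == "dice"], 0.5)
  recs <- rbind(r1, r1)
  recs$dice <- c(0.6, 0.8)
  s2 <- summarize_metrics(recs)
  expect_equal(s2$mean[s2$metric == "dice"], 0.7)
  expect_equal(s2$sd[s2$metric == "dice"], sd(c(0.6, 0.8)))
  expect_equal(summarize_metrics(recs[2:1, ]), s2)
  expect_error(summarize_metrics(recs[0, ]), "nrow|>= 1")
})

test_that("signed-rank test matches the textbook example and handles degeneracy", {
  a <- 1:6
  b <- a + 1
  res <- wilcoxon_signed_rank(a, b)
  # all six differences equal and same-signed: two-sided exact p = 2 / 2^6
  expect_equal(res$p_value, 0.03125, tolerance = 1e-12)
  expect_identical(res$method, "exact")
  expect_identical(res$n_effective, 6L)
  expect_warning(res0 <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3)), "zero")
  expect_identical(res0$p_value, 1)
  expect_identical(res0$n_effective, 0L)
})

test_that("exact p-values equal the exhaustive sign-flip enumeration for n <= 12", {
  set.seed(8)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    a <- round(rnorm(n), 2)
    b <- round(rnorm(n), 2)
    keep <- a != b
    if (sum(keep) < 2) next
    res <- wilcoxon_signed_rank(a[keep], b[keep])
    expect_equal(res$p_value, wilcoxon_brute_force(a[keep], b[keep]),
                 tolerance = 1e-12, label = sprintf("case %d", i))
  }
})

test_that("tie-free exact results agree with the standard library test", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(5:20, 1)
    a <- rnorm(n)
    b <- rnorm(n)
    res <- wilcoxon_signed_rank(a, b)
    ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE, correct = FALSE)
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("large samples fall back to a corrected normal approximation", {
  set.seed(14)
  a <- rnorm(60)
  b <- a + rnorm(60, mean = 0.3)
  res <- wilcoxon_signed_rank(a, b)
  expect_identical(res$method, "normal_approx")
  ref <- wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-8)
})

test_that("one-sided alternatives and the Pratt zero handling are available", {
  a <- c(3, 4, 5, 6, 7, 8)
  b <- c(1, 2, 3, 4, 5, 6)
  pg <- wilcoxon_signed_rank(a, b, alternative = "greater")$p_value
  pl <- wilcoxon_signed_rank(a, b, alternative = "less")$p_value
  expect_lt(pg, 0.05)
  expect_gt(pl, 0.9)
  withz <- wilcoxon_signed_rank(c(0, 1, 2, 3, 4, 5), c(0, 0, 0, 0, 0, 0),
                                zero_method = "pratt")
  expect_identical(withz$n_effective, 5L)
  expect_identical(withz$method, "normal_approx")
})

test_that("the ablation report has 12 p-values and a summary row per mode and metric", {
  set.seed(20)
  base_rec <- do.call(rbind, lapply(1:10, function(i) {
    compute_metrics(matrix(rbinom(16, 1, 0.5), 4),
                    matrix(rbinom(16, 1, 0.5), 4), sprintf("s%02d", i))
  }))
  sd_rec <- base_rec; sd_rec$dice <- pmin(1, sd_rec$dice + runif(10, 0, 0.1))
  pr_rec <- base_rec; pr_rec$dice <- pmin(1, pr_rec$dice + runif(10, 0, 0.2))
  rep_ <- ablation_report(list(base = base_rec, sd = sd_rec, prism = pr_rec))
  expect_identical(nrow(rep_$wilcoxon), 12L)
  expect_identical(nrow(rep_$summary), 12L)
  expect_setequal(unique(rep_$wilcoxon$comparison),
                  c("base vs sd", "base vs prism", "sd vs prism"))
  # identical records for all modes: all p-values 1, identical summaries
  same <- ablation_report(list(base = base_rec, sd = base_rec, prism = base_rec))
  expect_true(all(same$wilcoxon$p_value == 1))
  expect_identical(same$summary$mean[same$summary$mode == "base"],
                   same$summary$mean[same$summary$mode == "prism"])
  # mismatched sample ids invalidate the pairing
  bad <- sd_rec; bad$sample_id[1] <- "other"
  expect_error(ablation_report(list(base = base_rec, sd = bad)), "sample ids")
})

test_that("reports round-trip losslessly through the CSV writer", {
  set.seed(22)
  recs <- do.call(rbind, lapply(1:6, function(i) {
    compute_metrics(matrix(rbinom(16, 1, 0.5), 4),
                    matrix(rbinom(16, 1, 0.5), 4), sprintf("s%02d", i))
  }))
  rep_ <- ablation_report(list(base = recs, prism = recs))
  dir <- withr::local_tempdir()
  write_report(rep_, dir)
  back <- read_report(dir)
  expect_equal(back$summary$mean, rep_$summary$mean)
  expect_equal(back$wilcoxon$p_value, rep_$wilcoxon$p_value)
  expect_identical(nrow(back$records), nrow(rep_$records))
})
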