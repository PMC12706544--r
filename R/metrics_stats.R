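# Per-image segmentation metrics (Dice / IoU / Precision / Recall), mean +/- sd
# aggregation across images, and the paired Wilcoxon signed-rank comparison
# used to contrast training regimes.

#' Threshold a probability map into a binary mask
#'
#' Entries greater than or equal to the threshold map to 1 (so an exactly
#' 0.5-valued map at the default threshold is all-foreground), the rest to 0.
#' Idempotent on maps that are already binary.
#'
#' @param pred probability map (any numeric array).
#' @param threshold scalar in `(0, 1)`; default 0.5.
#' @return array of 0/1 values with the shape of `pred`.
#' @export
binarize <- function(pred, threshold = 0.5) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1)
  out <- (pred >= threshold) * 1
  dim(out) <- dim(pred)
  out
}

#' Pixel-wise confusion counts
#'
#' @param pred,target binary masks of identical shape.
#' @return named vector `c(tp, fp, fn, tn)`; the four counts sum to the pixel
#'   count.
#' @export
confusion_counts <- function(pred, target) {
  check_same_shape(pred, target, "confusion_counts")
  p <- as.numeric(pred); y <- as.numeric(target)
  c(tp = sum(p == 1 & y == 1), fp = sum(p == 1 & y == 0),
    fn = sum(p == 0 & y == 1), tn = sum(p == 0 & y == 0))
}

#' Per-image segmentation metrics
#'
#' Dice `2tp/(2tp+fp+fn)`, IoU `tp/(tp+fp+fn)`, Precision `tp/(tp+fp)` and
#' Recall `tp/(tp+fn)` from hard masks. Degenerate denominators follow the
#' usual evaluation convention for lesion segmentation: if both masks are
#' empty every metric is 1 (the prediction is vacuously perfect); if exactly
#' one is empty, a 0/0 precision or recall is scored 0.
#'
#' @param pred,target binary masks of identical shape.
#' @param sample_id optional identifier carried into the record.
#' @return a one-row data frame with columns `sample_id`, `dice`, `iou`,
#'   `precision`, `recall`.
#' @export
compute_metrics <- function(pred, target, sample_id = NA_character_) {
  cc <- confusion_counts(pred, target)
  tp <- cc[["tp"]]; fp <- cc[["fp"]]; fn <- cc[["fn"]]
  if (tp + fp + fn == 0) {
    dice <- iou <- precision <- recall <- 1
  } else {
    dice <- 2 * tp / (2 * tp + fp + fn)
    iou <- tp / (tp + fp + fn)
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  }
  data.frame(sample_id = sample_id, dice = dice, iou = iou,
             precision = precision, recall = recall,
             stringsAsFactors = FALSE)
}

#' Aggregate per-image metric records
#'
#' Sample mean and sample standard deviation (n - 1 denominator; 0 for a
#' single record) of each metric over images — per-image averaging, not
#' pixel-pooled.
#'
#' @param records data frame of rows from [compute_metrics()].
#' @return data frame with one row per metric: `metric`, `mean`, `sd`, `n`.
#' @export
summarize_metrics <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  metrics <- c("dice", "iou", "precision", "recall")
  do.call(rbind, lapply(metrics, function(m) {
    v <- records[[m]]
    data.frame(metric = m, mean = mean(v),
               sd = if (length(v) > 1L) sd(v) else 0,
               n = length(v), stringsAsFactors = FALSE)
  }))
}

# exact null distribution of W+ over all sign assignments, by dynamic
# programming on doubled ranks (doubling makes average ranks integral)
wsr_exact_pvalue <- function(ranks, w_plus, alternative) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- numeric(total + 1L) # counts[s + 1] = #assignments with 2*W+ = s
  counts[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1L - r)])
    counts <- counts + shifted
  }
  probs <- counts / 2^length(r2)
  w2 <- round(2 * w_plus)
  p_le <- sum(probs[seq_len(w2 + 1L)])
  p_ge <- sum(probs[(w2 + 1L):(total + 1L)])
  switch(alternative,
    two.sided = min(1, 2 * min(p_le, p_ge)),
    greater = p_ge,
    less = p_le
  )
}

wsr_normal_pvalue <- function(ranks, w_plus, alternative) {
  n <- length(ranks)
  mu <- n * (n + 1) / 4
  # tie correction on the variance
  tie_tab <- table(ranks)
  tie_term <- sum(tie_tab^3 - tie_tab) / 48
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - tie_term
  sigma <- sqrt(sigma2)
  cc <- 0.5 # continuity correction toward the mean
  z_ge <- (w_plus - mu - cc) / sigma
  z_le <- (w_plus - mu + cc) / sigma
  switch(alternative,
    two.sided = {
      p <- 2 * min(pnorm(z_le), pnorm(z_ge, lower.tail = FALSE))
      min(1, p)
    },
    greater = pnorm(z_ge, lower.tail = FALSE),
    less = pnorm(z_le)
  )
}

#' Paired Wilcoxon signed-rank test
#'
#' Tests whether paired observations `a` and `b` differ systematically.
#' Zero differences are discarded before ranking (classical convention;
#' `zero_method = "pratt"` instead ranks them and then drops them from the
#' statistic). Tied absolute differences receive average ranks. The null
#' distribution of `W+` (sum of ranks of positive differences) is computed
#' exactly — by enumeration over sign assignments via dynamic programming,
#' valid under ties — when the number of effective pairs is at most
#' `exact_limit`; otherwise a normal approximation with tie and continuity
#' corrections is used (always used for the Pratt variant).
#'
#' @param a,b equal-length numeric vectors of paired observations.
#' @param alternative `"two.sided"` (default), `"greater"` (a > b) or
#'   `"less"`.
#' @param zero_method `"wilcox"` (discard zero differences) or `"pratt"`.
#' @param exact_limit largest `n_effective` for which the exact distribution
#'   is enumerated.
#' @return list with `statistic` (W+), `p_value`, `n_effective`, `method`.
#' @export
wilcoxon_signed_rank <- function(a, b,
                                 alternative = c("two.sided", "greater", "less"),
                                 zero_method = c("wilcox", "pratt"),
                                 exact_limit = 25L) {
  alternative <- match.arg(alternative)
  zero_method <- match.arg(zero_method)
  stopifnot(is.numeric(a), is.numeric(b), length(a) == length(b),
            length(a) >= 2L)
  d <- a - b
  if (all(d == 0)) {
    warning("wilcoxon_signed_rank: all differences are zero; degenerate result")
    return(list(statistic = 0, p_value = 1, n_effective = 0L,
                method = "degenerate"))
  }
  if (zero_method == "wilcox") {
    d <- d[d != 0]
    r <- rank(abs(d))
    w_plus <- sum(r[d > 0])
    n_eff <- length(d)
    ranks_for_null <- r
  } else {
    r_all <- rank(abs(d)) # zeros included in the ranking
    keep <- d != 0
    w_plus <- sum(r_all[keep & d > 0])
    n_eff <- sum(keep)
    ranks_for_null <- r_all[keep]
  }
  if (zero_method == "wilcox" && n_eff <= exact_limit) {
    p <- wsr_exact_pvalue(ranks_for_null, w_plus, alternative)
    method <- "exact"
  } else {
    p <- wsr_normal_pvalue(ranks_for_null, w_plus, alternative)
    method <- "normal_approx"
  }
  list(statistic = w_plus, p_value = p, n_effective = as.integer(n_eff),
       method = method)
}

#' Ablation comparison of training regimes
#'
#' Combines per-mode metric records into (i) a per-mode mean +/- sd summary of
#' the four metrics and (ii) a matrix of pairwise two-sided Wilcoxon
#' signed-rank p-values (one per metric per mode pair, paired on sample id).
#'
#' @param runs named list mapping mode name to a per-image metrics data frame
#'   (as produced by [evaluate_params()] or [compute_metrics()] rows); all
#'   modes must cover the identical set of sample ids.
#' @return an `ablation_report` list with data frames `summary` (mode, metric,
#'   mean, sd, n), `wilcoxon` (comparison, metric, p_value, statistic,
#'   n_effective, method) and `records` (per sample per mode).
#' @export
ablation_report <- function(runs) {
  stopifnot(is.list(runs), length(runs) >= 2L, !is.null(names(runs)))
  modes <- names(runs)
  ids <- lapply(runs, function(r) sort(r$sample_id))
  for (m in modes[-1L]) {
    if (!identical(ids[[1L]], ids[[m]])) {
      stop(sprintf("ablation_report: sample ids of mode '%s' do not match '%s'",
                   m, modes[1L]))
    }
  }
  summary <- do.call(rbind, lapply(modes, function(m) {
    s <- summarize_metrics(runs[[m]])
    cbind(mode = m, s, stringsAsFactors = FALSE)
  }))
  metrics <- c("dice", "iou", "precision", "recall")
  pairs <- utils::combn(modes, 2L, simplify = FALSE)
  wil <- do.call(rbind, lapply(pairs, function(pr) {
    r1 <- runs[[pr[1L]]][order(runs[[pr[1L]]]$sample_id), ]
    r2 <- runs[[pr[2L]]][order(runs[[pr[2L]]]$sample_id), ]
    do.call(rbind, lapply(metrics, function(met) {
      wt <- suppressWarnings(wilcoxon_signed_rank(r1[[met]], r2[[met]]))
      data.frame(comparison = paste(pr[1L], "vs", pr[2L]), metric = met,
                 p_value = wt$p_value, statistic = wt$statistic,
                 n_effective = wt$n_effective, method = wt$method,
                 stringsAsFactors = FALSE)
    }))
  }))
  records <- do.call(rbind, lapply(modes, function(m) {
    cbind(mode = m, runs[[m]], stringsAsFactors = FALSE)
  }))
  structure(list(summary = summary, wilcoxon = wil, records = records),
            class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat("Ablation report\n\nPer-mode metrics (mean +/- sd over images):\n")
  s <- x$summary
  for (m in unique(s$mode)) {
    rows <- s[s$mode == m, ]
    cat(sprintf("  %-6s %s\n", m, paste(
      sprintf("%s %.4f +/- %.4f", rows$metric, rows$mean, rows$sd),
      collapse = "  ")))
  }
  cat("\nPairwise Wilcoxon signed-rank p-values:\n")
  w <- x$wilcoxon
  for (cmp in unique(w$comparison)) {
    rows <- w[w$comparison == cmp, ]
    cat(sprintf("  %-16s %s\n", cmp, paste(
      sprintf("%s p=%.4f", rows$metric, rows$p_value), collapse = "  ")))
  }
  invisible(x)
}
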