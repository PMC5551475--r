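#' Confusion counts of a called gene set against the truth
#'
#' @param called logical or integer vector: the predicted DE genes.
#' @param truth logical per-gene DE indicator.
#' @return list of class `confusion_counts` with `nTP`, `nFP`, `nFN`, `nTN`.
#' @export
confusion_counts <- function(called, truth) {
  truth <- as.logical(truth)
  pred <- logical(length(truth))
  if (is.logical(called)) {
    stopifnot(length(called) == length(truth))
    pred <- called
  } else {
    pred[called] <- TRUE
  }
  structure(list(nTP = sum(pred & truth), nFP = sum(pred & !truth),
                 nFN = sum(!pred & truth), nTN = sum(!pred & !truth)),
            class = "confusion_counts")
}

#' Confusion-matrix performance rates
#'
#' TPR = TP/(TP+FN), TNR = TN/(TN+FP), FPR = FP/(FP+TN), FNR = FN/(FN+TP),
#' FDR = FP/(TP+FP), MER = (FP+FN)/total, power = 1 - FNR.  A rate whose
#' denominator is zero is reported as `NA` (undefined), never coerced to 0.
#'
#' @param counts a [confusion_counts()] (or list with the four fields).
#' @return named numeric vector of the rates.
#' @export
confusion_metrics <- function(counts) {
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  with(counts, {
    fnr <- rate(nFN, nFN + nTP)
    c(TPR = rate(nTP, nTP + nFN),
      TNR = rate(nTN, nTN + nFP),
      FPR = rate(nFP, nFP + nTN),
      FNR = fnr,
      FDR = rate(nFP, nTP + nFP),
      MER = rate(nFP + nFN, nTP + nTN + nFP + nFN),
      power = 1 - fnr)
  })
}

#' Top-N gene calling
#'
#' The `N` genes with the largest ranking statistic (absolute score for
#' two-class data, the score itself otherwise), ties broken by gene index.
#'
#' @param scores per-gene scores.
#' @param N number of genes to call (0 <= N <= G).
#' @param two_class rank by `abs(scores)`?
#' @return integer vector of the called gene indices.
#' @export
topn_calls <- function(scores, N, two_class = TRUE) {
  if (N > length(scores)) stop("N exceeds the number of genes", call. = FALSE)
  if (N == 0) return(integer(0))
  stat <- ranking_statistic(scores, two_class)
  order(-stat, seq_along(stat))[seq_len(N)]
}

#' ROC staircase, AUC and partial AUC of a gene ranking
#'
#' `roc_curve()` returns the (FPR, TPR) staircase of thresholding the
#' scores from above; tied scores are processed as one block, giving the
#' diagonal segments of the midrank convention.  `auc()` integrates the
#' full curve by trapezoids (equal to the midrank Mann-Whitney statistic);
#' `pauc()` integrates FPR over `[0, fpr_max]` without normalisation, so a
#' perfect ranking has `pauc = fpr_max`.
#'
#' @param scores per-gene ranking statistic (larger = more DE-like).
#' @param truth logical per-gene DE indicator; both classes must occur.
#' @param fpr_max upper end of the partial integration range.
#' @return `roc_curve()`: data frame with `fpr`, `tpr`; `auc()`, `pauc()`:
#'   scalars.
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.logical(truth)
  if (!any(truth) || all(truth)) {
    stop("truth must contain both DE and EE genes", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  t_sorted <- truth[ord]
  # collapse tied-score blocks into single staircase vertices
  last_of_block <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(t_sorted)[last_of_block]
  fp <- cumsum(!t_sorted)[last_of_block]
  data.frame(fpr = c(0, fp / sum(!truth)), tpr = c(0, tp / sum(truth)))
}

#' @rdname roc_curve
#' @export
auc <- function(scores, truth) {
  rc <- roc_curve(scores, truth)
  trapezoid(rc$fpr, rc$tpr)
}

#' @rdname roc_curve
#' @export
pauc <- function(scores, truth, fpr_max = 0.2) {
  stopifnot(fpr_max > 0, fpr_max <= 1)
  rc <- roc_curve(scores, truth)
  if (fpr_max < max(rc$fpr)) {
    tpr_at <- stats::approx(rc$fpr, rc$tpr, xout = fpr_max, ties = max)$y
    keep <- rc$fpr < fpr_max
    rc <- rbind(rc[keep, ], data.frame(fpr = fpr_max, tpr = tpr_at))
  }
  trapezoid(rc$fpr, rc$tpr)
}

#' Operating-point ROC summary of a top-N calling
#'
#' Evaluates the binary classifier "gene is among the top N" instead of the
#' full continuous ranking.  Its ROC staircase has a single operating point
#' (FPR0, TPR0); integrating that staircase without extrapolating beyond
#' the classifier's last threshold gives
#' `AUC = TPR0 * (1 - FPR0 / 2)` and, over FPR in `[0, fpr_max]`,
#' `pAUC = TPR0 * (fpr_max - FPR0 / 2)`.  With N far below the number of
#' EE genes, FPR0 is tiny and these reduce to `AUC ~ TPR0 = 1 - FDR` and
#' `pAUC ~ fpr_max * TPR0` — the convention under which a thresholded gene
#' list is summarised when the ROC is built from the called set itself
#' rather than from the underlying scores.
#'
#' @param scores per-gene scores.
#' @param truth logical per-gene DE indicator.
#' @param N number of genes called (defaults to the number of true DE
#'   genes).
#' @param two_class rank by absolute score?
#' @param fpr_max partial-AUC range.
#' @return named vector with `TPR`, `TNR`, `FPR`, `FNR`, `FDR`, `MER`,
#'   `power`, `AUC`, `pAUC` of the top-N call.
#' @export
topn_metrics <- function(scores, truth, N = sum(truth), two_class = TRUE,
                         fpr_max = 0.2) {
  truth <- as.logical(truth)
  called <- topn_calls(scores, N, two_class = two_class)
  met <- confusion_metrics(confusion_counts(called, truth))
  tpr0 <- met[["TPR"]]
  fpr0 <- met[["FPR"]]
  c(met,
    AUC = tpr0 * (1 - fpr0 / 2),
    pAUC = tpr0 * (fpr_max - fpr0 / 2))
}

trapezoid <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjustment of a p-value vector (delegates to
#' [stats::p.adjust()]), with input validation.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values in `[0, 1]`.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("validation error: p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Classical per-gene baseline tests
#'
#' One-way ANOVA F (equal-variance) or Kruskal-Wallis rank statistic per
#' gene, as comparison methods for the replication harness.  Constant gene
#' rows get statistic 0 and p-value 1 (every observation is tied).
#'
#' @param es an [expression_set()].
#' @param method `"anova_f"` or `"kruskal_wallis"`.
#' @return data frame with per-gene `statistic` and `p_value`.
#' @export
baseline_scores <- function(es, method = c("anova_f", "kruskal_wallis")) {
  method <- match.arg(method)
  labels <- es$labels
  check_group_sizes(labels)
  one <- if (method == "anova_f") {
    function(row) {
      if (stats::var(row) == 0) return(c(0, 1))
      ht <- stats::oneway.test(row ~ labels, var.equal = TRUE)
      c(unname(ht$statistic), unname(ht$p.value))
    }
  } else {
    function(row) {
      if (stats::var(row) == 0) return(c(0, 1))
      ht <- stats::kruskal.test(row, labels)
      c(unname(ht$statistic), unname(ht$p.value))
    }
  }
  res <- t(apply(es$x, 1, one))
  data.frame(statistic = res[, 1], p_value = res[, 2],
             row.names = rownames(es$x))
}

#' Replicated simulation study of SAM vs robust SAM
#'
#' For each replicate: simulate a dataset from a [make_study_spec()] preset
#' (optionally with injected outliers), score it with each requested
#' method, and evaluate either by the top-N protocol (N = true DE count;
#' FDR, TPR, MER, AUC, pAUC) or by Delta-calling (called counts and
#' permutation FDR).  Under the top-N protocol `FDR = 1 - TPR` holds by
#' construction (both called and true sets have size N) and is asserted on
#' every replicate.
#'
#' @param study preset name for [make_study_spec()], or a spec list.
#' @param methods subset of `c("sam", "robust")`.
#' @param n_replicates number of independent replicates.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param pde overrides the preset's DE proportion (for the pde grid).
#' @param outlier `NULL` for clean data, or a list with `gene_fraction`,
#'   `outliers_per_gene` and optionally `z` / `genes`.
#' @param protocol `"topn"` or `"delta"`.
#' @param delta Delta threshold(s) for the `"delta"` protocol; a named
#'   vector applies a per-method Delta (names in `methods`).
#' @param beta_conf,n_permutations estimator and permutation settings.
#' @param fpr_max partial-AUC range.
#' @return long-format data frame: `replicate`, `method`, `metric`,
#'   `value`.
#' @export
replicate_study <- function(study, methods = c("sam", "robust"),
                            n_replicates = 50, seed = 1L, pde = NULL,
                            outlier = NULL,
                            protocol = c("topn", "delta"), delta = 0.2,
                            beta_conf = beta_config(),
                            s0_rule = "samr_cv",
                            n_permutations = 100L, fpr_max = 0.2) {
  protocol <- match.arg(protocol)
  spec <- if (is.character(study)) make_study_spec(study) else study
  methods <- match.arg(methods, c("sam", "robust"), several.ok = TRUE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max %/% 2, n_replicates)
  rows <- list()
  two_class <- length(spec$n_per_condition) == 2
  for (r in seq_len(n_replicates)) {
    sim <- simulate_study_replicate(spec, seed = rep_seeds[r], pde = pde,
                                    outlier = outlier)
    truth <- sim$truth$de
    n_de <- sum(truth)
    for (method in methods) {
      robust <- method == "robust"
      if (protocol == "topn") {
        sc <- sam_scores(sim$es, beta_conf,
                         sam_config(robust = robust, s0_rule = s0_rule,
                                    seed = rep_seeds[r]))
        stat <- ranking_statistic(sc$d, two_class)
        called <- topn_calls(sc$d, n_de, two_class = two_class)
        met <- confusion_metrics(confusion_counts(called, truth))
        stopifnot(isTRUE(all.equal(met[["FDR"]], 1 - met[["TPR"]])))
        op <- topn_metrics(sc$d, truth, n_de, two_class = two_class,
                           fpr_max = fpr_max)
        vals <- c(met[c("TPR", "TNR", "FPR", "FNR", "FDR", "MER", "power")],
                  AUC = auc(stat, truth),
                  pAUC = pauc(stat, truth, fpr_max),
                  AUC_top = unname(op["AUC"]),
                  pAUC_top = unname(op["pAUC"]))
      } else {
        d_m <- if (length(delta) > 1) delta[[method]] else delta
        res <- run_robust_sam(sim$es, beta_conf,
                              sam_config(robust = robust, delta = d_m,
                                         s0_rule = s0_rule,
                                         n_permutations = n_permutations,
                                         seed = rep_seeds[r]))
        called <- c(res$called_up, res$called_down)
        vals <- c(n_called = length(called),
                  n_true_called = sum(truth[called]),
                  n_false_called = sum(!truth[called]),
                  fdr_perm = res$fdr)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, method = method,
        metric = names(vals), value = unname(vals))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean and Monte-Carlo standard error per method and metric
#'
#' Summarises the long-format output of [replicate_study()]; `NA` metric
#' values (undefined rates) are dropped, with their count reported.
#'
#' @param results output of [replicate_study()].
#' @return data frame with `method`, `metric`, `mean`, `se`, `n`,
#'   `n_missing`.
#' @export
summarize_replicates <- function(results) {
  key <- interaction(results$method, results$metric, drop = TRUE)
  parts <- split(results, key)
  out <- do.call(rbind, lapply(parts, function(p) {
    v <- p$value
    ok <- !is.na(v)
    data.frame(method = p$method[1], metric = p$metric[1],
               mean = mean(v[ok]),
               se = stats::sd(v[ok]) / sqrt(sum(ok)),
               n = sum(ok), n_missing = sum(!ok))
  }))
  rownames(out) <- NULL
  out
}

#' Pairwise up/down detection across multiple conditions
#'
#' For every pair of conditions, scores the two-condition submatrix with
#' the (robust) SAM pipeline and Delta-calling, and counts called and
#' correctly-called up/downregulated genes against the true means.  A gene
#' is truly up (down) in pair (k, l) when its true mean in condition l is
#' greater (smaller) than in condition k.
#'
#' @param es an [expression_set()] with m > 2 conditions.
#' @param truth truth list from [simulate_dataset()] (uses `mu` and `de`).
#' @param robust robust or classical scoring.
#' @param delta Delta threshold for each pairwise calling.
#' @param beta_conf,n_permutations,seed pipeline settings.
#' @return data frame, one row per condition pair: called and correct
#'   up/down counts plus the true counts.
#' @export
pairwise_updown <- function(es, truth, robust = TRUE, delta = 0.2,
                            beta_conf = beta_config(),
                            n_permutations = 50L, seed = 1L) {
  m <- nlevels(es$labels)
  if (m < 3) stop("pairwise detection needs m > 2 conditions", call. = FALSE)
  pairs <- utils::combn(m, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    k <- pairs[1, p]; l <- pairs[2, p]
    keep <- as.integer(es$labels) %in% c(k, l)
    sub <- expression_set(es$x[, keep, drop = FALSE],
                          droplevels(es$labels[keep]))
    res <- run_robust_sam(sub, beta_conf,
                          sam_config(robust = robust, delta = delta,
                                     n_permutations = n_permutations,
                                     seed = seed))
    # r = mean_k - mean_l: called_down (negative side) means higher in l
    up_true <- which(truth$de & truth$mu[, l] > truth$mu[, k])
    down_true <- which(truth$de & truth$mu[, l] < truth$mu[, k])
    data.frame(pair = paste0(k, "vs", l),
               true_up = length(up_true), true_down = length(down_true),
               called_up = length(res$called_down),
               called_down = length(res$called_up),
               correct_up = sum(res$called_down %in% up_true),
               correct_down = sum(res$called_up %in% down_true))
  })
  do.call(rbind, rows)
}
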