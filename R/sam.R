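#' Configuration of the SAM scoring and permutation layer
#'
#' @param robust use the outlier-adaptive combined estimates (`TRUE`, the
#'   default) or plain classical estimates (`FALSE`, ordinary SAM).
#' @param s0_rule how the fuzz constant s0 is chosen from the per-gene
#'   standard deviations: `"percentile"` (the `s0_quantile`-th percentile of
#'   the s distribution) or `"samr_cv"` (scan percentiles 0, 5, ..., 100 and
#'   minimise the coefficient of variation of the median absolute deviation
#'   of the scores across s-quantile windows).
#' @param s0_quantile percentile (0-100) used by the `"percentile"` rule.
#' @param n_permutations number of label permutations B used for the
#'   expected order statistics and the permutation FDR.  When the data are
#'   two-class and the number of distinct label assignments is at most B,
#'   all assignments are enumerated instead.
#' @param delta nonnegative threshold on the deviation between observed and
#'   permutation-expected sorted scores that defines the called gene set.
#' @param seed integer seed controlling the permutation draw.
#' @return a list of class `sam_config`.
#' @export
sam_config <- function(robust = TRUE, s0_rule = c("percentile", "samr_cv"),
                       s0_quantile = 5, n_permutations = 100L,
                       delta = 0.2, seed = 1L) {
  s0_rule <- match.arg(s0_rule)
  stopifnot(n_permutations >= 1, all(delta >= 0),
            s0_quantile >= 0, s0_quantile <= 100)
  structure(list(robust = robust, s0_rule = s0_rule,
                 s0_quantile = s0_quantile,
                 n_permutations = as.integer(n_permutations),
                 delta = delta, seed = as.integer(seed)),
            class = "sam_config")
}

#' Two-class SAM numerator and denominator
#'
#' `r = mean1 - mean2` and the pooled fuzz-free denominator
#' `s = sqrt(a * ((n1 - 1) * var1 + (n2 - 1) * var2))` with
#' `a = (1/n1 + 1/n2) / (n1 + n2 - 2)`.
#'
#' @param theta a `theta_set` with exactly two conditions (from
#'   [combined_estimates()] or the classical fit).
#' @param counts integer vector `c(n1, n2)` of per-condition sample sizes.
#' @return list with per-gene vectors `r` and `s`.
#' @export
sam_two_class_stats <- function(theta, counts) {
  if (ncol(theta$mean) != 2 || length(counts) != 2) {
    stop("wrong arity: two-class statistic needs exactly 2 conditions",
         call. = FALSE)
  }
  a <- sum(1 / counts) / sum(counts - 1)
  r <- theta$mean[, 1] - theta$mean[, 2]
  s <- sqrt(a * ((counts[1] - 1) * theta$variance[, 1] +
                 (counts[2] - 1) * theta$variance[, 2]))
  list(r = unname(r), s = unname(s))
}

#' Multiclass SAM numerator and denominator
#'
#' Fisher-discriminant style numerator
#' `r = sqrt((sum(n_k) / prod(n_k)) * sum_k n_k * (mean_k - grand)^2)` with
#' the sample-size weighted grand mean, and the pooled denominator
#' `s = sqrt(a * sum_k (n_k - 1) * var_k)`, `a = sum(1/n_k) / sum(n_k - 1)`.
#' For two balanced classes `r` reduces to the absolute two-class numerator.
#'
#' @param theta a `theta_set` with m >= 2 conditions.
#' @param counts integer vector of the m per-condition sample sizes, each
#'   at least 2.
#' @return list with per-gene vectors `r` (nonnegative) and `s`.
#' @export
sam_multiclass_stats <- function(theta, counts) {
  m <- ncol(theta$mean)
  if (length(counts) != m || m < 2) {
    stop("wrong arity: need one sample count per condition (m >= 2)",
         call. = FALSE)
  }
  if (any(counts < 2)) {
    stop("insufficient data: every condition needs at least 2 samples",
         call. = FALSE)
  }
  grand <- as.numeric(theta$mean %*% counts) / sum(counts)
  between <- sweep(theta$mean, 1, grand)^2 %*% counts
  r <- sqrt(sum(counts) / prod(counts) * as.numeric(between))
  a <- sum(1 / counts) / sum(counts - 1)
  s <- sqrt(a * as.numeric(theta$variance %*% (counts - 1)))
  list(r = unname(r), s = unname(s))
}

#' Choose the SAM fuzz constant s0
#'
#' @param s nonnegative per-gene denominators.
#' @param r per-gene numerators; required by the `"samr_cv"` rule.
#' @param rule `"percentile"` (linear-interpolation percentile of `s`) or
#'   `"samr_cv"` (coefficient-of-variation minimising scan in the style of
#'   the original SAM software).
#' @param q percentile used by the `"percentile"` rule.
#' @return scalar s0 in `[0, max(s)]`.
#' @export
choose_s0 <- function(s, r = NULL, rule = c("percentile", "samr_cv"), q = 5) {
  rule <- match.arg(rule)
  if (length(s) == 0) stop("empty s vector", call. = FALSE)
  if (rule == "percentile") {
    return(unname(stats::quantile(s, q / 100, type = 7)))
  }
  if (is.null(r)) stop("samr_cv rule needs the numerators r", call. = FALSE)
  cand <- unname(stats::quantile(s, seq(0, 1, by = 0.05), type = 7))
  # windows of genes by s-quantile; cv of the mad of d across windows
  n_win <- min(100L, max(2L, floor(length(s) / 10)))
  win <- cut(rank(s, ties.method = "first"), breaks = n_win, labels = FALSE)
  cv <- vapply(cand, function(s0) {
    d <- r / (s + s0)
    mads <- tapply(d, win, stats::mad)
    stats::sd(mads) / abs(mean(mads))
  }, numeric(1))
  cand[which.min(cv)]
}

# scores for one labelling; theta selection mirrors the robust switch
score_labelling <- function(x, labels, robust, beta_conf, s0 = NULL) {
  es <- structure(list(x = x, labels = labels), class = "expr_set")
  counts <- condition_counts(labels)
  if (robust) {
    fits <- fit_all_groups(es, beta_conf)
    report <- flag_outliers(es, beta_conf, thetas = fits$robust)
    theta <- combined_estimates(es, report, beta_conf, fits = fits)
  } else {
    theta <- fit_all_groups_mle(es)
    report <- NULL
  }
  st <- if (length(counts) == 2) sam_two_class_stats(theta, counts)
        else sam_multiclass_stats(theta, counts)
  list(r = st$r, s = st$s, theta = theta, report = report)
}

# classical fit only (no robust iterations), for the non-robust path
fit_all_groups_mle <- function(es) {
  idx <- condition_index(es$labels)
  check_group_sizes(es$labels)
  G <- nrow(es$x)
  m <- length(idx)
  mean <- matrix(NA_real_, G, m, dimnames = list(rownames(es$x), names(idx)))
  variance <- mean
  for (k in seq_len(m)) {
    f <- mle_block(es$x[, idx[[k]], drop = FALSE])
    mean[, k] <- f$mean
    variance[, k] <- f$variance
  }
  theta_set(mean, variance, matrix("MLE", G, m), names(idx))
}

#' Per-gene SAM scores
#'
#' Computes `d = r / (s + s0)`.  With `config$robust = TRUE` the group
#' means and variances behind `r` and `s` come from [combined_estimates()]
#' (robust only where contamination was flagged); otherwise from the
#' classical fit.  Genes with `r = 0` and `s + s0 = 0` score 0.
#'
#' @param es an [expression_set()].
#' @param beta_conf a [beta_config()].
#' @param config a [sam_config()].
#' @return list with `d`, `r`, `s`, `s0`, the `theta` used, and the
#'   `outlier_report` (robust mode only).
#' @export
sam_scores <- function(es, beta_conf = beta_config(),
                       config = sam_config()) {
  sc <- score_labelling(es$x, es$labels, config$robust, beta_conf)
  s0 <- choose_s0(sc$s, sc$r,
                  rule = if (config$s0_rule == "samr_cv") "samr_cv" else "percentile",
                  q = config$s0_quantile)
  d <- safe_ratio(sc$r, sc$s + s0)
  list(d = d, r = sc$r, s = sc$s, s0 = s0,
       theta = sc$theta, report = sc$report)
}

safe_ratio <- function(num, den) {
  d <- num / den
  d[num == 0 & den == 0] <- 0
  d
}

# All two-class label assignments as an n x n_assign index matrix (columns =
# which samples take condition 1), or NULL when enumeration is infeasible.
enumerate_two_class <- function(labels, limit) {
  if (nlevels(labels) != 2) return(NULL)
  n <- length(labels)
  n1 <- sum(labels == levels(labels)[1])
  if (choose(n, n1) > limit) return(NULL)
  utils::combn(n, n1)
}

#' Permutation scores and expected order statistics
#'
#' Recomputes the SAM scores under permuted condition labels (the same
#' robust/classical mode as the observed scores; in robust mode the outlier
#' detection is re-run for every permuted labelling, since group membership
#' defines the group parameters).  The fuzz constant is held fixed at the
#' observed-data `s0`.  For two-class data with at most `n_permutations`
#' distinct label assignments, all assignments are enumerated; otherwise
#' `n_permutations` uniform random permutations are drawn (with replacement,
#' with a warning when the distinct assignments are fewer than requested).
#'
#' @param es an [expression_set()].
#' @param s0 fuzz constant from the observed fit.
#' @param beta_conf a [beta_config()].
#' @param config a [sam_config()]; `config$seed` makes the draw
#'   deterministic.
#' @return list with `expected` (mean of the i-th order statistic over
#'   permutations, length G) and `perm_scores` (B x G matrix of unsorted
#'   permuted scores).
#' @export
permutation_order_stats <- function(es, s0, beta_conf = beta_config(),
                                    config = sam_config()) {
  labels <- es$labels
  n <- length(labels)
  B <- config$n_permutations
  combs <- enumerate_two_class(labels, B)
  if (!is.null(combs)) {
    perms <- lapply(seq_len(ncol(combs)), function(b) {
      lab <- rep(levels(labels)[2], n)
      lab[combs[, b]] <- levels(labels)[1]
      factor(lab, levels = levels(labels))
    })
  } else {
    n_distinct <- exp(lfactorial(n) - sum(lfactorial(tabulate(labels))))
    if (n_distinct < B) {
      warning("fewer distinct label assignments (", round(n_distinct),
              ") than permutations requested; sampling with replacement")
    }
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(config$seed)
    perms <- replicate(B, labels[sample.int(n)], simplify = FALSE)
  }
  perm_scores <- t(vapply(perms, function(lab) {
    sc <- score_labelling(es$x, lab, config$robust, beta_conf)
    safe_ratio(sc$r, sc$s + s0)
  }, numeric(nrow(es$x))))
  expected <- colMeans(t(apply(perm_scores, 1, sort)))
  list(expected = expected, perm_scores = perm_scores)
}

get_rng_state <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Delta-thresholding of SAM scores
#'
#' Walks the sorted (expected, observed) score pairs of the quantile-quantile
#' plot.  On the upper side (nonnegative expected order statistics) the
#' upper cutoff is the smallest observed score whose deviation from its
#' expectation reaches `delta`; every gene scoring at or above it is called
#' upregulated.  The lower side is symmetric.
#'
#' @param d observed per-gene scores.
#' @param expected permutation-expected order statistics (sorted, length G).
#' @param delta nonnegative threshold.
#' @return list with `called_up` / `called_down` (integer gene indices),
#'   `cut_up` / `cut_low` (`Inf` / `-Inf` when no gene qualifies on that
#'   side), and the Q-Q table `qq` (expected, observed).
#' @export
delta_calling <- function(d, expected, delta) {
  stopifnot(length(d) == length(expected), delta >= 0)
  ord <- order(d)
  obs <- d[ord]
  up_ok <- expected >= 0 & (obs - expected) >= delta
  lo_ok <- expected <= 0 & (expected - obs) >= delta
  cut_up <- if (any(up_ok)) min(obs[up_ok]) else Inf
  cut_low <- if (any(lo_ok)) max(obs[lo_ok]) else -Inf
  list(called_up = which(d >= cut_up),
       called_down = which(d <= cut_low),
       cut_up = cut_up, cut_low = cut_low,
       qq = data.frame(expected = expected, observed = obs,
                       gene = ord))
}

#' Permutation estimate of the FDR among Delta-called genes
#'
#' The falsely-called count is the median over permutations of the number
#' of permuted scores beyond the cutoffs; the estimate is that count
#' divided by the number of called genes (0 when nothing is called).
#'
#' @param perm_scores B x G matrix of permuted scores.
#' @param cut_low,cut_up score cutoffs from [delta_calling()].
#' @param n_called number of genes called at those cutoffs.
#' @return scalar FDR estimate (pi0 is taken as 1).
#' @export
estimate_fdr <- function(perm_scores, cut_low, cut_up, n_called) {
  if (n_called == 0) return(0)
  false_calls <- apply(perm_scores, 1, function(z) {
    sum(z >= cut_up | z <= cut_low)
  })
  stats::median(false_calls) / n_called
}

#' Run the full (robust) SAM pipeline
#'
#' Estimation, outlier flagging, scoring, permutation expected order
#' statistics, Delta-calling and permutation FDR, in one call.  With
#' `config$robust = FALSE` this is ordinary SAM; with the default robust
#' mode, gene-condition groups flagged as outlier-contaminated use minimum
#' beta-divergence estimates (on clean data no group is flagged and the two
#' modes coincide).
#'
#' @param es an [expression_set()].
#' @param beta_conf a [beta_config()].
#' @param config a [sam_config()].
#' @return object of class `sam_result`: scores (`d`, `r`, `s`, `s0`),
#'   `expected` order statistics, `perm_scores`, `called_up`/`called_down`,
#'   cutoffs, `fdr`, the `outlier_report` (robust mode), `theta`, and the
#'   configurations used.
#' @examples
#' sim <- simulate_dataset(G = 60, n_per_condition = c(4, 4), pde = 0.2,
#'                         sigma2 = 0.1, seed = 1)
#' res <- run_robust_sam(sim$es, config = sam_config(n_permutations = 20))
#' res
#' @export
run_robust_sam <- function(es, beta_conf = beta_config(),
                           config = sam_config()) {
  sc <- sam_scores(es, beta_conf, config)
  perm <- permutation_order_stats(es, sc$s0, beta_conf, config)
  call <- delta_calling(sc$d, perm$expected, config$delta)
  n_called <- length(call$called_up) + length(call$called_down)
  fdr <- estimate_fdr(perm$perm_scores, call$cut_low, call$cut_up, n_called)
  structure(list(d = sc$d, r = sc$r, s = sc$s, s0 = sc$s0,
                 expected = perm$expected, perm_scores = perm$perm_scores,
                 called_up = call$called_up, called_down = call$called_down,
                 cut_up = call$cut_up, cut_low = call$cut_low,
                 qq = call$qq, fdr = fdr,
                 report = sc$report, theta = sc$theta,
                 beta_config = beta_conf, config = config),
            class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat("sam_result (", if (x$config$robust) "robust" else "classical",
      " mode): ", length(x$d), " genes, s0 = ", format(x$s0, digits = 4),
      "\n", sep = "")
  if (!is.null(x$report)) {
    cat("  lambda = ", format(x$report$lambda, digits = 4), ", ",
        sum(x$report$cell_flags), " flagged cells\n", sep = "")
  }
  cat("  Delta = ", x$config$delta, ": ", length(x$called_up), " up, ",
      length(x$called_down), " down called; est. FDR = ",
      format(x$fdr, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Ranking statistic used for top-N evaluation
#'
#' `abs(d)` for two-class scores (signed d), `d` itself for multiclass
#' scores (already nonnegative).
#'
#' @param d per-gene scores.
#' @param two_class whether the scores are signed two-class scores.
#' @return nonnegative ranking statistic.
#' @export
ranking_statistic <- function(d, two_class) {
  if (two_class) abs(d) else d
}
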