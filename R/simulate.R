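#' Simulate an expression matrix with known differential-expression truth
#'
#' Additive Gaussian model: `x[i, j] = mu[i, k(j)] + eps[i, j]`,
#' `eps ~ N(0, sigma2)`.  Equally expressed (EE) genes share a single mean
#' drawn uniformly from `(mean_low, mean_high)` across all conditions;
#' differentially expressed (DE) genes draw an independent mean from the
#' same range per condition (or one mean per block of a condition
#' partition, when `patterns` is supplied).  Because DE means are
#' independent draws, effect sizes form a continuum down to zero: some DE
#' genes are intrinsically hard, which is what keeps the power of any test
#' below 1 on these data.
#'
#' @param G number of genes.
#' @param n_per_condition integer vector of per-condition sample sizes
#'   (length m >= 2).
#' @param pde proportion of DE genes in `[0, 1]`; `round(G * pde)` genes
#'   (the first ones, positions drawn at random) are DE.
#' @param mean_low,mean_high bounds of the uniform mean range.
#' @param sigma2 noise variance (> 0).
#' @param balance_directions two-class only: force exactly half of the DE
#'   genes to be upregulated in condition 2 (`mu2 > mu1`) and half
#'   downregulated, by swapping the two draws where needed.
#' @param patterns optional list of condition partitions for DE genes with
#'   m > 2, e.g. `list(list(1, 2:4), list(1:2, 3:4))`: each DE gene is
#'   assigned one partition (cycling through the list) and draws one mean
#'   per block.
#' @param seed integer seed; the same seed reproduces the dataset bit for
#'   bit.
#' @return list with `es` (an [expression_set()]) and `truth`: `de`
#'   (logical per gene), `direction` (+1 up / -1 down in condition 2,
#'   two-class DE genes only, else NA), `pattern` (pattern index per DE
#'   gene when `patterns` is used), `mu` (G x m matrix of true means), and
#'   `outlier_cells` (empty data frame; filled by [inject_outliers()]).
#' @export
simulate_dataset <- function(G, n_per_condition, pde,
                             mean_low = 3, mean_high = 5, sigma2 = 0.3,
                             balance_directions = FALSE, patterns = NULL,
                             seed = 1L) {
  stopifnot(G >= 1, length(n_per_condition) >= 2, all(n_per_condition >= 2),
            pde >= 0, pde <= 1, mean_low < mean_high, sigma2 > 0)
  m <- length(n_per_condition)
  n <- sum(n_per_condition)
  n_de <- round(G * pde)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  de_idx <- sort(sample.int(G, n_de))
  de <- logical(G)
  de[de_idx] <- TRUE
  runif_range <- function(k) stats::runif(k, mean_low, mean_high)
  mu <- matrix(runif_range(G), G, m)  # EE genes: one shared mean
  direction <- rep(NA_integer_, G)
  pattern <- rep(NA_integer_, G)
  if (n_de > 0) {
    if (is.null(patterns)) {
      mu[de_idx, ] <- matrix(runif_range(n_de * m), n_de, m)
      if (m == 2) {
        dir_i <- sign(mu[de_idx, 2] - mu[de_idx, 1])
        if (balance_directions) {
          want_up <- rep(c(TRUE, FALSE), length.out = n_de)
          flip <- (dir_i > 0) != want_up
          mu[de_idx[flip], ] <- mu[de_idx[flip], 2:1]
          dir_i <- sign(mu[de_idx, 2] - mu[de_idx, 1])
        }
        direction[de_idx] <- as.integer(dir_i)
      }
    } else {
      if (m < 3) stop("patterns need m > 2 conditions", call. = FALSE)
      pattern[de_idx] <- rep(seq_along(patterns), length.out = n_de)
      for (p in seq_along(patterns)) {
        blocks <- patterns[[p]]
        if (!setequal(unlist(blocks), seq_len(m))) {
          stop("pattern ", p, " is not a partition of the conditions",
               call. = FALSE)
        }
        rows <- de_idx[pattern[de_idx] == p]
        for (i in rows) {
          for (b in blocks) mu[i, unlist(b)] <- runif_range(1)
        }
      }
    }
  }
  labels <- factor(rep(seq_len(m), n_per_condition))
  x <- mu[, as.integer(labels), drop = FALSE] +
    matrix(stats::rnorm(G * n, 0, sqrt(sigma2)), G, n)
  rownames(x) <- paste0("gene", seq_len(G))
  colnames(x) <- paste0("sample", seq_len(n))
  es <- expression_set(x, paste0("cond", as.integer(labels)))
  truth <- list(de = de, direction = direction, pattern = pattern, mu = mu,
                outlier_cells = data.frame(gene = integer(0),
                                           sample = integer(0)))
  list(es = es, truth = truth)
}

#' Inject outlying expression values
#'
#' Picks `floor(gene_fraction * G)` genes uniformly at random and replaces
#' `outliers_per_gene` randomly chosen cells in each with
#' `z + 2 * max(row before injection)`, so every injected value strictly
#' dominates its row.  The total injected cell count may not exceed
#' `max_cell_fraction` of all cells.
#'
#' @param es an [expression_set()].
#' @param gene_fraction fraction of genes to contaminate.
#' @param outliers_per_gene outlying cells per contaminated gene (1 or 2).
#' @param z offset of the replacement value; any fixed value in (5, 10),
#'   default the midpoint 7.5.
#' @param max_cell_fraction cap on the fraction of all cells replaced.
#' @param genes optional integer vector restricting the candidate genes
#'   (e.g. true DE genes only); the fraction still refers to all genes.
#' @param seed integer seed.
#' @return list with `es` (contaminated copy) and `outlier_cells`
#'   (data frame of gene/sample indices of every replaced cell).
#' @export
inject_outliers <- function(es, gene_fraction, outliers_per_gene = 1L,
                            z = 7.5, max_cell_fraction = 0.05,
                            genes = NULL, seed = 1L) {
  stopifnot(gene_fraction >= 0, gene_fraction <= 1,
            outliers_per_gene >= 1)
  G <- nrow(es$x)
  n <- ncol(es$x)
  n_genes <- floor(gene_fraction * G)
  n_cells <- n_genes * outliers_per_gene
  if (n_cells > max_cell_fraction * G * n) {
    stop("validation error: ", n_cells, " outlier cells exceed the cap of ",
         max_cell_fraction * 100, "% of all cells", call. = FALSE)
  }
  if (outliers_per_gene > n) {
    stop("validation error: more outliers per gene than samples", call. = FALSE)
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  pool <- if (is.null(genes)) seq_len(G) else genes
  if (n_genes > length(pool)) {
    stop("validation error: not enough candidate genes", call. = FALSE)
  }
  target <- sample(pool, n_genes)
  x <- es$x
  cells <- data.frame(gene = rep(target, each = outliers_per_gene),
                      sample = NA_integer_)
  row_pos <- 1L
  for (g in target) {
    j <- sample.int(n, outliers_per_gene)
    x[g, j] <- z + 2 * max(es$x[g, ])
    cells$sample[seq(row_pos, length.out = outliers_per_gene)] <- j
    row_pos <- row_pos + outliers_per_gene
  }
  out <- es
  out$x <- x
  list(es = out, outlier_cells = cells)
}

#' Preset configurations of the simulation studies
#'
#' Returns the generator settings of the package's three benchmark designs:
#'
#' * `study1`: G = 1000, two conditions of 10 samples, 100 DE genes (50 up,
#'   50 down), means Uniform(3, 5), `sigma2 = 0.3`; evaluated by
#'   Delta-calling.
#' * `study2_small` / `study2_large`: G = 10000, two conditions of 3 / 25
#'   samples, pde grid (0.02, 0.04, 0.06, 0.08, 0.1), `sigma2 = 0.3`;
#'   evaluated by top-N ranking.
#' * `study3_small` / `study3_large`: G = 10000, four conditions of 3 / 25
#'   samples, pde = 0.02, `sigma2 = 0.1`.
#' * `study3_patterns`: G = 1000, four conditions of 3, 300 patterned DE
#'   genes, `sigma2 = 0.1`; evaluated by pairwise up/down detection.
#'
#' Every preset carries the outlier grid `gene_fraction` in (0.1, 0.2, 0.5)
#' by `outliers_per_gene` in (1, 2); settings that would break the 5% cell
#' cap are rejected by [inject_outliers()] at run time.
#'
#' @param study preset name.
#' @return list with the `simulate_dataset()` arguments (`G`,
#'   `n_per_condition`, `pde` or `pde_grid`, `mean_low`, `mean_high`,
#'   `sigma2`, plus preset extras) and `outlier_grid` (data frame).
#' @export
make_study_spec <- function(study = c("study1", "study2_small", "study2_large",
                                      "study3_small", "study3_large",
                                      "study3_patterns")) {
  study <- match.arg(study)
  grid <- expand.grid(gene_fraction = c(0.10, 0.20, 0.50),
                      outliers_per_gene = c(1L, 2L))
  base <- list(mean_low = 3, mean_high = 5, outlier_grid = grid, study = study)
  spec <- switch(study,
    study1 = list(G = 1000L, n_per_condition = c(10L, 10L), pde = 0.1,
                  sigma2 = 0.3, balance_directions = TRUE, delta = 0.2),
    study2_small = list(G = 10000L, n_per_condition = c(3L, 3L), pde = 0.02,
                        pde_grid = c(0.02, 0.04, 0.06, 0.08, 0.1),
                        sigma2 = 0.3),
    study2_large = list(G = 10000L, n_per_condition = c(25L, 25L), pde = 0.02,
                        pde_grid = c(0.02, 0.04, 0.06, 0.08, 0.1),
                        sigma2 = 0.3),
    study3_small = list(G = 10000L, n_per_condition = rep(3L, 4), pde = 0.02,
                        sigma2 = 0.1),
    study3_large = list(G = 10000L, n_per_condition = rep(25L, 4), pde = 0.02,
                        sigma2 = 0.1),
    study3_patterns = list(G = 1000L, n_per_condition = rep(3L, 4), pde = 0.3,
                           sigma2 = 0.1,
                           patterns = list(list(1, 2:4), list(1:2, 3:4),
                                           list(1:3, 4), list(1, 2, 3:4)))
  )
  c(spec, base)
}

# simulate one replicate of a study spec (optionally contaminated)
simulate_study_replicate <- function(spec, seed, pde = NULL,
                                     outlier = NULL) {
  sim <- simulate_dataset(
    G = spec$G, n_per_condition = spec$n_per_condition,
    pde = if (is.null(pde)) spec$pde else pde,
    mean_low = spec$mean_low, mean_high = spec$mean_high,
    sigma2 = spec$sigma2,
    balance_directions = isTRUE(spec$balance_directions),
    patterns = spec$patterns, seed = seed)
  if (!is.null(outlier)) {
    inj <- inject_outliers(sim$es, gene_fraction = outlier$gene_fraction,
                           outliers_per_gene = outlier$outliers_per_gene,
                           z = if (is.null(outlier$z)) 7.5 else outlier$z,
                           genes = outlier$genes, seed = seed + 500000L)
    sim$es <- inj$es
    sim$truth$outlier_cells <- inj$outlier_cells
  }
  sim
}
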