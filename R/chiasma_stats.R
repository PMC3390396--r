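#' Chiasmata implied by a metaphase I bivalent shape
#'
#' Shape-based scoring of chiasma number: a pair of univalents carries no
#' chiasma, a rod bivalent one, a ring bivalent two. The rule caps a bivalent
#' at two chiasmata, so it slightly underestimates true crossover numbers on
#' bivalents bearing three or more; the simulator keeps the true event counts
#' (`n_class1`, `n_class2`) alongside the shape so the size of that
#' underestimate is itself measurable.
#'
#' @param shape_class Character vector with values in
#'   `c("univalent_pair", "rod", "ring")`.
#' @return Integer vector of chiasma counts in `{0, 1, 2}`.
#' @export
#' @examples
#' chiasmata_from_shape(c("ring", "rod", "univalent_pair"))
chiasmata_from_shape <- function(shape_class) {
  scores <- c(univalent_pair = 0L, rod = 1L, ring = 2L)
  bad <- setdiff(unique(shape_class), names(scores))
  if (length(bad))
    stop("unknown shape class: ", paste(bad, collapse = ", "))
  unname(scores[shape_class])
}

#' Per-cell chiasma frequency and bivalent count
#'
#' Sums the shape-based chiasma scores of all homolog pairs of one cell and
#' counts how many of them are true bivalents (rod or ring; univalent pairs
#' are not connected and do not count).
#'
#' @param records Data frame of one cell's homolog pairs with columns
#'   `cell_id` and `shape_class`.
#' @return List with `cell_id`, `chiasma_count`, `bivalent_count`.
#' @export
#' @examples
#' rec <- data.frame(cell_id = "c1",
#'                   shape_class = c(rep("rod", 2), rep("ring", 10)))
#' cell_chiasma_frequency(rec)  # 22 chiasmata, 12 bivalents
cell_chiasma_frequency <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("cell_id", "shape_class") %in% names(records)))
  if (nrow(records) == 0L) stop("empty cell: no bivalent records")
  if (length(unique(records$cell_id)) != 1L)
    stop("all records must share one cell_id")
  sc <- chiasmata_from_shape(records$shape_class)
  list(cell_id = records$cell_id[[1]],
       chiasma_count = sum(sc),
       bivalent_count = sum(records$shape_class %in% c("rod", "ring")))
}

#' Per-cell chiasma counts for a whole cells table
#'
#' Applies [cell_chiasma_frequency()] to every cell of a cells table (the
#' dialect written by [simulate_meiosis()] or supplied by the user).
#'
#' @param cells Data frame with columns `cell_id`, `shape_class`, and
#'   optionally `genotype`.
#' @return Data frame with one row per cell: `cell_id`, `genotype` (if
#'   present), `chiasma_count`, `bivalent_count`.
#' @export
chiasma_counts <- function(cells) {
  stopifnot(is.data.frame(cells),
            all(c("cell_id", "shape_class") %in% names(cells)))
  per_cell <- lapply(split(cells, cells$cell_id), cell_chiasma_frequency)
  out <- data.frame(
    cell_id = vapply(per_cell, `[[`, "", "cell_id"),
    chiasma_count = vapply(per_cell, `[[`, integer(1), "chiasma_count"),
    bivalent_count = vapply(per_cell, `[[`, integer(1), "bivalent_count"),
    stringsAsFactors = FALSE, row.names = NULL)
  if ("genotype" %in% names(cells)) {
    geno <- vapply(split(as.character(cells$genotype), cells$cell_id),
                   `[[`, "", 1L)
    out$genotype <- geno[out$cell_id]
    out <- out[c("cell_id", "genotype", "chiasma_count", "bivalent_count")]
  }
  out
}

#' Mean, SD and n of per-cell chiasma counts
#'
#' @param counts Numeric vector of per-cell chiasma counts (or a data frame
#'   from [chiasma_counts()], whose `chiasma_count` column is used).
#' @return List with `mean`, `sd` (sample SD), `n`.
#' @export
#' @examples
#' summarize_genotype(c(0, 2))  # mean 1, sd sqrt(2)
summarize_genotype <- function(counts) {
  if (is.data.frame(counts)) counts <- counts$chiasma_count
  counts <- as.numeric(counts)
  if (length(counts) < 2L)
    stop("need at least two cells to summarise a genotype")
  list(mean = mean(counts), sd = sd(counts), n = length(counts))
}

#' Poisson goodness of fit for per-cell chiasma counts
#'
#' Chi-square test of the hypothesis that per-cell counts are Poisson with
#' unknown mean. The rate is estimated by the sample mean; expected
#' frequencies over the integer categories `0, 1, ..., max` (with an open
#' upper tail) are compared with observed frequencies after pooling adjacent
#' categories inward from both tails until every expected frequency reaches
#' `min_expected`. Degrees of freedom are `categories - 2` (one lost to the
#' total, one to the estimated mean); published analyses sometimes use other
#' binning conventions, so `force_df` lets the p-value be computed at a
#' stated df.
#'
#' @param counts Non-negative integer vector of per-cell counts.
#' @param min_expected Pooling threshold for expected category frequencies
#'   (default 1, keeping many categories at typical cytological sample
#'   sizes).
#' @param force_df Optional df override used only for the p-value.
#' @return Object of class `poisson_gof`: `chi2`, `df`, `p_value`, `lambda`,
#'   `bin_edges` (category lower bounds after pooling), `n`.
#' @export
#' @examples
#' set.seed(1)
#' poisson_gof(rpois(130, 6.5))
poisson_gof <- function(counts, min_expected = 1, force_df = NULL) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L) stop("need at least two counts")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  n <- length(counts)
  lambda <- mean(counts)
  if (sd(counts) == 0 && n < 30)
    warning("degenerate count distribution: all counts identical")
  kmax <- max(counts)
  cats <- 0:kmax
  obs <- tabulate(counts + 1L, nbins = kmax + 1L)
  expp <- dpois(cats, lambda)
  expp[length(expp)] <- expp[length(expp)] + ppois(kmax, lambda, lower.tail = FALSE)
  expn <- n * expp

  # pool inward from both tails until each expected count >= min_expected
  lower <- 1L; upper <- length(expn)
  repeat {
    changed <- FALSE
    if (upper - lower >= 1L && expn[lower] < min_expected) {
      expn[lower + 1L] <- expn[lower + 1L] + expn[lower]
      obs[lower + 1L] <- obs[lower + 1L] + obs[lower]
      lower <- lower + 1L; changed <- TRUE
    }
    if (upper - lower >= 1L && expn[upper] < min_expected) {
      expn[upper - 1L] <- expn[upper - 1L] + expn[upper]
      obs[upper - 1L] <- obs[upper - 1L] + obs[upper]
      upper <- upper - 1L; changed <- TRUE
    }
    if (!changed) break
  }
  keep <- lower:upper
  obs <- obs[keep]; expn <- expn[keep]
  df <- length(keep) - 2L
  if (df < 1L)
    stop("fewer than three categories after pooling; cannot test")
  chi2 <- sum((obs - expn)^2 / expn)
  p_df <- if (is.null(force_df)) df else as.integer(force_df)
  structure(
    list(chi2 = chi2, df = p_df,
         p_value = pchisq(chi2, p_df, lower.tail = FALSE),
         lambda = lambda, bin_edges = cats[keep], n = n),
    class = "poisson_gof")
}

#' @export
print.poisson_gof <- function(x, ...) {
  cat(sprintf(
    "Poisson goodness of fit: chi2[%d] = %.3g, p = %.4g (lambda-hat = %.3g, n = %d)\n",
    x$df, x$chi2, x$p_value, x$lambda, x$n))
  invisible(x)
}

#' Pooled two-sample t test from summary statistics
#'
#' Classical equal-variance two-sample t test computed from group means,
#' sample SDs, and sizes, as used to compare per-cell chiasma frequencies
#' between genotypes reported as mean +/- SD. The pooled test has
#' `df = n1 + n2 - 2`; `welch = TRUE` gives the unequal-variance alternative
#' with Satterthwaite df.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param welch Use the Welch (unequal-variance) test instead of the pooled
#'   test.
#' @return Object of class `t_test_summary`: `t`, `df`, `p_value` (two-sided).
#' @export
#' @examples
#' pooled_t_test(6.5, 2.1, 130, 2.1, 1.3, 121)
pooled_t_test <- function(mean1, sd1, n1, mean2, sd2, n2, welch = FALSE) {
  for (v in list(mean1, sd1, n1, mean2, sd2, n2))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("all summary statistics must be single finite numbers")
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("SDs must be >= 0")
  if (sd1 == 0 && sd2 == 0 && mean1 == mean2)
    stop("t statistic undefined: both SDs zero and means equal")
  if (welch) {
    se2_1 <- sd1^2 / n1; se2_2 <- sd2^2 / n2
    se <- sqrt(se2_1 + se2_2)
    df <- (se2_1 + se2_2)^2 / (se2_1^2 / (n1 - 1) + se2_2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  tval <- (mean1 - mean2) / se
  structure(
    list(t = tval, df = df,
         p_value = 2 * pt(abs(tval), df, lower.tail = FALSE),
         method = if (welch) "welch" else "pooled"),
    class = "t_test_summary")
}

#' @export
print.t_test_summary <- function(x, ...) {
  cat(sprintf("Two-sample t (%s): t[%s] = %.4g, two-sided p = %.4g\n",
              x$method,
              if (x$df == round(x$df)) format(x$df) else sprintf("%.1f", x$df),
              x$t, x$p_value))
  invisible(x)
}

#' Percentage of chiasmata retained in a mutant
#'
#' `100 * mutant_mean / wt_mean`; e.g. a mutant mean of 6.5 against a
#' wild-type mean of 20.7 retains about 31% of chiasmata.
#'
#' @param mutant_mean,wt_mean Per-cell chiasma means; `wt_mean > 0`.
#' @return Percentage.
#' @export
retention_percent <- function(mutant_mean, wt_mean) {
  if (!is.numeric(wt_mean) || wt_mean <= 0)
    stop("'wt_mean' must be > 0")
  100 * mutant_mean / wt_mean
}

#' Fraction of crossovers formed by the interference-sensitive pathway
#'
#' `100 * class1_marker_mean / total_co_mean`: the per-cell mean count of
#' class I marker foci over the total crossover mean.
#'
#' @param class1_marker_mean Mean class I marker focus count per cell.
#' @param total_co_mean Mean total crossovers per cell, > 0.
#' @return Percentage.
#' @export
class1_fraction <- function(class1_marker_mean, total_co_mean) {
  if (!is.numeric(total_co_mean) || total_co_mean <= 0)
    stop("'total_co_mean' must be > 0")
  100 * class1_marker_mean / total_co_mean
}

#' Fold change between two focus-count means
#'
#' @param numerator_mean,denominator_mean Means; denominator > 0.
#' @return Ratio (e.g. 36.2 / 24.5 = 1.48, an ~1.5-fold increase).
#' @export
fold_change <- function(numerator_mean, denominator_mean) {
  if (!is.numeric(denominator_mean) || denominator_mean <= 0)
    stop("'denominator_mean' must be > 0")
  numerator_mean / denominator_mean
}
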