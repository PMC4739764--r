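#' Mann-Whitney U test (two-sided), exact for small samples
#'
#' U is computed from midranks.  The two-sided p-value is the probability,
#' under the permutation null, that |U - n_a n_b / 2| is at least as large
#' as observed (the U distribution is symmetric about n_a n_b / 2 under
#' exchangeability, with or without ties):
#' \itemize{
#'   \item tie-free data: exact tail from the null U distribution
#'     (`pwilcox`), equivalent to full enumeration;
#'   \item tied data with choose(n_a + n_b, n_a) <= 2e5 (which covers every
#'     split of a combined sample of 20): exact enumeration of all group
#'     assignments with midranks;
#'   \item otherwise: normal approximation with tie correction and
#'     continuity correction.
#' }
#'
#' @param group_a,group_b numeric vectors (non-empty)
#' @return object of class `mt_stat_result`: `test`, `statistic` (U of
#'   group_a), `p_value`, `n` (c(n_a, n_b)), `method` ("exact" or
#'   "normal_approx")
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop_f("both groups must be non-empty")
  na <- length(group_a); nb <- length(group_b); n <- na + nb
  all_v <- c(group_a, group_b)
  rk <- rank(all_v)                       # midranks
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  ties <- any(duplicated(all_v))

  if (!ties) {
    # exact tail of the null U distribution; symmetric about mu
    p <- if (U < mu) 2 * stats::pwilcox(U, na, nb)
         else if (U > mu) 2 * (1 - stats::pwilcox(U - 1, na, nb))
         else 1
    p <- min(1, p)
    method <- "exact"
  } else if (choose(n, na) <= 2e5) {
    cmb <- utils::combn(n, na)
    Uall <- colSums(matrix(rk[cmb], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(Uall - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    tie_tab <- table(all_v)
    sig2 <- na * nb / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  structure(list(test = "mann_whitney_u", statistic = U, p_value = p,
                 n = c(na, nb), method = method),
            class = "mt_stat_result")
}

#' Fisher's exact test on a 2 x 2 table (two-sided)
#'
#' Two-sided p-value as the sum of hypergeometric probabilities, over all
#' tables with the observed margins, of tables no more probable than the
#' observed one.
#'
#' @param table 2 x 2 matrix of non-negative integer counts with at least
#'   one positive margin
#' @return `mt_stat_result` with `statistic` = odds ratio (sample)
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop_f("need a 2 x 2 table")
  if (any(table < 0) || any(table != round(table)))
    stop_f("table entries must be non-negative integers")
  if (sum(table) == 0) stop_f("at least one margin must be positive")
  m <- sum(table[1, ])       # row 1 total
  nn <- sum(table[2, ])      # row 2 total
  kk <- sum(table[, 1])      # column 1 total
  x <- table[1, 1]
  lo <- max(0, kk - nn); hi <- min(kk, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, nn, kk)
  p_obs <- stats::dhyper(x, m, nn, kk)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  orat <- if (table[1, 2] * table[2, 1] > 0)
    (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1]) else Inf
  structure(list(test = "fisher_exact_2x2", statistic = orat,
                 p_value = min(1, p), n = c(m + nn),
                 method = "exact"), class = "mt_stat_result")
}

#' @export
print.mt_stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, two-sided p = %.4g (%s; n = %s)\n",
              x$test, x$statistic, x$p_value, x$method,
              paste(x$n, collapse = ", ")))
  invisible(x)
}

#' Assemble a condition-comparison report
#'
#' Writes, under `out_dir`: `condition_table.csv` (per-condition mean
#' fraction +/- s.d. with axon and comet totals), `stats.csv` (one row per
#' comparison), optionally `phenotype_counts.csv`, and a bar plot of the
#' per-condition plus-end-out fractions with s.d. error bars.  All tables
#' are regenerable from the CSV outputs alone; rerunning on identical
#' inputs writes byte-identical tables.
#'
#' @param condition_summaries named list: condition -> data.frame from
#'   [summarize_polarity()] (rows = axons)
#' @param stats named list: comparison label -> `mt_stat_result`
#' @param phenotype_counts optional data.frame of per-condition phenotype
#'   counts
#' @param out_dir output directory (created if needed)
#' @return invisible character vector of files written
#' @export
build_report <- function(condition_summaries, stats = list(),
                         phenotype_counts = NULL, out_dir) {
  if (length(condition_summaries) == 0)
    stop_f("missing upstream output: no condition summaries")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()

  cond <- do.call(rbind, lapply(names(condition_summaries), function(nm) {
    agg <- aggregate_condition(condition_summaries[[nm]])
    cbind(condition = nm, agg)
  }))
  f <- file.path(out_dir, "condition_table.csv")
  utils::write.csv(cond, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  if (length(stats)) {
    st <- do.call(rbind, lapply(names(stats), function(nm) {
      s <- stats[[nm]]
      data.frame(comparison = nm, test = s$test, statistic = s$statistic,
                 p_value = s$p_value, method = s$method,
                 n = paste(s$n, collapse = "|"))
    }))
    f <- file.path(out_dir, "stats.csv")
    utils::write.csv(st, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  if (!is.null(phenotype_counts)) {
    f <- file.path(out_dir, "phenotype_counts.csv")
    utils::write.csv(phenotype_counts, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }

  pl <- ggplot2::ggplot(cond, ggplot2::aes(x = condition, y = mean_f_out)) +
    ggplot2::geom_col(fill = "grey35", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(0, mean_f_out - sd_f_out),
      ymax = pmin(1, mean_f_out + sd_f_out)), width = 0.15) +
    ggplot2::labs(y = "fraction of comets plus-end-out (per-axon mean)",
                  x = NULL) +
    ggplot2::ylim(0, 1) + ggplot2::theme_classic()
  f <- file.path(out_dir, "polarity_fractions.pdf")
  suppressWarnings(ggplot2::ggsave(f, pl, width = 4, height = 3.2))
  files <- c(files, f)
  invisible(files)
}
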