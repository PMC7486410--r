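#' Matched-subsampling bootstrap comparison of tagged vs untagged cells
#'
#' Tests whether a statistic of the tagged cells (e.g. the proportion of
#' modulated cells, or a mean parameter) exceeds what random untagged cells
#' would give. Each of `n_reps` surrogate draws samples, within every field
#' of view, as many untagged cells (without replacement) as there are tagged
#' cells in that FOV, and recomputes the statistic. The observed value is
#' significant when it falls above the 95th percentile of the surrogate
#' distribution (upper tail; the two-sided variant uses the 2.5th/97.5th).
#'
#' @param values per-cell values: logical for `statistic = "proportion"`,
#'   numeric for `statistic = "mean"`.
#' @param tags logical per-cell vector, TRUE for tagged cells.
#' @param fov_ids per-cell field-of-view identifier.
#' @param statistic `"proportion"` or `"mean"`.
#' @param n_reps surrogate draws.
#' @param two_sided use the 2.5/97.5 percentile rule instead of the upper
#'   95th.
#' @param seed optional integer seed.
#' @return object of class `group_comparison`: `observed`, `surrogate`
#'   (length `n_reps`), empirical `p` (upper-tail fraction of surrogates >=
#'   observed), percentile `thresholds`, `significant`.
#' @export
matched_subsample_test <- function(values, tags, fov_ids,
                                   statistic = c("proportion", "mean"),
                                   n_reps = 1000, two_sided = FALSE,
                                   seed = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(length(values) == length(tags),
            length(values) == length(fov_ids))
  tags <- as.logical(tags)
  if (!any(tags)) stop("no tagged cell")
  stat_fun <- mean   # proportion = mean of logicals
  vals <- if (statistic == "proportion") as.logical(values) else
    as.numeric(values)

  fovs <- unique(fov_ids[tags])
  pools <- list(); k <- integer()
  for (f in fovs) {
    kf <- sum(tags & fov_ids == f)
    pool <- which(!tags & fov_ids == f)
    if (length(pool) < kf) {
      stop(sprintf("FOV '%s' has %d tagged cells but only %d untagged cells",
                   f, kf, length(pool)))
    }
    pools[[length(pools) + 1L]] <- pool
    k <- c(k, kf)
  }
  observed <- stat_fun(vals[tags])
  surrogate <- with_seed(seed, {
    vapply(seq_len(n_reps), function(rep) {
      idx <- unlist(lapply(seq_along(pools), function(j) {
        p <- pools[[j]]
        p[sample.int(length(p), k[j])]
      }))
      stat_fun(vals[idx])
    }, numeric(1))
  })
  thresholds <- if (two_sided) {
    quantile(surrogate, c(0.025, 0.975), names = FALSE)
  } else {
    quantile(surrogate, 0.95, names = FALSE)
  }
  significant <- if (two_sided) {
    observed > thresholds[2] || observed < thresholds[1]
  } else {
    observed > thresholds
  }
  structure(list(statistic = statistic, observed = observed,
                 surrogate = surrogate, p = mean(surrogate >= observed),
                 thresholds = thresholds, significant = significant,
                 two_sided = two_sided, n_reps = n_reps,
                 n_tagged = sum(tags)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s: observed %.4g vs surrogate %s (%d reps): %s (p = %.3g)\n",
    x$statistic, x$observed,
    paste(sprintf("%.4g", x$thresholds), collapse = "/"),
    x$n_reps, if (x$significant) "significant" else "not significant", x$p))
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric enumeration at fixed margins: the two-sided p-value
#' is the sum of the probabilities of all tables whose probability does not
#' exceed that of the observed table (the convention of most statistical
#' software). A table with a zero margin carries no information and returns
#' p = 1 by convention.
#'
#' @param x 2x2 matrix of non-negative integer counts.
#' @return list of class `fisher_exact`: `p.value`, `odds_ratio` (sample
#'   odds ratio), `table`.
#' @examples
#' fisher_exact_test(matrix(c(5, 18, 12, 10), 2, byrow = TRUE))$p.value
#' @export
fisher_exact_test <- function(x) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(2L, 2L))) stop("`x` must be a 2x2 table")
  if (any(x < 0) || any(x != round(x))) {
    stop("counts must be non-negative integers")
  }
  r1 <- sum(x[1, ]); r2 <- sum(x[2, ])
  c1 <- sum(x[, 1]); c2 <- sum(x[, 2])
  if (sum(x) == 0) stop("empty table")
  orat <- (x[1, 1] * x[2, 2]) / (x[1, 2] * x[2, 1])
  if (min(r1, r2, c1, c2) == 0) {
    message("zero margin: p = 1 by convention")
    p <- 1
  } else {
    support <- max(0, c1 - r2):min(r1, c1)
    probs <- dhyper(support, r1, r2, c1)
    p_obs <- dhyper(x[1, 1], r1, r2, c1)
    p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }
  structure(list(p.value = p, odds_ratio = orat, table = x),
            class = "fisher_exact")
}

#' @export
print.fisher_exact <- function(x, ...) {
  cat(sprintf("<fisher_exact> two-sided p = %.4g, odds ratio = %.3g\n",
              x$p.value, x$odds_ratio))
  invisible(x)
}
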