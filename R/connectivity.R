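#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino skewness Z and the Anscombe-Glynn kurtosis Z into
#' the omnibus statistic `K2 = Z1^2 + Z2^2`, chi-squared with 2 degrees of
#' freedom under normality.
#'
#' @param x numeric sample (n >= 8).
#' @return list with `statistic` (K2), `p.value`, `z_skewness`, `z_kurtosis`,
#'   `n`.
#' @export
dagostino_test <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) stop("dagostino_test requires at least 8 observations")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance sample")
  b1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2

  # skewness (D'Agostino 1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  if (y == 0) y <- 1   # convention of the reference implementation
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  denom <- 1 + xk * sqrt(2 / (a - 4))
  term2 <- sign(denom) * ((1 - 2 / a) / abs(denom))^(1 / 3)
  z2 <- ((1 - 2 / (9 * a)) - term2) / sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p.value = pchisq(k2, 2, lower.tail = FALSE),
       z_skewness = z1, z_kurtosis = z2, n = n)
}

#' Directed functional-connectivity graph from pairwise spike lags
#'
#' For every unordered cell pair (A, B) collects the lags of B's spikes
#' relative to each of A's spikes within `+/-max_lag_ms` (the reverse
#' distribution is its mirror). A pair is excluded when sparse
#' (fewer than `min_samples` lags), when the lag distribution is a zero-delay
#' correlation (|mean lag| below one frame duration — covering Gaussians
#' centered at zero, tested with [dagostino_test()]), or when it is
#' consistent with uniform co-activation (Kolmogorov-Smirnov test against the
#' uniform distribution on `+/-max_lag_ms`, p >= `alpha`). Retained pairs
#' contribute one directed edge: A to B when the mean lag is positive, B to A
#' when negative.
#'
#' @param r an [activity_raster()].
#' @param min_samples minimal number of lag samples (>= 8, the normality-test
#'   requirement).
#' @param alpha threshold for the shape tests.
#' @param max_lag_ms lag window in milliseconds.
#' @return object of class `functional_graph`: `graph` (a directed
#'   \pkg{igraph} object over all cells), `edges` data frame
#'   (`source`, `target`, `mean_lag_ms`, `n_samples`), `lag_tests` data frame
#'   with every pair's verdict, `out_degree`, `betweenness`, `cell_ids`,
#'   `tag`.
#' @export
compute_lag_graph <- function(r, min_samples = 20, alpha = 0.05,
                              max_lag_ms = 1000) {
  stopifnot(inherits(r, "activity_raster"))
  if (min_samples < 8) stop("min_samples must be >= 8")
  fr <- r$frame_rate_hz
  frame_ms <- 1000 / fr
  max_lag_f <- floor(max_lag_ms / frame_ms)
  nc <- n_cells(r)
  spikes <- lapply(seq_len(nc), function(i) which(r$onsets[i, ] == 1L) - 1L)

  tests <- list(); edges <- list()
  for (a in seq_len(nc - 1L)) {
    sa <- spikes[[a]]
    if (!length(sa)) next
    for (b in (a + 1L):nc) {
      sb <- spikes[[b]]
      if (!length(sb)) next
      d <- as.vector(outer(sb, sa, "-"))
      d <- d[abs(d) <= max_lag_f]
      lag_ms <- d * frame_ms
      n <- length(lag_ms)
      rec <- list(a = a, b = b, n = n, mean_lag_ms = NA_real_,
                  normal_p = NA_real_, uniform_p = NA_real_,
                  verdict = NA_character_)
      if (n < min_samples) {
        rec$verdict <- "excluded_sparse"
      } else {
        ml <- mean(lag_ms)
        rec$mean_lag_ms <- ml
        if (var(lag_ms) > 0) {
          rec$normal_p <- dagostino_test(lag_ms)$p.value
        }
        rec$uniform_p <- suppressWarnings(
          ks.test(lag_ms, "punif", -max_lag_ms, max_lag_ms)$p.value)
        if (abs(ml) < frame_ms) {
          # zero-delay correlation, Gaussian-shaped or not
          rec$verdict <- if (!is.na(rec$normal_p) && rec$normal_p >= alpha) {
            "excluded_normal"
          } else "excluded_zero_lag"
        } else if (rec$uniform_p >= alpha) {
          rec$verdict <- "excluded_uniform"
        } else {
          rec$verdict <- "retained"
          if (ml > 0) {
            edges[[length(edges) + 1L]] <- data.frame(
              source = a, target = b, mean_lag_ms = ml, n_samples = n)
          } else if (ml < 0) {
            edges[[length(edges) + 1L]] <- data.frame(
              source = b, target = a, mean_lag_ms = -ml, n_samples = n)
          } else {
            message("tied mean lag (exactly 0) for pair ", a, "-", b,
                    ": no edge drawn")
          }
        }
      }
      tests[[length(tests) + 1L]] <- rec
    }
  }
  lag_tests <- do.call(rbind, lapply(tests, as.data.frame))
  if (is.null(lag_tests)) {
    lag_tests <- data.frame(a = integer(), b = integer(), n = integer(),
                            mean_lag_ms = numeric(), normal_p = numeric(),
                            uniform_p = numeric(), verdict = character())
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = integer(), target = integer(),
               mean_lag_ms = numeric(), n_samples = integer())
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = seq_len(nc)))
  out_degree <- igraph::degree(g, mode = "out")
  btw <- igraph::betweenness(g, directed = TRUE)
  structure(list(graph = g, edges = edges, lag_tests = lag_tests,
                 out_degree = unname(out_degree),
                 betweenness = unname(btw), n_cells = nc,
                 cell_ids = r$cell_ids, tag = r$tag,
                 frame_rate_hz = fr, min_samples = min_samples,
                 alpha = alpha, max_lag_ms = max_lag_ms),
            class = "functional_graph")
}

#' @export
print.functional_graph <- function(x, ...) {
  cat(sprintf("<functional_graph> %d cells, %d directed edge(s)\n",
              x$n_cells, nrow(x$edges)))
  vt <- table(x$lag_tests$verdict)
  if (length(vt)) {
    cat("  pair verdicts:",
        paste(sprintf("%s=%d", names(vt), vt), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classify hub cells across fields of view
#'
#' A cell is a hub if all three criteria hold jointly: (1) it sends output
#' connections to at least `min_fraction` of the cells in its own field of
#' view; (2) its connection count reaches the top `100 - degree_pctile`
#' percent of the pooled across-FOV out-degree distribution; (3) its
#' betweenness centrality reaches the pooled `betweenness_pctile` percentile.
#' Percentile criteria use >= on the pooled empirical quantiles.
#'
#' @param graphs a single [compute_lag_graph()] result or a list of them
#'   (one per field of view).
#' @param min_fraction minimal fraction of within-FOV cells contacted.
#' @param degree_pctile pooled out-degree percentile for criterion 2.
#' @param betweenness_pctile pooled betweenness percentile for criterion 3.
#' @return object of class `hub_classification`: per-cell data frame
#'   (`fov`, `cell`, `cell_id`, `tag`, `out_degree`, `out_degree_pctile`,
#'   `betweenness`, `betweenness_pctile`, the three criteria and `hub`),
#'   plus the pooled thresholds.
#' @export
classify_hubs <- function(graphs, min_fraction = 0.05, degree_pctile = 95,
                          betweenness_pctile = 80) {
  if (inherits(graphs, "functional_graph")) graphs <- list(graphs)
  stopifnot(length(graphs) >= 1L,
            all(vapply(graphs, inherits, logical(1), "functional_graph")))
  pooled_deg <- unlist(lapply(graphs, `[[`, "out_degree"))
  pooled_btw <- unlist(lapply(graphs, `[[`, "betweenness"))
  thr_deg <- quantile(pooled_deg, degree_pctile / 100, names = FALSE)
  thr_btw <- quantile(pooled_btw, betweenness_pctile / 100, names = FALSE)
  deg_ecdf <- ecdf(pooled_deg); btw_ecdf <- ecdf(pooled_btw)
  cells <- do.call(rbind, lapply(seq_along(graphs), function(f) {
    g <- graphs[[f]]
    crit_local <- g$out_degree >= min_fraction * g$n_cells & g$out_degree > 0
    crit_deg <- g$out_degree >= thr_deg
    crit_btw <- g$betweenness >= thr_btw
    data.frame(fov = f, cell = seq_len(g$n_cells), cell_id = g$cell_ids,
               tag = g$tag, out_degree = g$out_degree,
               out_degree_pctile = 100 * deg_ecdf(g$out_degree),
               betweenness = g$betweenness,
               betweenness_pctile = 100 * btw_ecdf(g$betweenness),
               crit_local = crit_local, crit_degree = crit_deg,
               crit_betweenness = crit_btw,
               hub = crit_local & crit_deg & crit_btw)
  }))
  rownames(cells) <- NULL
  structure(list(cells = cells, degree_threshold = thr_deg,
                 betweenness_threshold = thr_btw,
                 min_fraction = min_fraction),
            class = "hub_classification")
}

#' @export
print.hub_classification <- function(x, ...) {
  cat(sprintf("<hub_classification> %d hub(s) of %d cells in %d FOV(s)\n",
              sum(x$cells$hub), nrow(x$cells), max(x$cells$fov)))
  invisible(x)
}

#' @export
summary.hub_classification <- function(object, ...) {
  print(object)
  d <- object$cells
  tot <- sum(d$out_degree)
  if (tot > 0 && any(!is.na(d$tag))) {
    by_tag <- tapply(d$out_degree, d$tag, sum)
    for (tg in names(by_tag)) {
      cat(sprintf("  tag %s: %.1f%% of all output connections, %d/%d hubs\n",
                  tg, 100 * by_tag[[tg]] / tot,
                  sum(d$hub[d$tag == tg], na.rm = TRUE),
                  sum(d$tag == tg, na.rm = TRUE)))
    }
  }
  invisible(object)
}

#' Export a functional graph
#'
#' `write_edge_list` writes a CSV with columns
#' `source,target,mean_lag_ms,n_samples`; `write_graphml` writes the directed
#' graph in GraphML via \pkg{igraph}.
#'
#' @param g a [compute_lag_graph()] result.
#' @param path output file path.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "functional_graph"))
  write.table(g$edges, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(g, path) {
  stopifnot(inherits(g, "functional_graph"))
  igraph::write_graph(g$graph, path, format = "graphml")
  invisible(path)
}
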