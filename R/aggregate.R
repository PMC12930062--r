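#' Aggregate an image-level metric table to one mouse x ROI record
#'
#' Averages the per-image summaries of one mouse and one region of
#' interest (up to 4 images: 2 hemispheres x 2 sections) into a single
#' record, the unit entering group-level analysis. Images missing from the
#' full design are tolerated: the mean runs over the available replicates
#' and the image count is recorded.
#'
#' @param summaries data.frame with one row per image, columns
#'   \code{mouse}, \code{roi} (and optionally \code{group},
#'   \code{hemisphere}, \code{section}) plus numeric metric columns
#'   (\code{n_pre}, \code{n_post}, \code{n_coloc},
#'   \code{mean_intensity_pre}, \code{mean_intensity_post},
#'   \code{coloc_volume_total}).
#' @param metrics metric columns to average; defaults to all numeric
#'   columns other than identifiers.
#' @return one-row data.frame: \code{mouse}, \code{group}, \code{roi},
#'   \code{image_count}, then the per-metric means.
#' @examples
#' s <- data.frame(mouse = "m1", roi = "MO", n_coloc = c(900, 1000, 1100))
#' aggregateMouseROI(s)$n_coloc
#' @export
aggregateMouseROI <- function(summaries, metrics = NULL) {
  if (!nrow(summaries)) stop("no image summaries to aggregate")
  if (!all(c("mouse", "roi") %in% names(summaries)))
    stop("summaries need 'mouse' and 'roi' columns")
  if (length(unique(summaries$mouse)) > 1L ||
      length(unique(summaries$roi)) > 1L)
    stop("summaries mix mouse and/or ROI; aggregate one cell at a time")
  if (is.null(metrics)) {
    idcols <- c("mouse", "group", "roi", "hemisphere", "section",
                "image_id")
    metrics <- setdiff(names(summaries)[vapply(summaries, is.numeric,
                                               logical(1))], idcols)
  }
  out <- data.frame(
    mouse = as.character(summaries$mouse[1]),
    group = if ("group" %in% names(summaries))
      as.character(summaries$group[1]) else NA_character_,
    roi = as.character(summaries$roi[1]),
    image_count = nrow(summaries))
  for (m in metrics) out[[m]] <- mean(summaries[[m]], na.rm = TRUE)
  out
}

#' ROUT robust outlier flagging (univariate, Q percent FDR)
#'
#' Flags outliers in a vector of values with the ROUT procedure reduced to
#' the univariate case: the constant model is fit robustly by the median
#' (K = 1 parameter), the robust standard deviation of the residuals
#' (RSDR) is the 68.27th percentile of the absolute residuals scaled by
#' \eqn{n/(n - K)}, and residuals are tested outside-in with an
#' FDR-controlling threshold: ranking residuals by decreasing magnitude,
#' value \eqn{i} (and every larger residual) is flagged when its two-tailed
#' t-probability (\eqn{t_i = |r_i| / RSDR}, \eqn{df = n - K}) falls below
#' \eqn{\alpha_i = (Q/100)\,(n - (i - 1))/n}. The flag set is invariant to
#' permutation of the input and to affine transforms of the values.
#'
#' @param values numeric vector, \code{n >= 3}, all finite.
#' @param Q maximum desired false-discovery rate among flagged points, in
#'   percent (1 is the conventional choice).
#' @return object of class \code{"routReport"}: list with \code{values},
#'   \code{Q}, logical \code{flags}, robust location \code{center}
#'   (median) and robust scale \code{rsdr}.
#' @examples
#' r <- routOutliers(c(rnorm(11), 50), Q = 1)
#' which(r$flags)
#' @export
routOutliers <- function(values, Q = 1) {
  if (length(values) < 3L) stop("ROUT needs at least 3 values")
  if (anyNA(values) || any(!is.finite(values)))
    stop("values must be finite")
  if (Q <= 0 || Q >= 100) stop("Q must be in (0, 100) percent")
  n <- length(values)
  K <- 1L
  med <- stats::median(values)
  r <- values - med
  rsdr <- stats::quantile(abs(r), probs = 0.6827, names = FALSE, type = 7) *
    n / (n - K)
  flags <- rep(FALSE, n)
  if (rsdr > 0 || any(abs(r) > 0)) {
    absr <- abs(r)
    ord <- order(absr, decreasing = TRUE)
    tval <- if (rsdr > 0) absr[ord] / rsdr
            else ifelse(absr[ord] > 0, Inf, 0)
    p <- 2 * stats::pt(-tval, df = n - K)
    alpha <- Q / 100 * (n - (seq_len(n) - 1L)) / n
    hit <- which(p < alpha)
    if (length(hit)) {
      k <- max(hit)
      # flag by magnitude so ties at the boundary are treated alike
      flags <- absr >= absr[ord[k]] & absr > 0
    }
  }
  structure(list(values = values, Q = Q, flags = flags,
                 center = med, rsdr = rsdr),
            class = "routReport")
}

#' @export
print.routReport <- function(x, ...) {
  cat(sprintf("ROUT outlier report (Q = %g%%): %d/%d flagged\n",
              x$Q, sum(x$flags), length(x$values)))
  cat(sprintf("  robust location %.6g, RSDR %.6g\n", x$center, x$rsdr))
  if (any(x$flags))
    cat("  flagged values:", paste(format(x$values[x$flags]),
                                   collapse = ", "), "\n")
  invisible(x)
}

#' Group mean, SEM and n of a metric after ROUT outlier removal
#'
#' Summarizes one metric of mouse x ROI records per group x ROI cell.
#' Outlier removal with [routOutliers()] is applied within each cell before
#' summarizing (skipped for cells with fewer than 3 values, where the test
#' is undefined); \code{n} reflects the removals.
#'
#' @param records data.frame of aggregated records (one row per mouse x
#'   ROI), e.g. rows of [aggregateMouseROI()] outputs.
#' @param metric name of the metric column to summarize.
#' @param Q ROUT false-discovery rate, percent.
#' @param by grouping columns (default \code{c("group", "roi")}).
#' @return data.frame with one row per cell: grouping columns,
#'   \code{mean}, \code{sem}, \code{n}, \code{n_outliers}.
#' @export
groupSummary <- function(records, metric, Q = 1,
                         by = c("group", "roi")) {
  if (!metric %in% names(records)) stop("unknown metric: ", metric)
  by <- intersect(by, names(records))
  if (!length(by)) stop("no grouping columns present")
  cells <- split(records, records[by], drop = TRUE)
  rows <- lapply(cells, function(cell) {
    v <- cell[[metric]]
    v <- v[is.finite(v)]
    n_out <- 0L
    if (length(v) >= 3L) {
      rep_ <- routOutliers(v, Q = Q)
      n_out <- sum(rep_$flags)
      v <- v[!rep_$flags]
    }
    out <- cell[1, by, drop = FALSE]
    out$mean <- if (length(v)) mean(v) else NA_real_
    out$sem <- if (length(v) > 1) stats::sd(v) / sqrt(length(v))
               else NA_real_
    out$n <- length(v)
    out$n_outliers <- n_out
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[do.call(order, out[by]), , drop = FALSE]
}
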