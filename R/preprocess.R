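#' Remove out-of-range acceleration values
#'
#' The sensor encodes acceleration as 8-bit counts, so the standard range is
#' 0-255; transmission glitches occasionally produce values outside it,
#' which are treated as outliers and removed before any statistics are
#' computed.
#'
#' @param values Numeric vector of acceleration counts.
#' @param lower,upper Inclusive retention bounds (defaults 0 and 255).
#' @return List with `values` (retained, original order) and `removed`
#'   (count of discarded values).
#' @export
range_filter <- function(values, lower = 0, upper = 255) {
  keep <- !is.na(values) & values >= lower & values <= upper
  list(values = values[keep], removed = sum(!keep))
}

#' Tukey-fence outlier bounds from quartiles
#'
#' Computes the first and third quartiles (linear interpolation between
#' order statistics, the common type-7 rule), the interquartile range
#' `IQR = Q3 - Q1`, and the criteria for upper and lower outliers
#' `CUO = Q3 + 1.5 * IQR`, `CLO = Q1 - 1.5 * IQR`.
#'
#' @param values Numeric vector with at least 4 values.
#' @return List of class `outlier_bounds` with elements `quartile1`,
#'   `quartile3`, `iqr`, `cuo`, `clo`.
#' @export
iqr_bounds <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 4L) {
    stop("insufficient data: iqr_bounds needs at least 4 values")
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  structure(
    list(quartile1 = q[1], quartile3 = q[2], iqr = iqr,
         cuo = q[2] + 1.5 * iqr, clo = q[1] - 1.5 * iqr),
    class = "outlier_bounds"
  )
}

#' @export
print.outlier_bounds <- function(x, ...) {
  cat(sprintf("Quartile fence: Q1=%.2f Q3=%.2f IQR=%.2f  CLO=%.2f CUO=%.2f\n",
              x$quartile1, x$quartile3, x$iqr, x$clo, x$cuo))
  invisible(x)
}

#' Filter values by the quartile (Tukey-fence) rule
#'
#' Retains values `v` with `CLO <= v <= CUO`; the fences are computed from
#' the input itself unless precomputed bounds are supplied.
#'
#' @param values Numeric vector.
#' @param bounds Optional [iqr_bounds()] result.
#' @return Retained values, with attribute `removed` (discarded count).
#' @export
iqr_filter <- function(values, bounds = NULL) {
  if (is.null(bounds)) bounds <- iqr_bounds(values)
  keep <- !is.na(values) & values >= bounds$clo & values <= bounds$cuo
  out <- values[keep]
  attr(out, "removed") <- sum(!keep)
  out
}

#' Clean a labeled dataset with the range and quartile rules
#'
#' Applies [range_filter()] and then [iqr_filter()] to each axis, per goat;
#' a sample is dropped when any of its axis values fails either rule. The
#' quartile fences are computed per goat and axis over the assembled
#' dataset.
#'
#' @param samples Labeled sample data.frame from [build_dataset()].
#' @param axes Axis columns to clean (default x, y, z; y is skipped
#'   automatically if absent).
#' @return Cleaned data.frame with attribute `removed`
#'   (`range` and `iqr` counts of dropped rows).
#' @export
clean_samples <- function(samples, axes = c("x", "y", "z")) {
  axes <- intersect(axes, names(samples))
  in_range <- rep(TRUE, nrow(samples))
  for (a in axes) {
    in_range <- in_range & samples[[a]] >= 0 & samples[[a]] <= 255
  }
  n_range <- sum(!in_range)
  samples <- samples[in_range, ]
  keep <- rep(TRUE, nrow(samples))
  for (g in unique(samples$goat_id)) {
    gi <- samples$goat_id == g
    for (a in axes) {
      v <- samples[[a]][gi]
      if (length(v) >= 4L) {
        b <- iqr_bounds(v)
        keep[gi] <- keep[gi] & v >= b$clo & v <= b$cuo
      }
    }
  }
  out <- samples[keep, ]
  rownames(out) <- NULL
  attr(out, "removed") <- c(range = n_range, iqr = sum(!keep))
  out
}

entropy_bits <- function(x) {
  p <- table(x)
  p <- p[p > 0] / length(x)
  -sum(p * log2(p))
}

#' Rank axis features by information gain and gain ratio
#'
#' For each axis, the information gain is `H(label) - sum_v p(v) H(label |
#' feature = v)` with every distinct integer count treated as one category,
#' and the gain ratio divides by the split information (the entropy of the
#' feature's own value distribution), defined as 0 when the split
#' information is 0. The two axes with the highest gain ratio are flagged as
#' the selected model features.
#'
#' @param samples Labeled sample data.frame with a binary `label` column.
#' @param features Feature columns to score (default `c("x","y","z")`).
#' @return data.frame (`feature, info_gain, gain_ratio, selected`), sorted
#'   by decreasing gain ratio.
#' @export
rank_features <- function(samples, features = c("x", "y", "z")) {
  features <- intersect(features, names(samples))
  y <- samples$label
  if (length(unique(y)) < 2L) {
    stop("cannot rank features: only one class present")
  }
  h_y <- entropy_bits(y)
  score <- function(f) {
    v <- samples[[f]]
    split <- split(y, v)
    cond <- sum(vapply(split, function(s) length(s) * entropy_bits(s),
                       numeric(1))) / length(y)
    ig <- max(h_y - cond, 0)
    si <- entropy_bits(v)
    c(info_gain = ig, gain_ratio = if (si == 0) 0 else ig / si)
  }
  sc <- t(vapply(features, score, numeric(2)))
  out <- data.frame(feature = features, info_gain = sc[, "info_gain"],
                    gain_ratio = sc[, "gain_ratio"],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$gain_ratio), ]
  out$selected <- seq_len(nrow(out)) <= 2L
  rownames(out) <- NULL
  out
}
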