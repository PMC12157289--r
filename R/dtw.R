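# Dynamic time warping over per-EO protein series.
#
# The alignment compares values only: clock times play no role, so two days
# with the same protein sequence at different hours are identical to DTW.
# Step pattern: symmetric, diagonal weight 2, no warping window; the raw
# cumulative cost is normalised by n + m so that series of different lengths
# (days with different EO counts) are comparable.

#' Dynamic time warping distance between two protein series
#'
#' Dynamic-programming alignment with local cost \eqn{|x_i - y_j|} and the
#' symmetric step pattern \eqn{D(i,j) = \min(D(i-1,j-1) + 2d, D(i-1,j) + d,
#' D(i,j-1) + d)}; \eqn{D(1,1) = d(1,1)}. The normalised distance divides the
#' final cost by \eqn{n + m}. The optimal warping path is recovered by
#' traceback; ties between predecessor cells break diagonal, then up, then
#' left (this affects only the reported path, never the distance).
#'
#' @param x,y Non-empty numeric vectors (per-EO protein, g).
#' @return Object of class \code{dtw_result}: \code{raw_distance},
#'   \code{normalized_distance}, \code{path} (two-column matrix of 1-based
#'   index pairs from (1,1) to (n,m)) and \code{path_length}.
#' @export
#' @examples
#' dtw_distance(c(1, 3, 2), c(1, 2))$normalized_distance  # 0.4
dtw_distance <- function(x, y) {
  if (!length(x) || !length(y)) stop("series must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("series must not contain missing values")
  n <- length(x); m <- length(y)
  d <- abs(outer(x, y, "-"))
  D <- matrix(NA_real_, n, m)
  D[1, 1] <- d[1, 1]
  if (n > 1) D[2:n, 1] <- D[1, 1] + cumsum(d[2:n, 1])
  if (m > 1) D[1, 2:m] <- D[1, 1] + cumsum(d[1, 2:m])
  if (n > 1 && m > 1) {
    for (i in 2:n) for (j in 2:m) {
      D[i, j] <- min(D[i - 1, j - 1] + 2 * d[i, j],
                     D[i - 1, j] + d[i, j],
                     D[i, j - 1] + d[i, j])
    }
  }
  # traceback, preferring diagonal > up > left
  path <- matrix(c(n, m), 1, 2)
  i <- n; j <- m
  while (i > 1 || j > 1) {
    if (i > 1 && j > 1) {
      cand <- c(D[i - 1, j - 1] + 2 * d[i, j],
                D[i - 1, j] + d[i, j],
                D[i, j - 1] + d[i, j])
      pick <- which(cand <= min(cand))[1]
      if (pick == 1L) { i <- i - 1; j <- j - 1 }
      else if (pick == 2L) i <- i - 1
      else j <- j - 1
    } else if (i > 1) i <- i - 1
    else j <- j - 1
    path <- rbind(c(i, j), path)
  }
  structure(list(raw_distance = D[n, m],
                 normalized_distance = D[n, m] / (n + m),
                 path = unname(path),
                 path_length = nrow(path)),
            class = "dtw_result")
}

#' @export
print.dtw_result <- function(x, ...) {
  cat("DTW alignment: raw", format(x$raw_distance),
      "| normalised", format(x$normalized_distance),
      "| path length", x$path_length, "\n")
  invisible(x)
}

# Coerce an intake_series_set / list of vectors to a labelled list of values.
series_values <- function(series) {
  if (inherits(series, "intake_series_set") ||
      (is.list(series) && length(series) &&
       all(vapply(series, is.list, TRUE)))) {
    vals <- lapply(series, `[[`, "values")
    names(vals) <- vapply(series, `[[`, "", "series_id")
  } else {
    vals <- lapply(series, as.numeric)
    if (is.null(names(vals)))
      names(vals) <- as.character(seq_along(vals))
  }
  vals
}

#' Pairwise normalised DTW distance matrix
#'
#' Computes every unordered pair once (self-comparisons are fixed at zero)
#' and returns a symmetric labelled matrix of normalised distances.
#'
#' @param series An \code{intake_series_set} (see [to_series()]) or a list of
#'   numeric vectors; at least 2 series.
#' @return Symmetric numeric matrix with zero diagonal; dimnames are the
#'   series labels in input order.
#' @export
distance_matrix <- function(series) {
  vals <- series_values(series)
  if (length(vals) < 2L) stop("need at least 2 series")
  if (any(vapply(vals, length, 0L) == 0L)) stop("series must be non-empty")
  m <- dtw_pairwise_norm(vals)
  dimnames(m) <- list(names(vals), names(vals))
  m
}

# Shared validation for functions consuming a dissimilarity matrix.
check_dissimilarity <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    stop("dissimilarity matrix must be square")
  if (any(!is.finite(dm))) stop("dissimilarity matrix must be finite")
  if (any(dm < 0)) stop("dissimilarities must be nonnegative")
  if (any(abs(dm - t(dm)) > 1e-8)) stop("dissimilarity matrix must be symmetric")
  if (any(diag(dm) != 0)) stop("dissimilarity matrix must have zero diagonal")
  dm
}
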