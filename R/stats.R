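# Rank-based group comparisons used by the cluster reports.

joint_ranks <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(values)
  ties <- table(values)
  list(values = values, g = g, r = r,
       N = length(values),
       tie_term = sum(ties^3 - ties))
}

#' Kruskal-Wallis rank-sum test
#'
#' \eqn{H = \frac{12}{N(N+1)} \sum_g n_g (\bar r_g - \frac{N+1}{2})^2}
#' on joint ranks, divided by the tie correction
#' \eqn{1 - \sum(t^3 - t)/(N^3 - N)}; the p-value comes from a chi-square
#' with (number of groups - 1) degrees of freedom. When every observation is
#' identical the tie correction is zero and the statistic is undefined; this
#' is reported as a degenerate result rather than an error.
#'
#' @param groups List of at least two non-empty numeric vectors.
#' @return List: \code{H}, \code{df}, \code{p}, \code{degenerate}.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4)))$H  # 2.4
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L || any(lengths(groups) == 0L))
    stop("need at least two non-empty groups")
  jr <- joint_ranks(groups)
  df <- length(groups) - 1L
  C <- 1 - jr$tie_term / (jr$N^3 - jr$N)
  if (C <= 0)
    return(list(H = NA_real_, df = df, p = NA_real_, degenerate = TRUE))
  rbar <- tapply(jr$r, jr$g, mean)
  ng <- lengths(groups)
  H <- 12 / (jr$N * (jr$N + 1)) * sum(ng * (rbar - (jr$N + 1) / 2)^2) / C
  list(H = H, df = df, p = pchisq(H, df, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Dunn's post hoc test with multiplicity adjustment
#'
#' All pairwise comparisons on joint ranks:
#' \eqn{z_{ij} = (\bar r_i - \bar r_j) / \sqrt{\left(\frac{N(N+1)}{12} -
#' \frac{\sum(t^3-t)}{12(N-1)}\right)\left(\frac{1}{n_i} +
#' \frac{1}{n_j}\right)}}, two-sided normal p-values, Bonferroni-adjusted by
#' the number of pairs (capped at 1).
#'
#' @param groups List of at least two non-empty numeric vectors; names are
#'   used as group labels.
#' @param adjust Only \code{"bonferroni"} is offered.
#' @return Data frame: \code{group_i}, \code{group_j}, \code{z},
#'   \code{p_raw}, \code{p_adj}, \code{degenerate}.
#' @export
dunn_test <- function(groups, adjust = "bonferroni") {
  adjust <- match.arg(adjust)
  if (length(groups) < 2L || any(lengths(groups) == 0L))
    stop("need at least two non-empty groups")
  labels <- names(groups)
  if (is.null(labels)) labels <- as.character(seq_along(groups))
  jr <- joint_ranks(groups)
  rbar <- tapply(jr$r, jr$g, mean)
  ng <- lengths(groups)
  sigma2 <- jr$N * (jr$N + 1) / 12 - jr$tie_term / (12 * (jr$N - 1))
  pairs <- utils::combn(length(groups), 2)
  npairs <- ncol(pairs)
  res <- lapply(seq_len(npairs), function(c) {
    i <- pairs[1, c]; j <- pairs[2, c]
    num <- rbar[[i]] - rbar[[j]]
    den <- sqrt(sigma2 * (1 / ng[i] + 1 / ng[j]))
    if (!is.finite(den) || den <= 0) {
      z <- if (num == 0) 0 else NA_real_
      degenerate <- TRUE
    } else {
      z <- num / den
      degenerate <- FALSE
    }
    p <- if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z))
    data.frame(group_i = labels[i], group_j = labels[j], z = z,
               p_raw = p, p_adj = pmin(1, p * npairs),
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
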