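#' Pearson and partial correlation with t-test significance
#'
#' The statistical kernel of the pipeline. `pearson_corr` is the
#' product-moment correlation (order 0). `partial_first` removes one control
#' variable,
#' \deqn{r_{12,3} = \frac{r_{12} - r_{13} r_{23}}
#'                       {\sqrt{(1-r_{13}^2)(1-r_{23}^2)}},}
#' and `partial_second` removes two controls by recursion on the first-order
#' coefficients,
#' \deqn{r_{12,34} = \frac{r_{12,3} - r_{14,3}\, r_{24,3}}
#'                        {\sqrt{(1-r_{14,3}^2)(1-r_{24,3}^2)}}.}
#' In the pipeline variable 1 is the NDVI anomaly series, variable 2 the
#' (accumulated) precipitation anomaly series, and variables 3 and 4 the
#' temperature and radiation anomaly controls.
#'
#' Missing data are handled pairwise-complete on the full tuple: a time point
#' is dropped from all series if any of them is missing there, so every
#' correlation entering the recursion shares one sample.
#'
#' @param x,y,z,z1,z2 Numeric series of equal length.
#' @param alpha Significance level for the two-sided t-test (default 0.05).
#' @return A list of class `correlation_value` with elements `r`, `order`,
#'   `n` (complete sample size), `t_stat`, `p_value`, `significant`,
#'   `alpha`.
#' @examples
#' set.seed(1)
#' x <- rnorm(34); z1 <- rnorm(34); z2 <- rnorm(34)
#' y <- 0.8 * x + 0.5 * z1 + rnorm(34, sd = 0.3)
#' partial_second(x, y, z1, z2)$r
#' @name partial_correlation
NULL

corr_value <- function(r, order, n, alpha) {
  s <- r_significance(r, n, n_controls = order, alpha = alpha)
  structure(list(r = r, order = order, n = n, t_stat = s$t_stat,
                 p_value = s$p_value, significant = s$significant,
                 alpha = alpha),
            class = "correlation_value")
}

#' @export
print.correlation_value <- function(x, ...) {
  cat(sprintf("r = %.4f (order %d, n = %d, t = %.3f, p = %.4g%s)\n",
              x$r, x$order, x$n, x$t_stat, x$p_value,
              if (isTRUE(x$significant)) sprintf(", significant at %g", x$alpha)
              else ""))
  invisible(x)
}

complete_tuple <- function(...) {
  s <- list(...)
  len <- unique(vapply(s, length, 1L))
  if (length(len) != 1) stop("series lengths differ", call. = FALSE)
  keep <- Reduce(`&`, lapply(s, function(v) !is.na(v)))
  lapply(s, function(v) v[keep])
}

raw_pearson <- function(x, y) {
  cx <- x - mean(x); cy <- y - mean(y)
  sx <- sum(cx * cx); sy <- sum(cy * cy)
  if (sx <= 0 || sy <= 0)
    stop("correlation undefined for a constant series", call. = FALSE)
  sum(cx * cy) / sqrt(sx * sy)
}

#' @rdname partial_correlation
#' @export
pearson_corr <- function(x, y, alpha = 0.05) {
  s <- complete_tuple(x, y)
  n <- length(s[[1]])
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  corr_value(raw_pearson(s[[1]], s[[2]]), order = 0L, n = n, alpha = alpha)
}

first_order_r <- function(r12, r13, r23) {
  den <- sqrt((1 - r13^2) * (1 - r23^2))
  if (!is.finite(den) || den < .Machine$double.eps^0.5)
    stop("degenerate control: a control is perfectly correlated with x or y",
         call. = FALSE)
  (r12 - r13 * r23) / den
}

#' @rdname partial_correlation
#' @export
partial_first <- function(x, y, z, alpha = 0.05) {
  s <- complete_tuple(x, y, z)
  n <- length(s[[1]])
  if (n < 4) stop("need at least 4 complete triples", call. = FALSE)
  r12 <- raw_pearson(s[[1]], s[[2]])
  r13 <- raw_pearson(s[[1]], s[[3]])
  r23 <- raw_pearson(s[[2]], s[[3]])
  corr_value(first_order_r(r12, r13, r23), order = 1L, n = n, alpha = alpha)
}

#' @rdname partial_correlation
#' @export
partial_second <- function(x, y, z1, z2, alpha = 0.05) {
  s <- complete_tuple(x, y, z1, z2)
  n <- length(s[[1]])
  if (n < 5) stop("need at least 5 complete quadruples", call. = FALSE)
  r12 <- raw_pearson(s[[1]], s[[2]])
  r13 <- raw_pearson(s[[1]], s[[3]])
  r23 <- raw_pearson(s[[2]], s[[3]])
  r14 <- raw_pearson(s[[1]], s[[4]])
  r24 <- raw_pearson(s[[2]], s[[4]])
  r34 <- raw_pearson(s[[3]], s[[4]])
  r12.3 <- first_order_r(r12, r13, r23)
  r14.3 <- first_order_r(r14, r13, r34)
  r24.3 <- first_order_r(r24, r23, r34)
  corr_value(first_order_r(r12.3, r14.3, r24.3), order = 2L, n = n,
             alpha = alpha)
}

#' Significance of a (partial) correlation coefficient
#'
#' Two-sided t-test with `df = n - 2 - n_controls` degrees of freedom,
#' `t = r * sqrt(df / (1 - r^2))`. A coefficient of exactly +-1 gets
#' `t = Inf`, `p = 0` by convention.
#'
#' @param r Correlation coefficient(s), vectorised.
#' @param n Sample size used to compute `r`.
#' @param n_controls Number of control variables (0, 1 or 2).
#' @param alpha Significance level.
#' @return A list with vectors `t_stat`, `p_value`, `significant`, `df`.
#' @export
r_significance <- function(r, n, n_controls = 0L, alpha = 0.05) {
  df <- n - 2L - n_controls
  if (any(df < 1)) stop("not enough degrees of freedom", call. = FALSE)
  t_stat <- ifelse(abs(r) >= 1, sign(r) * Inf, r * sqrt(df / (1 - r^2)))
  p <- 2 * stats::pt(-abs(t_stat), df)
  p[abs(r) >= 1] <- 0
  list(t_stat = t_stat, p_value = p, significant = p < alpha, df = df)
}

#' Critical correlation coefficient at a significance level
#'
#' The smallest |r| whose two-sided t-test with `df = n - 2 - n_controls`
#' degrees of freedom rejects at level `alpha`. Used for the confidence
#' reference lines of zonal box plots.
#'
#' @inheritParams r_significance
#' @return Numeric critical |r|.
#' @export
critical_r <- function(alpha, n, n_controls = 0L) {
  df <- n - 2L - n_controls
  if (df < 1) stop("not enough degrees of freedom", call. = FALSE)
  tc <- stats::qt(1 - alpha / 2, df)
  tc / sqrt(df + tc^2)
}

# ---- vectorised column engine -------------------------------------------
# Second-order partial correlation computed column-by-column on matrices
# whose columns are per-pixel year series. Columns containing NA fall back to
# the scalar path with pairwise-complete filtering; degenerate columns
# (constant series, perfectly correlated controls) yield NA.

col_pearson <- function(A, B) {
  cA <- sweep(A, 2, colMeans(A)); cB <- sweep(B, 2, colMeans(B))
  den <- sqrt(colSums(cA * cA) * colSums(cB * cB))
  r <- colSums(cA * cB) / den
  r[den <= 0] <- NA_real_
  r
}

first_order_vec <- function(r12, r13, r23) {
  den <- sqrt((1 - r13^2) * (1 - r23^2))
  out <- (r12 - r13 * r23) / den
  out[!is.finite(den) | den < .Machine$double.eps^0.5] <- NA_real_
  out
}

parcor2_columns <- function(X, Y, Z1, Z2, alpha = 0.05) {
  n <- nrow(X); m <- ncol(X)
  r <- rep(NA_real_, m); p <- rep(NA_real_, m); nn <- rep(NA_integer_, m)
  has_na <- colSums(is.na(X) | is.na(Y) | is.na(Z1) | is.na(Z2)) > 0
  ok <- which(!has_na)
  if (length(ok)) {
    Xo <- X[, ok, drop = FALSE]; Yo <- Y[, ok, drop = FALSE]
    Z1o <- Z1[, ok, drop = FALSE]; Z2o <- Z2[, ok, drop = FALSE]
    r12 <- col_pearson(Xo, Yo);  r13 <- col_pearson(Xo, Z1o)
    r23 <- col_pearson(Yo, Z1o); r14 <- col_pearson(Xo, Z2o)
    r24 <- col_pearson(Yo, Z2o); r34 <- col_pearson(Z1o, Z2o)
    r12.3 <- first_order_vec(r12, r13, r23)
    r14.3 <- first_order_vec(r14, r13, r34)
    r24.3 <- first_order_vec(r24, r23, r34)
    r[ok] <- first_order_vec(r12.3, r14.3, r24.3)
    nn[ok] <- n
  }
  for (j in which(has_na)) {
    res <- tryCatch(partial_second(X[, j], Y[, j], Z1[, j], Z2[, j],
                                   alpha = alpha),
                    error = function(e) NULL)
    if (!is.null(res)) { r[j] <- res$r; nn[j] <- res$n }
  }
  r <- pmin(1, pmax(-1, r))
  fin <- is.finite(r) & !is.na(nn) & nn >= 5L
  if (any(fin)) {
    sg <- r_significance(r[fin], nn[fin], n_controls = 2L, alpha = alpha)
    p[fin] <- sg$p_value
  }
  r[!fin] <- NA_real_
  list(r = r, p = p, n = nn)
}
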