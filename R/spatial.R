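#' Pearson product-moment correlation
#'
#' Thin validated wrapper used by the correlation report: requires at least
#' three paired finite values and nonzero variance in both vectors.
#' @param x,y Numeric vectors of equal length.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop_validation("need paired vectors of equal length >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_validation("non-finite values in correlation input")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop_validation("zero variance in correlation input")
  stats::cor(x, y)
}

#' Precompute distance-class structure for the modified t-test
#'
#' Builds the equal-width Euclidean distance classes (default 12, spanning
#' distances up to half the maximum pairwise distance; more distant pairs
#' are treated as uncorrelated) and the trace terms of the effective
#' sample-size formula, so that repeated tests on the same coordinates are
#' cheap. Class 0 is the diagonal (variance) term.
#'
#' @param coords n x 2 matrix of site coordinates; rows must be unique.
#' @param n_classes Number of distance classes.
#' @return An object of class `dutilleul_prep`.
#' @export
dutilleul_prep <- function(coords, n_classes = 12) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 10) stop_validation("need at least 10 sites")
  if (anyDuplicated(paste(coords[, 1], coords[, 2])))
    stop_validation("site coordinates must be unique")
  D <- as.matrix(stats::dist(coords))
  half_max <- max(D) / 2
  width <- half_max / n_classes
  CL <- pmin(ceiling(D / width), n_classes + 1L)
  CL[CL > n_classes] <- 0L           # pairs beyond half the max distance
  diag(CL) <- -1L                    # variance term handled separately
  # per-class pair counts (ordered pairs) and row sums
  S <- vapply(seq_len(n_classes), function(h) sum(CL == h), numeric(1))
  r <- vapply(seq_len(n_classes), function(h) rowSums(CL == h), numeric(n))
  # trace terms over classes 0..K, class 0 = identity (diagonal)
  S_full <- c(n, S)
  r_full <- cbind(rep(1, n), r)
  K1 <- n_classes + 1L
  Tmat <- matrix(0, K1, K1)
  for (h in seq_len(K1)) for (g in seq_len(h)) {
    trAA <- if (h == g) S_full[h] else 0
    Tmat[h, g] <- Tmat[g, h] <-
      trAA - 2 * sum(r_full[, h] * r_full[, g]) / n + S_full[h] * S_full[g] / n^2
  }
  u <- c(n - 1, -S / n)
  structure(list(n = n, n_classes = n_classes, width = width,
                 class_label = as.vector(CL), S = S, Tmat = Tmat, u = u),
            class = "dutilleul_prep")
}

# distance-class autocovariance estimates for one centered variable:
# c(variance, per-class mean cross-product)
class_autocov <- function(xc, prep) {
  q <- rowsum(as.vector(tcrossprod(xc)), prep$class_label)
  lbl <- as.integer(rownames(q))
  a <- numeric(prep$n_classes)
  present <- lbl >= 1
  a[lbl[present]] <- q[present] / prep$S[lbl[present]]
  c(mean(xc^2), a)
}

#' Dutilleul's modified t-test for correlation under spatial autocorrelation
#'
#' Tests the Pearson correlation of two spatially indexed variables,
#' replacing the sample size by Dutilleul's effective sample size. The
#' spatial autocovariance of each variable is estimated in equal-width
#' distance classes and plugged into the covariance matrices Sx and Sy of
#' the trace formula
#' `M = 1 + tr(B Sx) tr(B Sy) / tr(B Sx B Sy)` with centering matrix B;
#' the statistic `t = r * sqrt((M - 2)/(1 - r^2))` is referred to a
#' t-distribution with `M - 2` degrees of freedom (two-sided). For
#' spatially independent data M is close to n; positive autocorrelation
#' shared by both variables shrinks M and makes the test more conservative
#' than the classic one. If the estimated trace denominator is degenerate
#' the function falls back to the classic t-test with a warning.
#'
#' @param x,y Numeric vectors over the same sites.
#' @param coords n x 2 coordinate matrix (ignored when `prep` is given).
#' @param n_classes Number of distance classes (default 12).
#' @param prep Optional [dutilleul_prep()] result for these coordinates.
#' @return An object of classes `dutilleul_test` and `htest`, with the
#'   effective sample size in `$ess` and the uncorrected p-value in
#'   `$p_classic`.
#' @export
dutilleul_test <- function(x, y, coords = NULL, n_classes = 12, prep = NULL) {
  if (is.null(prep)) {
    if (is.null(coords)) stop_validation("either coords or prep is required")
    prep <- dutilleul_prep(coords, n_classes)
  }
  n <- prep$n
  if (length(x) != n || length(y) != n)
    stop_validation("variable length does not match the coordinate set")
  r <- pearson_cor(x, y)
  a <- class_autocov(x - mean(x), prep)
  b <- class_autocov(y - mean(y), prep)
  tr_x <- sum(a * prep$u)
  tr_y <- sum(b * prep$u)
  tr_xy <- as.numeric(a %*% prep$Tmat %*% b)
  method <- "Dutilleul's modified t-test of association"
  if (!is.finite(tr_xy) || tr_xy <= 0 || tr_x <= 0 || tr_y <= 0) {
    warning("degenerate spatial covariance estimate; falling back to the classic t-test")
    ess <- n
    method <- "Pearson's correlation t-test (classic fallback)"
  } else {
    ess <- min(max(1 + tr_x * tr_y / tr_xy, 2), n)
  }
  df <- ess - 2
  tstat <- if (df > 0 && abs(r) < 1) r * sqrt(df / (1 - r^2))
           else if (abs(r) >= 1) sign(r) * Inf else NA_real_
  p <- if (df > 0) 2 * stats::pt(abs(tstat), df, lower.tail = FALSE) else 1
  df_c <- n - 2
  t_c <- if (abs(r) < 1) r * sqrt(df_c / (1 - r^2)) else sign(r) * Inf
  p_classic <- 2 * stats::pt(abs(t_c), df_c, lower.tail = FALSE)
  structure(list(statistic = c(t = tstat),
                 parameter = c(df = df),
                 estimate = c(cor = r),
                 p.value = p,
                 ess = unname(ess),
                 n = n,
                 p_classic = p_classic,
                 method = method,
                 data.name = paste(deparse(substitute(x)), "and",
                                   deparse(substitute(y)))),
            class = c("dutilleul_test", "htest"))
}

#' Pairwise correlation report with spatially corrected significance
#'
#' Mirrors a lower-triangular correlation table: Pearson r for every pair of
#' score vectors, with p-values from Dutilleul's modified t-test and a
#' significance marker at the 0.05 level.
#'
#' @param scores Named list of numeric vectors over the same sites.
#' @param coords n x 2 coordinate matrix for those sites.
#' @param n_classes Distance classes for the correction.
#' @return A data.frame with columns `var1, var2, r, ess, p_value, signif`.
#' @export
correlation_report <- function(scores, coords, n_classes = 12) {
  stopifnot(is.list(scores), length(scores) >= 2, !is.null(names(scores)))
  prep <- dutilleul_prep(coords, n_classes)
  nm <- names(scores)
  rows <- list()
  for (i in seq_along(nm)[-1]) for (j in seq_len(i - 1)) {
    tt <- dutilleul_test(scores[[i]], scores[[j]], prep = prep)
    rows[[length(rows) + 1L]] <- data.frame(
      var1 = nm[i], var2 = nm[j], r = unname(tt$estimate),
      ess = tt$ess, p_value = tt$p.value,
      signif = ifelse(tt$p.value < 0.05, "*", ""))
  }
  do.call(rbind, rows)
}
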