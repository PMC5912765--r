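#' Bootstrap CV% curve over a marker-count grid
#'
#' For each marker count m on the grid, draws B resamples of m band
#' columns (with replacement by default), computes the full pairwise
#' Jaccard dissimilarity matrix per resample, and per individual pair
#' the coefficient of variation CV_ij = 100 * sd / mean over the B
#' sampled dissimilarities. The per-m summary is the median of CV_ij
#' over eligible pairs — pairs whose mean dissimilarity is zero
#' (effectively identical individuals) are excluded, and so are pairs
#' undefined in a given resample (no shared or differing presences;
#' their CV uses the remaining resamples).
#'
#' @param x an \code{ssr_matrix}.
#' @param grid increasing integer vector of marker counts (default
#'   3, 6, 9, ... up to the total band count).
#' @param B resamples per grid point (>= 2).
#' @param seed integer seed.
#' @param replace sample columns with replacement (bootstrap, default)
#'   or without (subsampling; grid then limited to the band count).
#' @param pooled if TRUE, compute one CV per resample across the
#'   pooled vector of all pairwise dissimilarities and take the median
#'   over resamples, instead of the default per-pair CV summarized by
#'   the median over pairs.
#' @return List of class \code{sufficiency_curve} with \code{grid},
#'   \code{cv} (median CV% per grid point), \code{n_pairs_used},
#'   \code{B}, \code{seed}, \code{replace}.
#' @export
cv_curve <- function(x, grid = NULL, B = 1000L, seed = 1L, replace = TRUE,
                     pooled = FALSE) {
  L <- ncol(x)
  if (is.null(grid)) grid <- seq(3L, L, by = 3L)
  grid <- as.integer(grid)
  if (any(diff(grid) <= 0L)) stop("grid must be strictly increasing")
  if (any(grid < 1L) || any(grid > L))
    stop("grid values must lie in [1, total band count]")
  if (B < 2L) stop("B must be >= 2")
  n <- nrow(x)
  ut <- upper.tri(matrix(0, n, n))
  set.seed(seed)
  cv_med <- numeric(length(grid))
  used <- integer(length(grid))
  for (k in seq_along(grid)) {
    m <- grid[k]
    s1 <- s0 <- s2 <- numeric(sum(ut))
    cv_rep <- numeric(B)
    for (b in seq_len(B)) {
      cols <- sample.int(L, m, replace = replace)
      ct <- jaccard_counts(x[, cols, drop = FALSE])
      denom <- ct$a + ct$b + ct$cc
      d <- 1 - ct$a / denom     # NaN where a pair is undefined
      dv <- d[ut]
      ok <- is.finite(dv)
      if (pooled) {
        cv_rep[b] <- if (sum(ok) >= 2 && mean(dv[ok]) > 0)
          100 * stats::sd(dv[ok]) / mean(dv[ok]) else NA_real_
      }
      s0[ok] <- s0[ok] + 1
      s1[ok] <- s1[ok] + dv[ok]
      s2[ok] <- s2[ok] + dv[ok]^2
    }
    if (pooled) {
      if (all(is.na(cv_rep)))
        stop("all resamples degenerate at m = ", m, ": insufficient signal")
      cv_med[k] <- stats::median(cv_rep, na.rm = TRUE)
      used[k] <- sum(!is.na(cv_rep))
      next
    }
    mu <- s1 / s0
    vr <- pmax(0, (s2 - s1^2 / s0) / (s0 - 1))
    eligible <- s0 >= 2 & mu > 0
    if (!any(eligible))
      stop("all pairs excluded at m = ", m, ": insufficient signal")
    cvp <- 100 * sqrt(vr[eligible]) / mu[eligible]
    cv_med[k] <- stats::median(cvp)
    used[k] <- sum(eligible)
  }
  structure(list(grid = grid, cv = cv_med, n_pairs_used = used,
                 B = as.integer(B), seed = as.integer(seed),
                 replace = replace),
            class = "sufficiency_curve")
}

#' Fit a decay model to a CV curve
#'
#' Default model is the power law CV(m) = a * m^b, fitted by least
#' squares of log CV on log m — sampling theory for means of m
#' resampled markers gives CV proportional to m^(-1/2), so b near
#' -0.5 is expected. An exponential alternative
#' CV(m) = a * exp(b * m) + c is available. Non-positive CV points are
#' excluded with a warning; at least 3 usable points are required.
#'
#' @param curve a \code{sufficiency_curve}.
#' @param model \code{"power"} (default) or \code{"exponential"}.
#' @return List of class \code{sufficiency_fit}: \code{a}, \code{b}
#'   (and \code{c} for the exponential), \code{model}, \code{fitted}
#'   values on the grid, and the input curve.
#' @export
fit_decay <- function(curve, model = c("power", "exponential")) {
  model <- match.arg(model)
  stopifnot(inherits(curve, "sufficiency_curve"))
  keep <- curve$cv > 0
  if (any(!keep)) warning(sum(!keep), " non-positive CV point(s) excluded")
  m <- curve$grid[keep]; cv <- curve$cv[keep]
  if (length(m) < 3L) stop("need at least 3 usable grid points")
  if (model == "power") {
    fit <- stats::lm(log(cv) ~ log(m))
    a <- exp(unname(coef(fit)[1])); b <- unname(coef(fit)[2])
    fitted <- a * curve$grid^b
    out <- list(a = a, b = b, model = model, fitted = fitted, curve = curve)
  } else {
    start <- list(a = max(cv) - min(cv), b = -1 / stats::median(m), c = min(cv) / 2)
    # scaleOffset keeps convergence testing sane on (near-)exact data
    fit <- stats::nls(cv ~ a * exp(b * m) + c, start = start,
                      control = stats::nls.control(maxiter = 500,
                                                   scaleOffset = 1))
    cf <- coef(fit)
    fitted <- cf["a"] * exp(cf["b"] * curve$grid) + cf["c"]
    out <- list(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
                model = model, fitted = fitted, curve = curve)
  }
  class(out) <- "sufficiency_fit"
  out
}

#' Minimum marker count achieving a CV threshold
#'
#' Inverts the fitted decay curve: the smallest integer m with fitted
#' CV(m) at or below the threshold.
#'
#' @param fit a \code{sufficiency_fit} with negative decay rate b.
#' @param threshold_pct CV threshold in percent (default 10, the
#'   conventional acceptability cutoff).
#' @return Integer m*.
#' @examples
#' # a = 60, b = -0.5, threshold 10 -> (60/10)^2 = 36 markers
#' @export
markers_for_threshold <- function(fit, threshold_pct = 10) {
  stopifnot(inherits(fit, "sufficiency_fit"))
  if (fit$b >= 0) stop("fitted decay rate b is non-negative: no crossing")
  if (fit$model == "power") {
    if (fit$a <= threshold_pct) return(1L)
    mstar <- as.integer(ceiling((threshold_pct / fit$a)^(1 / fit$b) - 1e-9))
  } else {
    cc <- if (is.null(fit$c)) 0 else fit$c
    if (threshold_pct <= cc)
      stop("threshold below the fitted asymptote (", round(cc, 3), "%)")
    if (fit$a + cc <= threshold_pct) return(1L)
    mstar <- as.integer(ceiling(log((threshold_pct - cc) / fit$a) / fit$b - 1e-9))
  }
  max(mstar, 1L)
}

#' @export
print.sufficiency_curve <- function(x, ...) {
  cat("marker-sufficiency CV curve:", length(x$grid), "grid points,",
      "B =", x$B, "\n")
  print(data.frame(m = x$grid, median_cv_pct = round(x$cv, 3)),
        row.names = FALSE)
  invisible(x)
}

#' @export
print.sufficiency_fit <- function(x, ...) {
  if (x$model == "power")
    cat(sprintf("power-law fit: CV(m) = %.4g * m^%.4g\n", x$a, x$b))
  else
    cat(sprintf("exponential fit: CV(m) = %.4g * exp(%.4g m) + %.4g\n",
                x$a, x$b, x$c))
  invisible(x)
}
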