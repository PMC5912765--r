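#' Evanno delta-K from a table of clustering-run log-likelihoods
#'
#' Implements the second-difference statistic used to choose the
#' number of subpopulations K from repeated Bayesian clustering runs:
#' with L(K) the mean log probability of the data over runs at K,
#' L'(K) = L(K) - L(K-1), |L''(K)| = |L'(K+1) - L'(K)| and
#' deltaK = |L''(K)| / sd(lnP at K), defined for interior K only. The
#' second difference uses per-K means, and the run-to-run standard
#' deviation is the sample (n-1) form. The best K is the interior K
#' maximizing deltaK (ties broken toward the smallest K); runs with
#' zero spread give an undefined (flagged) deltaK.
#'
#' @param table data.frame with columns \code{K} (integer >= 1) and
#'   \code{lnP} (log probability of data), one row per run; an
#'   optional \code{run} column is ignored. Needs >= 3 consecutive K
#'   values with >= 2 runs each.
#' @return List of class \code{evanno_table}: a per-K data.frame
#'   (\code{K}, \code{reps}, \code{mean_lnP}, \code{sd_lnP},
#'   \code{Lp}, \code{absLpp}, \code{deltaK}) and \code{best_K} (NA if
#'   deltaK is undefined everywhere).
#' @export
delta_k <- function(table) {
  if (!all(c("K", "lnP") %in% names(table)))
    stop("table needs columns K and lnP")
  ks <- sort(unique(table$K))
  if (length(ks) < 3L) stop("need at least 3 distinct K values")
  if (!all(diff(ks) == 1L)) stop("K grid has gaps: ", paste(ks, collapse = ", "))
  reps <- vapply(ks, function(k) sum(table$K == k), integer(1))
  if (any(reps < 2L))
    stop("need >= 2 runs per K; short at K = ",
         paste(ks[reps < 2L], collapse = ", "))
  mu <- vapply(ks, function(k) mean(table$lnP[table$K == k]), numeric(1))
  sdv <- vapply(ks, function(k) stats::sd(table$lnP[table$K == k]), numeric(1))
  nk <- length(ks)
  Lp <- c(NA, diff(mu))                             # L'(K) = L(K) - L(K-1)
  absLpp <- rep(NA_real_, nk)
  interior <- 2:(nk - 1)
  absLpp[interior] <- abs(Lp[interior + 1] - Lp[interior])
  dk <- rep(NA_real_, nk)
  dk[interior] <- ifelse(sdv[interior] > 0,
                         absLpp[interior] / sdv[interior], NA_real_)
  out <- data.frame(K = ks, reps = reps, mean_lnP = mu, sd_lnP = sdv,
                    Lp = Lp, absLpp = absLpp, deltaK = dk)
  best <- if (all(is.na(dk))) NA_integer_ else ks[which.max(dk)]
  structure(list(table = out, best_K = best), class = "evanno_table")
}

#' @export
print.evanno_table <- function(x, ...) {
  print(transform(x$table, mean_lnP = round(mean_lnP, 2),
                  sd_lnP = round(sd_lnP, 3), deltaK = round(deltaK, 3)),
        row.names = FALSE)
  cat("best K:", x$best_K, "\n")
  invisible(x)
}

#' Read a run-likelihood table (K, run, lnP) from CSV
#' @param path CSV with columns K, run (optional), lnP.
#' @return data.frame suitable for \code{\link{delta_k}}.
#' @export
read_run_likelihoods <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("K", "lnP") %in% names(df)))
    stop("expected columns K and lnP in ", path)
  df
}
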