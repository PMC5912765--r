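#' Squared molecular distance between two band profiles
#'
#' Squared Euclidean distance on 0/1 profiles, i.e. the band mismatch
#' count — the standard choice for binary dominant data. With missing
#' calls the raw mismatch count m over the c compared bands is rescaled
#' to L * m / c for total band count L, keeping distances comparable
#' across pairs; it equals the plain mismatch count on complete data.
#'
#' @param xv,yv 0/1/NA vectors over the same band list.
#' @return The (rescaled) squared distance.
#' @export
squared_distance <- function(xv, yv) {
  if (length(xv) != length(yv)) stop("vectors must share the band list")
  ok <- !is.na(xv) & !is.na(yv)
  cc <- sum(ok)
  if (cc == 0L) stop("no bands compared: distance undefined")
  length(xv) * sum(xv[ok] != yv[ok]) / cc
}

# full pairwise squared-distance matrix (vectorized)
squared_distance_matrix <- function(x) {
  ct <- jaccard_counts(x)
  mism <- ct$b + ct$cc
  if (any(ct$compared == 0))
    stop("pair(s) with no compared bands: squared distance undefined")
  d2 <- ncol(x) * mism / ct$compared
  diag(d2) <- 0
  dimnames(d2) <- list(rownames(x), rownames(x))
  d2
}

# sums of squares and variance components from a squared-distance
# matrix and a group index list; core of both the observed statistic
# and each permutation
amova_components <- function(d2, idx) {
  N <- nrow(d2)
  G <- length(idx)
  ng <- lengths(idx)
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within <- sum(vapply(idx, function(i)
    sum(d2[i, i, drop = FALSE]) / 2 / length(i), numeric(1)))
  ss_among <- ss_total - ss_within
  df_among <- G - 1L
  df_within <- N - G
  ms_among <- ss_among / df_among
  sigma_within <- ss_within / df_within
  n0 <- (N - sum(ng^2) / N) / df_among
  sigma_among <- (ms_among - sigma_within) / n0
  denom <- sigma_among + sigma_within
  list(ss_total = ss_total, ss_within = ss_within, ss_among = ss_among,
       df_among = df_among, df_within = df_within,
       sigma_among = sigma_among, sigma_within = sigma_within,
       phi = if (denom == 0) NA_real_ else sigma_among / denom)
}

#' One-level analysis of molecular variance (AMOVA) with Phi-ST
#'
#' Partitions squared molecular distances among versus within
#' predefined groups. Variance components follow the classical
#' weighted ANOVA estimators; Phi-ST = sigma2_among / (sigma2_among +
#' sigma2_within). Significance is tested by permuting individuals
#' among groups with group sizes fixed; p = (1 + #{permuted Phi >=
#' observed}) / (n_permutations + 1). A negative among-group component
#' (hence slightly negative Phi) is reported as-is, not truncated.
#'
#' @param x an \code{ssr_matrix}.
#' @param partition an \code{ssr_partition} with >= 2 groups, each of
#'   size >= 2.
#' @param n_permutations number of label permutations (>= 99).
#' @param seed integer seed for the permutations.
#' @return List of class \code{amova_table}: a per-stratum data.frame
#'   (df, SS, variance component, percent of variation), \code{phi_st},
#'   \code{p_value}, \code{n_permutations}, \code{seed}.
#' @export
amova <- function(x, partition, n_permutations = 1023L, seed = 1L) {
  lv <- levels(partition)
  if (length(lv) < 2L) stop("AMOVA needs at least two groups")
  sizes <- table(partition)
  if (any(sizes < 2L))
    stop("singleton group(s): ", paste(lv[sizes < 2L], collapse = ", "))
  if (n_permutations < 99L) stop("use at least 99 permutations")
  d2 <- squared_distance_matrix(x)
  labels <- as.character(partition[rownames(x)])
  idx <- lapply(setNames(nm = lv), function(g) which(labels == g))
  obs <- amova_components(d2, idx)
  if (is.na(obs$phi))
    stop("all individuals identical: Phi-ST undefined")

  set.seed(seed)
  phi_perm <- vapply(seq_len(n_permutations), function(k) {
    perm <- sample(labels)
    amova_components(d2, lapply(setNames(nm = lv),
                                function(g) which(perm == g)))$phi
  }, numeric(1))
  p <- (1 + sum(phi_perm >= obs$phi, na.rm = TRUE)) / (n_permutations + 1)

  denom <- obs$sigma_among + obs$sigma_within
  strata <- data.frame(
    stratum = c("among groups", "within groups", "total"),
    df = c(obs$df_among, obs$df_within, obs$df_among + obs$df_within),
    SS = c(obs$ss_among, obs$ss_within, obs$ss_total),
    variance = c(obs$sigma_among, obs$sigma_within, denom),
    pct_variation = c(100 * obs$sigma_among / denom,
                      100 * obs$sigma_within / denom, 100),
    stringsAsFactors = FALSE)
  structure(list(strata = strata, phi_st = obs$phi, p_value = p,
                 n_permutations = n_permutations, seed = seed,
                 groups = lv, group_sizes = as.integer(sizes)),
            class = "amova_table")
}

#' @export
print.amova_table <- function(x, ...) {
  cat("AMOVA (", paste(x$groups, collapse = " vs "), ")\n", sep = "")
  print(transform(x$strata, SS = round(SS, 3), variance = round(variance, 4),
                  pct_variation = round(pct_variation, 2)), row.names = FALSE)
  cat(sprintf("Phi-ST = %.4f, p = %.4g (%d permutations, seed %d)\n",
              x$phi_st, x$p_value, x$n_permutations, x$seed))
  invisible(x)
}

#' AMOVA for a list of two-group contrasts
#'
#' Runs \code{\link{amova}} on each named group pair, excluding all
#' other individuals — the layout used to contrast a cultivar pool
#' against each germplasm group in turn.
#'
#' @param x an \code{ssr_matrix}.
#' @param partition an \code{ssr_partition}.
#' @param pairs list of length-2 character vectors of group labels.
#' @param n_permutations,seed passed to \code{\link{amova}}; each
#'   contrast gets a seed offset so contrasts are independently
#'   reproducible.
#' @return Named list of \code{amova_table}s ("g1_vs_g2").
#' @export
pairwise_group_amovas <- function(x, partition, pairs,
                                  n_permutations = 1023L, seed = 1L) {
  res <- list()
  for (k in seq_along(pairs)) {
    pr <- pairs[[k]]
    if (length(pr) != 2L) stop("each contrast must name two groups")
    if (pr[1] == pr[2]) stop("contrast of a group with itself: ", pr[1])
    missing <- setdiff(pr, levels(partition))
    if (length(missing)) stop("unknown group(s): ", paste(missing, collapse = ", "))
    keep <- names(partition)[partition %in% pr]
    sub <- ssr_matrix(x[keep, , drop = FALSE][, colSums(x[keep, , drop = FALSE] == 1L,
                                                        na.rm = TRUE) > 0L, drop = FALSE])
    part <- ssr_partition(setNames(as.character(partition[keep]), keep), sub)
    res[[paste(pr, collapse = "_vs_")]] <-
      amova(sub, part, n_permutations, seed + k)
  }
  res
}
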