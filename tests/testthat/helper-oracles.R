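# Independent oracles, written before (and kept apart from) the
# implementation paths they check.

# Jaccard complement by explicit set arithmetic on presence sets
oracle_jaccard_pair <- function(xi, xj) {
  ok <- which(!is.na(xi) & !is.na(xj))
  si <- intersect(which(xi == 1L), ok)
  sj <- intersect(which(xj == 1L), ok)
  u <- length(union(si, sj))
  if (u == 0L) return(NA_real_)
  1 - length(intersect(si, sj)) / u
}

oracle_jaccard_matrix <- function(x) {
  n <- nrow(x)
  D <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- oracle_jaccard_pair(x[i, ], x[j, ])
  D
}

# brute-force AMOVA from first principles: explicit pairwise loops for
# the squared distances, then the one-level variance-component algebra
oracle_amova <- function(x, groups) {
  n <- nrow(x); L <- ncol(x)
  d2 <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- !is.na(x[i, ]) & !is.na(x[j, ])
    d2[i, j] <- L * sum(x[i, ok] != x[j, ok]) / sum(ok)
  }
  gl <- unique(groups); G <- length(gl)
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ss_total <- ss_total + d2[i, j]
  ss_total <- ss_total / n
  ss_within <- 0
  for (g in gl) {
    idx <- which(groups == g)
    acc <- 0
    for (i in idx) for (j in idx) if (i < j) acc <- acc + d2[i, j]
    ss_within <- ss_within + acc / length(idx)
  }
  ss_among <- ss_total - ss_within
  sigma_w <- ss_within / (n - G)
  n0 <- (n - sum(table(groups)^2) / n) / (G - 1)
  sigma_a <- (ss_among / (G - 1) - sigma_w) / n0
  list(ss_total = ss_total, ss_within = ss_within, ss_among = ss_among,
       sigma_among = sigma_a, sigma_within = sigma_w,
       phi = sigma_a / (sigma_a + sigma_w))
}

# random binary panel with every band present somewhere and every
# individual carrying at least one band
random_panel <- function(n, L, p = 0.3, miss = 0, seed = 1) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(n * L, 1L, p), n, L)
    if (miss > 0) m[runif(n * L) < miss] <- NA
    m <- m[, colSums(m == 1L, na.rm = TRUE) > 0L, drop = FALSE]
    if (ncol(m) >= 3L && all(rowSums(m == 1L, na.rm = TRUE) > 0L)) break
  }
  rownames(m) <- sprintf("I%02d", seq_len(n))
  colnames(m) <- sprintf("PA.%04d", 100L + seq_len(ncol(m)))
  m
}

# random unrooted tree with positive branch lengths and its additive
# (path-length) distance matrix
random_additive <- function(n_leaves, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n_leaves, br = NULL))
  tr$edge.length <- runif(nrow(tr$edge), 0.5, 2)
  D <- ape::cophenetic.phylo(tr)
  ord <- order(rownames(D))
  list(tree = tr, D = D[ord, ord])
}
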