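#' Neighbor-joining tree from a dissimilarity matrix
#'
#' Classical Saitou-Nei agglomeration with the Studier-Keppler
#' rate-corrected Q criterion: at each step the pair minimizing
#' Q_ij = (r - 2) d_ij - R_i - R_j is joined (ties broken by the
#' lexicographically smallest label pair, internal nodes being ranked
#' by their smallest descendant leaf), limb lengths come from the
#' standard formulas, and distances to the new node are
#' (d_ik + d_jk - d_ij) / 2. Exact on additive matrices. Negative
#' branch lengths are retained with a warning rather than clamped,
#' since clamping silently distorts path distances.
#'
#' @param D labeled symmetric dissimilarity matrix, >= 3 taxa.
#' @return An unrooted \code{ape::phylo} tree with branch lengths.
#' @export
neighbor_joining <- function(D) {
  check_square_distance(D)
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  dm <- D
  # each active node: a Newick fragment and its smallest descendant leaf
  nwk <- rownames(D)
  rep_leaf <- rownames(D)
  fmt <- function(z) format(z, digits = 15, scientific = FALSE, trim = TRUE)
  any_negative <- FALSE

  while (nrow(dm) > 3L) {
    r <- nrow(dm)
    R <- rowSums(dm)
    Q <- (r - 2) * dm - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)) & upper.tri(Q),
                  arr.ind = TRUE)
    key <- apply(cand, 1, function(ij)
      paste(sort(rep_leaf[ij]), collapse = "\r"))
    pick <- cand[order(key)[1], ]
    i <- min(pick); j <- max(pick)
    li <- dm[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- dm[i, j] - li
    if (li < 0 || lj < 0) any_negative <- TRUE
    new_nwk <- paste0("(", nwk[i], ":", fmt(li), ",", nwk[j], ":", fmt(lj), ")")
    new_rep <- min(rep_leaf[i], rep_leaf[j])
    dk <- (dm[i, ] + dm[j, ] - dm[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    rep_leaf <- c(rep_leaf[keep], new_rep)
    rownames(dm) <- colnames(dm) <- rep_leaf
  }
  # three-point closure
  la <- (dm[1, 2] + dm[1, 3] - dm[2, 3]) / 2
  lb <- (dm[1, 2] + dm[2, 3] - dm[1, 3]) / 2
  lc <- (dm[1, 3] + dm[2, 3] - dm[1, 2]) / 2
  if (any(c(la, lb, lc) < 0)) any_negative <- TRUE
  text <- paste0("(", nwk[1], ":", fmt(la), ",", nwk[2], ":", fmt(lb),
                 ",", nwk[3], ":", fmt(lc), ");")
  if (any_negative) warning("negative branch length(s) retained")
  ape::read.tree(text = text)
}

#' Neighbor-joining tree with marker-bootstrap support
#'
#' Builds the NJ tree on the full Jaccard dissimilarity matrix, then
#' resamples band columns with replacement B times; each replicate
#' yields its own Jaccard + NJ tree, and every internal edge of the
#' main tree is annotated with the percentage of replicates containing
#' the same leaf bipartition. Replicates in which some pair has no
#' shared or differing presences are skipped and counted; more than
#' 10\% skipped is an error.
#'
#' @param x an \code{ssr_matrix} with >= 3 individuals.
#' @param B number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @return The main \code{phylo} tree with \code{node.label} holding
#'   integer support percentages and attributes \code{B_used} /
#'   \code{B_skipped}.
#' @export
bootstrap_nj <- function(x, B = 1000L, seed = 1L) {
  if (B < 1L) stop("B must be >= 1")
  main <- neighbor_joining(jaccard_matrix(x))
  set.seed(seed)
  reps <- list()
  skipped <- 0L
  for (b in seq_len(B)) {
    cols <- sample.int(ncol(x), ncol(x), replace = TRUE)
    # replicate trees only feed bipartition counts; their negative-length
    # warnings are noise
    t_b <- tryCatch(
      suppressWarnings(neighbor_joining(jaccard_matrix(x[, cols, drop = FALSE]))),
      error = function(e) NULL)
    if (is.null(t_b)) skipped <- skipped + 1L else reps[[length(reps) + 1L]] <- t_b
  }
  if (skipped > 0.1 * B)
    stop(skipped, " of ", B, " bootstrap replicates had undefined pairs (> 10%)")
  if (skipped > 0L)
    message(skipped, " bootstrap replicate(s) skipped (undefined pairs)")
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  main$node.label <- round(100 * counts / length(reps))
  attr(main, "B_used") <- length(reps)
  attr(main, "B_skipped") <- skipped
  main
}

#' Principal coordinate analysis (classical metric MDS)
#'
#' Gower double-centering of -d^2/2 followed by eigendecomposition.
#' Coordinates are returned for positive eigenvalues only (eigenvector
#' scaled by the square root of its eigenvalue); percent explained is
#' relative to the sum of positive eigenvalues. Non-Euclidean inputs
#' (typical for Jaccard distances) produce negative eigenvalues, which
#' are counted and reported but not corrected by default.
#'
#' @param D labeled symmetric dissimilarity matrix.
#' @param n_axes number of axes to return (default: all positive);
#'   truncated with a warning if it exceeds the positive-eigenvalue
#'   count.
#' @return List of class \code{pcoa_result}: \code{coordinates}
#'   (individuals x axes), \code{eigenvalues} (descending, all),
#'   \code{percent_explained} (positive axes, sums to 100),
#'   \code{negative_count}.
#' @export
pcoa <- function(D, n_axes = NULL) {
  check_square_distance(D)
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- 1e-9 * max(1, abs(eig$values[1]))
  pos <- which(eig$values > tol)
  neg <- sum(eig$values < -tol)
  if (length(pos) == 0L) {
    coords <- matrix(numeric(0), n, 0, dimnames = list(rownames(D), NULL))
    pct <- numeric(0)
  } else {
    coords <- sweep(eig$vectors[, pos, drop = FALSE], 2,
                    sqrt(eig$values[pos]), `*`)
    dimnames(coords) <- list(rownames(D), paste0("Axis", seq_along(pos)))
    pct <- 100 * eig$values[pos] / sum(eig$values[pos])
  }
  if (!is.null(n_axes)) {
    if (n_axes > ncol(coords)) {
      warning("only ", ncol(coords), " positive axes available; truncating")
      n_axes <- ncol(coords)
    }
    coords <- coords[, seq_len(n_axes), drop = FALSE]
    pct <- pct[seq_len(n_axes)]
  }
  structure(list(coordinates = coords, eigenvalues = eig$values,
                 percent_explained = pct, negative_count = neg),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("PCoA:", ncol(x$coordinates), "positive axes,",
      x$negative_count, "negative eigenvalues\n")
  if (length(x$percent_explained))
    cat("percent explained:",
        paste(round(x$percent_explained[seq_len(min(5, length(x$percent_explained)))], 2),
              collapse = ", "), "...\n")
  invisible(x)
}
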