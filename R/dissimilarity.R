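#' Jaccard-complement dissimilarity between two band vectors
#'
#' Over bands scored in both individuals, with a = shared presences,
#' b and c = presences unique to either: similarity = a/(a+b+c) and
#' d = 1 - similarity. Joint absences carry no signal — important for
#' dominant markers, where 0 is uninformative. Bands missing in either
#' member are dropped (pairwise deletion).
#'
#' @param xv,yv 0/1/NA vectors over the same band list.
#' @return List with \code{d} and \code{compared} (bands non-missing in
#'   both).
#' @export
jaccard_pair <- function(xv, yv) {
  if (length(xv) != length(yv)) stop("vectors must share the band list")
  ok <- !is.na(xv) & !is.na(yv)
  a <- sum(xv[ok] == 1L & yv[ok] == 1L)
  b <- sum(xv[ok] == 1L & yv[ok] == 0L)
  cc <- sum(xv[ok] == 0L & yv[ok] == 1L)
  if (a + b + cc == 0L)
    stop("Jaccard dissimilarity undefined: no shared or differing presences")
  list(d = 1 - a / (a + b + cc), compared = sum(ok))
}

# vectorized a/b/c counts for all pairs; returns list of n x n matrices
jaccard_counts <- function(x) {
  N1 <- (!is.na(x)) * (x == 1L); N1[is.na(N1)] <- 0
  N0 <- (!is.na(x)) * (x == 0L); N0[is.na(N0)] <- 0
  a <- tcrossprod(N1)
  b <- tcrossprod(N1, N0)
  obs <- tcrossprod(N1 + N0)
  list(a = a, b = b, cc = t(b), compared = obs)
}

#' Pairwise Jaccard-complement dissimilarity matrix
#'
#' @param x an \code{ssr_matrix} (or plain 0/1/NA matrix with
#'   rownames) with at least two individuals.
#' @return Labeled symmetric matrix of dissimilarities with zero
#'   diagonal and a \code{compared} attribute (per-pair count of bands
#'   non-missing in both members).
#' @export
jaccard_matrix <- function(x) {
  if (nrow(x) < 2L) stop("need at least two individuals")
  ct <- jaccard_counts(x)
  denom <- ct$a + ct$b + ct$cc
  und <- denom == 0
  diag(und) <- FALSE
  if (any(und)) {
    idx <- which(und, arr.ind = TRUE)[1, ]
    stop("Jaccard dissimilarity undefined for pair (",
         rownames(x)[idx[1]], ", ", rownames(x)[idx[2]],
         "): no shared or differing presences")
  }
  d <- 1 - ct$a / denom
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  attr(d, "compared") <- ct$compared
  d
}

#' Within- and between-group dissimilarity summary
#'
#' Within-group mean over all unordered member pairs; between-group
#' mean over all cross pairs; singleton groups have undefined within
#' means (NA, flagged).
#'
#' @param D labeled symmetric dissimilarity matrix.
#' @param partition an \code{ssr_partition} covering the labels.
#' @return List of class \code{group_dissimilarity} with \code{within}
#'   (named vector), \code{between} (symmetric group matrix, within
#'   means on the diagonal), and \code{singleton} flags.
#' @export
group_summary <- function(D, partition) {
  gs <- levels(partition)
  idx <- lapply(setNames(nm = gs), function(g)
    match(names(partition)[partition == g], rownames(D)))
  within <- vapply(gs, function(g) {
    i <- idx[[g]]
    if (length(i) < 2L) return(NA_real_)
    mean(D[i, i][upper.tri(D[i, i])])
  }, numeric(1))
  between <- matrix(NA_real_, length(gs), length(gs), dimnames = list(gs, gs))
  diag(between) <- within
  if (length(gs) > 1L) {
    for (i in seq_along(gs)[-1]) for (j in seq_len(i - 1L)) {
      m <- mean(D[idx[[gs[i]]], idx[[gs[j]]]])
      between[i, j] <- between[j, i] <- m
    }
  }
  structure(list(within = within, between = between,
                 singleton = vapply(idx, length, integer(1)) < 2L),
            class = "group_dissimilarity")
}

#' @export
print.group_dissimilarity <- function(x, ...) {
  cat("group dissimilarity summary (within on diagonal):\n")
  print(round(x$between, 3))
  if (any(x$singleton))
    cat("singleton group(s), within undefined:",
        paste(names(x$singleton)[x$singleton], collapse = ", "), "\n")
  invisible(x)
}

#' Mean dissimilarity of one accession to a group
#'
#' @param D labeled symmetric dissimilarity matrix.
#' @param partition an \code{ssr_partition}.
#' @param accession individual label (excluded from its own
#'   comparison if a group member).
#' @param group group label.
#' @return Mean of d(accession, m) over group members m != accession.
#' @export
accession_vs_group <- function(D, partition, accession, group) {
  if (!accession %in% rownames(D)) stop("unknown accession: ", accession)
  if (!group %in% levels(partition)) stop("unknown group: ", group)
  members <- setdiff(names(partition)[partition == group], accession)
  if (length(members) == 0L)
    stop("no group members to compare '", accession, "' against")
  mean(D[accession, members])
}

#' Extreme dissimilarity pairs
#'
#' Global (or within one group) off-diagonal argmin and argmax; ties
#' are broken by lexicographic order of the sorted label pair.
#'
#' @param D labeled symmetric dissimilarity matrix.
#' @param partition optional \code{ssr_partition}, required with
#'   \code{within}.
#' @param within optional group label restricting the search.
#' @return List with \code{min} and \code{max}, each a list
#'   \code{(pair, value)}.
#' @export
extreme_pairs <- function(D, partition = NULL, within = NULL) {
  labels <- rownames(D)
  if (!is.null(within)) {
    if (is.null(partition)) stop("'within' filtering needs a partition")
    labels <- names(partition)[partition == within]
  }
  if (length(labels) < 2L) stop("need at least two eligible individuals")
  sub <- D[labels, labels]
  ut <- which(upper.tri(sub), arr.ind = TRUE)
  pairs <- data.frame(i = labels[ut[, 1]], j = labels[ut[, 2]],
                      d = sub[ut], stringsAsFactors = FALSE)
  key <- mapply(function(a, b) paste(sort(c(a, b)), collapse = "\r"),
                pairs$i, pairs$j)
  pick <- function(row) list(pair = sort(c(row$i, row$j)), value = row$d)
  list(min = pick(pairs[order(pairs$d, key)[1], ]),
       max = pick(pairs[order(-pairs$d, key)[1], ]))
}
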