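#' Band (allele) frequencies for one primer
#'
#' The frequency of a band is the number of its present calls divided
#' by the total number of present calls the primer produced in the
#' subset — band occurrences over total band occurrences, so the
#' frequencies of a primer sum to one.
#'
#' @param x an \code{ssr_matrix}.
#' @param primer primer label.
#' @param subset optional character vector of individual labels
#'   (default: all individuals).
#' @return Named numeric vector of frequencies, one per band of the
#'   primer, summing to 1.
#' @export
band_frequencies <- function(x, primer, subset = NULL) {
  cols <- primer_cols(x, primer)
  rows <- if (is.null(subset)) seq_len(nrow(x)) else {
    unknown <- setdiff(subset, rownames(x))
    if (length(unknown)) stop("unknown individuals: ", paste(unknown, collapse = ", "))
    match(subset, rownames(x))
  }
  if (length(rows) == 0L) stop("empty subset")
  counts <- colSums(x[rows, cols, drop = FALSE] == 1L, na.rm = TRUE)
  tot <- sum(counts)
  if (tot == 0L)
    stop("no present calls for primer '", primer, "' in the subset; frequencies undefined")
  counts / tot
}

#' Polymorphism Information Content from band frequencies
#'
#' PIC = 1 - sum_i p_i^2 - sum_{i<j} 2 p_i^2 p_j^2 (Botstein form with
#' strictly ordered pairs).
#'
#' @param p numeric vector of frequencies summing to 1 (within 1e-9).
#' @return PIC in [0, 1); 0 iff a single band carries all calls.
#' @examples
#' pic(c(0.5, 0.5)) # 0.375
#' @export
pic <- function(p) {
  if (abs(sum(p) - 1) > 1e-9)
    stop("frequencies must sum to 1 (got ", format(sum(p)), ")")
  if (any(p < 0)) stop("negative frequency")
  s2 <- sum(p^2)
  s4 <- sum(p^4)
  1 - s2 - (s2^2 - s4) # (sum p^2)^2 - sum p^4 = 2 * sum_{i<j} p_i^2 p_j^2
}

# carrier proportion M_b per band of a primer, missing excluded band-wise
band_carrier_proportion <- function(x, primer, rows = seq_len(nrow(x))) {
  cols <- primer_cols(x, primer)
  sub <- x[rows, cols, drop = FALSE]
  colSums(sub == 1L, na.rm = TRUE) / colSums(!is.na(sub))
}

#' Multiplex ratio, polymorphic fraction and effective multiplex ratio
#'
#' The multiplex ratio n is the mean number of bands amplified per
#' individual at the primer (individuals with any missing call at the
#' primer are excluded from the mean); beta is the fraction of the
#' primer's bands that are polymorphic (carrier proportion strictly
#' between 0 and 1); the effective multiplex ratio is E = n * beta.
#'
#' @inheritParams band_frequencies
#' @return List with elements \code{n}, \code{beta}, \code{E}.
#' @export
multiplex_and_effective <- function(x, primer, subset = NULL) {
  cols <- primer_cols(x, primer)
  rows <- if (is.null(subset)) seq_len(nrow(x)) else match(subset, rownames(x))
  sub <- x[rows, cols, drop = FALSE]
  complete <- rowSums(is.na(sub)) == 0L
  if (!any(complete))
    stop("no individual with complete data at primer '", primer, "'")
  n <- mean(rowSums(sub[complete, , drop = FALSE]))
  M <- band_carrier_proportion(x, primer, rows)
  beta <- mean(M > 0 & M < 1)
  list(n = n, beta = beta, E = n * beta)
}

#' Marker index
#'
#' MI = PIC * E, the product of polymorphism information content and
#' effective multiplex ratio; no rounding is applied.
#'
#' @param pic_value PIC estimate.
#' @param e_value effective multiplex ratio.
#' @return The product.
#' @examples
#' round(marker_index(0.720, 2.938), 3) # 2.115
#' @export
marker_index <- function(pic_value, e_value) {
  stopifnot(is.finite(pic_value), is.finite(e_value))
  pic_value * e_value
}

#' Resolving power of a primer
#'
#' Per band, the information content is Ib = 1 - 2 * |0.5 - M| with M
#' the carrier proportion (missing calls excluded band-wise); the
#' resolving power is Rp = sum_b Ib, maximal for bands carried by half
#' the individuals.
#'
#' @inheritParams band_frequencies
#' @return List with \code{Rp} and the per-band \code{Ib} vector.
#' @export
resolving_power <- function(x, primer, subset = NULL) {
  rows <- if (is.null(subset)) seq_len(nrow(x)) else match(subset, rownames(x))
  M <- band_carrier_proportion(x, primer, rows)
  Ib <- 1 - 2 * abs(0.5 - M)
  list(Rp = sum(Ib), Ib = Ib)
}

#' Profile discrimination of a primer
#'
#' Counts the distinct presence/absence patterns (fingerprints) the
#' primer produces among individuals with no missing call there. The
#' percentage uses the full individual count of the matrix as
#' denominator even when some individuals were excluded for missing
#' data.
#'
#' @inheritParams band_frequencies
#' @return List with \code{distinct_profiles} and \code{profile_pct}.
#' @export
profile_discrimination <- function(x, primer, subset = NULL) {
  cols <- primer_cols(x, primer)
  rows <- if (is.null(subset)) seq_len(nrow(x)) else match(subset, rownames(x))
  sub <- x[rows, cols, drop = FALSE]
  complete <- rowSums(is.na(sub)) == 0L
  if (!any(complete))
    stop("no individual with complete data at primer '", primer, "'")
  patterns <- apply(sub[complete, , drop = FALSE], 1, paste, collapse = "")
  k <- length(unique(patterns))
  list(distinct_profiles = k, profile_pct = 100 * k / length(rows))
}

#' Within-group gene diversity
#'
#' For each primer i, D_i = 1 - sum_j p_ij^2 with p_ij the band
#' frequencies computed within the group; the group's diversity is the
#' arithmetic mean of D_i over primers with at least one present call
#' in the group.
#'
#' @param x an \code{ssr_matrix}.
#' @param partition an \code{ssr_partition}.
#' @param group group label.
#' @return List with \code{group}, per-primer \code{D} (NA where the
#'   primer has no data in the group), and \code{mean_D}.
#' @export
gene_diversity <- function(x, partition, group) {
  if (!group %in% levels(partition)) stop("unknown group: ", group)
  members <- names(partition)[partition == group]
  D <- vapply(primer_names(x), function(pr) {
    p <- tryCatch(band_frequencies(x, pr, members), error = function(e) NULL)
    if (is.null(p)) NA_real_ else 1 - sum(p^2)
  }, numeric(1))
  if (all(is.na(D))) stop("group '", group, "' has no data at any primer")
  list(group = group, D = D, mean_D = mean(D, na.rm = TRUE))
}

#' Per-primer informativeness table for one or more subsets
#'
#' One row per primer and subset with the full index bundle (band count
#' N, PIC, multiplex ratio n, polymorphic fraction beta, effective
#' multiplex ratio E, marker index MI, resolving power Rp, distinct
#' profiles and their percentage), plus a Total/Mean footer per subset
#' (sum of N; means of the indices). Values are stored unrounded;
#' reports conventionally round indices to 3 decimals and percentages
#' to 1.
#'
#' @param x an \code{ssr_matrix}.
#' @param subsets named list of individual-label vectors; default one
#'   subset \code{all} covering every individual.
#' @return A data.frame, footer rows flagged in the \code{primer}
#'   column as \code{"Total"} and \code{"Mean"}.
#' @export
stats_table <- function(x, subsets = list(all = rownames(x))) {
  if (is.null(names(subsets)) || any(names(subsets) == ""))
    stop("subsets must be a named list")
  out <- list()
  for (s in names(subsets)) {
    rows_s <- subsets[[s]]
    per <- lapply(primer_names(x), function(pr) {
      p <- band_frequencies(x, pr, rows_s)
      me <- multiplex_and_effective(x, pr, rows_s)
      rp <- resolving_power(x, pr, rows_s)
      prof <- profile_discrimination(x, pr, rows_s)
      data.frame(subset = s, primer = pr, N = length(p),
                 PIC = pic(p), n = me$n, beta = me$beta, E = me$E,
                 MI = marker_index(pic(p), me$E), Rp = rp$Rp,
                 distinct_profiles = prof$distinct_profiles,
                 profile_pct = prof$profile_pct,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, per)
    footer <- data.frame(
      subset = s, primer = c("Total", "Mean"),
      N = c(sum(tab$N), mean(tab$N)),
      PIC = c(NA, mean(tab$PIC)), n = c(NA, mean(tab$n)),
      beta = c(NA, mean(tab$beta)), E = c(NA, mean(tab$E)),
      MI = c(NA, mean(tab$MI)), Rp = c(NA, mean(tab$Rp)),
      distinct_profiles = c(NA, mean(tab$distinct_profiles)),
      profile_pct = c(NA, mean(tab$profile_pct)),
      stringsAsFactors = FALSE)
    out[[s]] <- rbind(tab, footer)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
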