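#' Per-group present-band sets
#'
#' A band is present in a group if at least one member carries it
#' (missing calls ignored).
#'
#' @param x an \code{ssr_matrix}.
#' @param partition an \code{ssr_partition}.
#' @return Named list of character vectors (band labels, in band
#'   order), one per group.
#' @export
group_presence <- function(x, partition) {
  lapply(setNames(nm = levels(partition)), function(g) {
    members <- names(partition)[partition == g]
    sub <- x[members, , drop = FALSE]
    colnames(x)[colSums(sub == 1L, na.rm = TRUE) > 0L]
  })
}

#' Exclusive (private) alleles per group
#'
#' A band is exclusive to a group when it is present there and in no
#' other group; exclusivity is a presence-set property — a single
#' carrier suffices.
#'
#' @param presence per-group presence sets from
#'   \code{\link{group_presence}}.
#' @param total_bands total number of distinct bands in the panel
#'   (percentage denominator).
#' @return A list per group with \code{bands}, \code{count} and
#'   \code{pct} (of total_bands).
#' @export
exclusive_alleles <- function(presence, total_bands) {
  if (length(presence) < 2L) stop("need at least two groups")
  lapply(setNames(nm = names(presence)), function(g) {
    others <- unique(unlist(presence[setdiff(names(presence), g)]))
    excl <- setdiff(presence[[g]], others)
    list(bands = excl, count = length(excl),
         pct = 100 * length(excl) / total_bands)
  })
}

#' Bands absent from a focal group, attributed to their source groups
#'
#' @param presence per-group presence sets.
#' @param focal_group focal group label.
#' @param total_bands total distinct band count (percentage
#'   denominator).
#' @return List with a per-band attribution data.frame (\code{band},
#'   \code{carried_by} — comma-joined group list, \code{exclusive_to} —
#'   the single carrier group or NA), \code{count} and \code{pct}.
#' @export
absence_report <- function(presence, focal_group, total_bands) {
  if (!focal_group %in% names(presence)) stop("unknown group: ", focal_group)
  all_bands <- unique(unlist(presence))
  absent <- setdiff(all_bands, presence[[focal_group]])
  carriers <- lapply(absent, function(b)
    names(presence)[vapply(presence, function(s) b %in% s, logical(1))])
  df <- data.frame(
    band = absent,
    carried_by = vapply(carriers, paste, character(1), collapse = ","),
    exclusive_to = vapply(carriers, function(g)
      if (length(g) == 1L) g else NA_character_, character(1)),
    stringsAsFactors = FALSE)
  list(bands = df, count = length(absent),
       pct = 100 * length(absent) / total_bands)
}

#' Trace source-exclusive alleles into a target group
#'
#' Finds bands exclusive to \code{source_group} among the non-target
#' groups and lists the target-group individuals carrying them. The
#' target is excluded from the exclusivity comparison: a band private
#' to the source within the germplasm may still occur in the target —
#' that co-occurrence is the tracing signal.
#'
#' @param x an \code{ssr_matrix}.
#' @param partition an \code{ssr_partition}.
#' @param source_group,target_group group labels (distinct).
#' @return data.frame with columns \code{band} and \code{individual}
#'   (one row per carrier); zero rows when nothing is traced.
#' @export
trace_exclusive <- function(x, partition, source_group, target_group) {
  lv <- levels(partition)
  if (!source_group %in% lv) stop("unknown group: ", source_group)
  if (!target_group %in% lv) stop("unknown group: ", target_group)
  if (source_group == target_group) stop("source and target group must differ")
  presence <- group_presence(x, partition)
  others <- setdiff(lv, c(source_group, target_group))
  excl <- setdiff(presence[[source_group]],
                  unique(unlist(presence[others])))
  targets <- names(partition)[partition == target_group]
  hits <- lapply(excl, function(b) {
    carriers <- targets[which(x[targets, b] == 1L)]
    if (length(carriers))
      data.frame(band = b, individual = carriers, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(band = character(0), individual = character(0))
  out
}

#' Full allele ledger for a partitioned panel
#'
#' Bundles total band count, per-group presence and exclusive sets with
#' percentages, and (optionally) a focal-group absence report — the
#' group-occupancy accounting used to compare a cultivated pool against
#' its basic germplasm.
#'
#' @param x an \code{ssr_matrix}.
#' @param partition an \code{ssr_partition}.
#' @param focal_group optional focal group for the absence report.
#' @return List of class \code{allele_ledger}.
#' @export
allele_ledger <- function(x, partition, focal_group = NULL) {
  presence <- group_presence(x, partition)
  total <- ncol(x)
  excl <- exclusive_alleles(presence, total)
  out <- list(total_bands = total,
              presence = presence,
              present_counts = vapply(presence, length, integer(1)),
              exclusive = excl,
              absence = if (!is.null(focal_group))
                absence_report(presence, focal_group, total))
  class(out) <- "allele_ledger"
  out
}

#' @export
print.allele_ledger <- function(x, ...) {
  cat("allele ledger:", x$total_bands, "bands\n")
  for (g in names(x$presence))
    cat(sprintf("  %s: %d present, %d exclusive (%.2f%%)\n", g,
                length(x$presence[[g]]), x$exclusive[[g]]$count,
                x$exclusive[[g]]$pct))
  if (!is.null(x$absence))
    cat(sprintf("  absent from focal group: %d (%.1f%%)\n",
                x$absence$count, x$absence$pct))
  invisible(x)
}
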