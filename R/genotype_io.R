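#' Parse a band identifier of the form PRIMER.SIZE
#'
#' Band (allele) labels combine the amplifying primer pair and the
#' fragment size in base pairs, e.g. \code{"SCB436.0186"}. The size part
#' is zero-padded to four digits on output but unpadded input is
#' accepted.
#'
#' @param x character vector of serialized band labels.
#' @return A data.frame with columns \code{primer} (character) and
#'   \code{size} (integer, base pairs), one row per input label.
#' @examples
#' parse_band_id("SCB436.0186")
#' @export
parse_band_id <- function(x) {
  stopifnot(is.character(x), length(x) >= 1L)
  parts <- strsplit(x, ".", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) != 2L || !grepl("^[0-9]+$", p[2]) || nchar(p[1]) == 0L,
                logical(1))
  if (any(bad)) {
    stop("malformed band label(s): ", paste(x[bad], collapse = ", "),
         " (expected PRIMER.SIZE with numeric size)")
  }
  data.frame(
    primer = vapply(parts, `[`, character(1), 1L),
    size = as.integer(vapply(parts, `[`, character(1), 2L)),
    stringsAsFactors = FALSE
  )
}

#' Serialize band identifiers
#'
#' @param primer character vector of primer labels.
#' @param size integer vector of fragment sizes (bp).
#' @return Character vector "PRIMER.SIZE" with the size zero-padded to
#'   4 digits.
#' @examples
#' format_band_id("SCB436", 186)
#' @export
format_band_id <- function(primer, size) {
  stopifnot(length(primer) == length(size), all(size > 0))
  sprintf("%s.%04d", primer, as.integer(size))
}

#' Construct a binary genotype matrix
#'
#' The central container: individuals in rows, bands (dominant markers)
#' in columns, cells coded 1 = band present, 0 = absent, NA = missing.
#' Each band belongs to exactly one primer, derived from its
#' PRIMER.SIZE column name.
#'
#' @param values numeric/integer matrix of 0/1/NA with unique rownames
#'   (individuals) and colnames (band labels, PRIMER.SIZE form).
#' @return An object of class \code{ssr_matrix}: the integer matrix with
#'   a \code{primer} attribute (character vector, one entry per band).
#' @export
ssr_matrix <- function(values) {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("genotype matrix needs individual rownames and band colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate individual labels: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate band labels: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  vals <- values
  storage.mode(vals) <- "integer"
  ok <- is.na(vals) | vals == 0L | vals == 1L
  if (!all(ok)) {
    idx <- which(!ok, arr.ind = TRUE)[1, ]
    stop("non-ternary cell at individual '", rownames(vals)[idx[1]],
         "', band '", colnames(vals)[idx[2]], "'")
  }
  present <- colSums(vals == 1L, na.rm = TRUE)
  if (any(present == 0L))
    stop("band(s) with no present call: ",
         paste(colnames(vals)[present == 0L], collapse = ", "))
  ids <- parse_band_id(colnames(vals))
  colnames(vals) <- format_band_id(ids$primer, ids$size)
  structure(vals, primer = ids$primer, class = c("ssr_matrix", "matrix"))
}

#' @export
print.ssr_matrix <- function(x, ...) {
  cat("ssr_matrix:", nrow(x), "individuals x", ncol(x), "bands (",
      length(unique(attr(x, "primer"))), "primers,",
      sum(is.na(x)), "missing cells )\n")
  invisible(x)
}

#' Primer label of each band
#' @param x an \code{ssr_matrix}.
#' @return Character vector, one primer label per band column.
#' @export
band_primers <- function(x) attr(x, "primer")

#' Primer labels present in a matrix, in band order
#' @param x an \code{ssr_matrix}.
#' @export
primer_names <- function(x) unique(attr(x, "primer"))

# columns of a given primer; errors on unknown primer
primer_cols <- function(x, primer) {
  cols <- which(attr(x, "primer") == primer)
  if (length(cols) == 0L) stop("unknown primer: ", primer)
  cols
}

#' Construct a group partition
#'
#' Assigns every individual of a genotype matrix to exactly one named
#' group. Group order is first-appearance order in the input.
#'
#' @param groups character vector of group labels named by individual.
#' @param matrix optional \code{ssr_matrix}; if given, coverage is
#'   checked (every individual once, no extras).
#' @return A factor of class \code{ssr_partition}, names = individuals,
#'   levels in first-appearance order.
#' @export
ssr_partition <- function(groups, matrix = NULL) {
  if (is.null(names(groups))) stop("groups must be named by individual")
  if (anyDuplicated(names(groups)))
    stop("duplicate individuals in partition: ",
         paste(unique(names(groups)[duplicated(names(groups))]), collapse = ", "))
  lev <- unique(unname(groups)) # first-appearance order, pre-reordering
  if (!is.null(matrix)) {
    miss <- setdiff(rownames(matrix), names(groups))
    extra <- setdiff(names(groups), rownames(matrix))
    if (length(miss) || length(extra))
      stop("partition does not cover matrix individuals exactly;",
           if (length(miss)) paste0(" missing: ", paste(miss, collapse = ", ")) else "",
           if (length(extra)) paste0(" unknown: ", paste(extra, collapse = ", ")) else "")
    groups <- groups[rownames(matrix)]
  }
  f <- factor(groups, levels = lev)
  names(f) <- names(groups)
  class(f) <- c("ssr_partition", "factor")
  f
}

# delimiter from file extension: .csv -> comma, anything else -> tab
sniff_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a genotype table from delimited text
#'
#' Expects a header row of band labels (PRIMER.SIZE) and a first column
#' of individual labels; cells must be 0, 1 or the missing token
#' (\code{"?"} always accepted as an alias). Emits a loading report
#' (individuals, bands, primers, missing cells) as a message.
#'
#' @param path file path; delimiter sniffed from extension (.csv comma,
#'   otherwise tab).
#' @param missing_token cell value denoting a missing call.
#' @return An \code{ssr_matrix}.
#' @export
read_genotype_table <- function(path, missing_token = "NA") {
  # read.table mangles duplicate header names, so check them raw first
  hdr <- strsplit(readLines(path, n = 1L), sniff_delim(path), fixed = TRUE)[[1]][-1]
  if (anyDuplicated(hdr))
    stop("duplicate band labels in header: ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  raw <- utils::read.table(path, sep = sniff_delim(path), header = TRUE,
                           row.names = NULL, check.names = FALSE,
                           colClasses = "character", na.strings = NULL)
  if (ncol(raw) < 2L) stop("genotype table needs an individual column plus bands")
  inds <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  miss <- vals == missing_token | vals == "?"
  bad <- !(miss | vals == "0" | vals == "1")
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("non-ternary cell '", vals[idx[1], idx[2]], "' at row ", idx[1],
         " (individual '", inds[idx[1]], "'), column '",
         colnames(vals)[idx[2]], "'")
  }
  vals[miss] <- NA
  num <- as.integer(vals)
  dim(num) <- dim(vals)
  rownames(num) <- inds
  colnames(num) <- colnames(vals)
  m <- ssr_matrix(num)
  message(sprintf("loaded %d individuals, %d bands, %d primers, %d missing cells",
                  nrow(m), ncol(m), length(primer_names(m)), sum(is.na(m))))
  m
}

#' Write a genotype table as delimited text
#'
#' Inverse of \code{\link{read_genotype_table}}; round-trips exactly,
#' including missing cells.
#'
#' @param x an \code{ssr_matrix}.
#' @param path output path; delimiter sniffed from extension.
#' @param missing_token token written for missing cells.
#' @export
write_genotype_table <- function(x, path, missing_token = "NA") {
  out <- matrix(as.character(x), nrow(x), ncol(x), dimnames = dimnames(x))
  out[is.na(x)] <- missing_token
  df <- data.frame(individual = rownames(x), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sniff_delim(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a two-column individual-to-group metadata table
#'
#' @param path delimited text file, columns (individual, group), header
#'   optional but recommended.
#' @param matrix the \code{ssr_matrix} the partition must cover.
#' @return An \code{ssr_partition} with group order = first-appearance
#'   order in the file.
#' @export
read_partition <- function(path, matrix) {
  raw <- utils::read.table(path, sep = sniff_delim(path), header = TRUE,
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2L) stop("metadata table needs (individual, group) columns")
  g <- raw[[2]]
  names(g) <- raw[[1]]
  ssr_partition(g, matrix)
}

#' Write a partition as a two-column CSV
#' @param partition an \code{ssr_partition}.
#' @param path output path.
#' @export
write_partition <- function(partition, path) {
  utils::write.table(
    data.frame(individual = names(partition), group = as.character(partition)),
    path, sep = sniff_delim(path), quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_square_distance <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("distance matrix must be square")
  if (is.null(rownames(D))) stop("distance matrix must be labeled")
  if (max(abs(D - t(D))) > 1e-12)
    stop("distance matrix is not symmetric")
  if (max(abs(diag(D))) > 1e-12)
    stop("distance matrix diagonal is not zero")
  invisible(TRUE)
}

#' Write a distance matrix (square CSV or square PHYLIP)
#'
#' @param D labeled symmetric matrix with zero diagonal.
#' @param path output path.
#' @param format \code{"square-csv"} (header row and label column) or
#'   \code{"phylip"} (first line N, then label + N values per row).
#' @export
write_distance_matrix <- function(D, path, format = c("square-csv", "phylip")) {
  format <- match.arg(format)
  check_square_distance(D)
  if (format == "square-csv") {
    df <- data.frame(label = rownames(D), D, check.names = FALSE)
    utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  } else {
    lines <- c(format(nrow(D)),
               vapply(seq_len(nrow(D)), function(i) {
                 paste(c(rownames(D)[i], format(D[i, ], digits = 10)),
                       collapse = "  ")
               }, character(1)))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a square-CSV distance matrix written by
#' \code{\link{write_distance_matrix}}
#' @param path path to a square CSV with a label column.
#' @return Labeled symmetric matrix.
#' @export
read_distance_matrix <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  D <- as.matrix(raw[, -1, drop = FALSE])
  rownames(D) <- raw[[1]]
  check_square_distance(D)
  D
}
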