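#' Read a plain-text key=value analysis configuration
#'
#' Lines of the form \code{key = value}; blank lines and \code{#}
#' comments ignored. Recognized keys: \code{genotypes}, \code{groups},
#' \code{out_dir}, \code{contrasts} (comma-separated \code{g1:g2}
#' pairs), \code{focal_group}, \code{perms}, \code{boots},
#' \code{suff_step}, \code{suff_reps}, \code{threshold}, \code{seed}.
#'
#' @param path configuration file.
#' @return Named list.
#' @export
read_analysis_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  cfg <- setNames(lapply(kv, function(p) trimws(p[2])),
                  vapply(kv, function(p) trimws(p[1]), character(1)))
  for (k in c("perms", "boots", "suff_step", "suff_reps", "seed"))
    if (!is.null(cfg[[k]])) cfg[[k]] <- as.integer(cfg[[k]])
  if (!is.null(cfg$threshold)) cfg$threshold <- as.numeric(cfg$threshold)
  if (!is.null(cfg$contrasts))
    cfg$contrasts <- lapply(strsplit(cfg$contrasts, ",")[[1]],
                            function(s) trimws(strsplit(s, ":")[[1]]))
  cfg
}

#' Run the full dominant-SSR analysis pipeline
#'
#' Orchestrates stats -> allele accounting -> Jaccard distances ->
#' AMOVA contrasts -> bootstrap NJ tree -> PCoA -> marker sufficiency
#' from one configuration, writing a report bundle of plain CSV/Newick
#' artifacts plus a JSON manifest recording the package version, seeds
#' and parameters (sufficient to reproduce every output). One global
#' seed fans out to fixed per-stage offsets so stages can be rerun
#' independently yet deterministically. Any stage failure aborts with
#' the stage name; partial outputs of the failed run are removed.
#'
#' @param config named list (see \code{\link{read_analysis_config}})
#'   or path to a config file. Required: \code{genotypes},
#'   \code{groups} (file paths) or \code{matrix}/\code{partition}
#'   objects, \code{out_dir}, \code{seed}.
#' @return Invisibly, the manifest list.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  if (is.null(config$seed)) stop("config must set a seed")
  if (is.null(config$out_dir)) stop("config must set out_dir")
  perms <- if (is.null(config$perms)) 1023L else config$perms
  boots <- if (is.null(config$boots)) 100L else config$boots
  step <- if (is.null(config$suff_step)) 3L else config$suff_step
  reps <- if (is.null(config$suff_reps)) 100L else config$suff_reps
  thr <- if (is.null(config$threshold)) 10 else config$threshold
  seed <- as.integer(config$seed)

  if (!is.null(config$matrix)) {
    x <- config$matrix; part <- config$partition
  } else {
    x <- read_genotype_table(config$genotypes)
    part <- read_partition(config$groups, x)
  }
  contrasts <- config$contrasts
  if (is.null(contrasts) && length(levels(part)) >= 2L)
    contrasts <- utils::combn(levels(part), 2, simplify = FALSE)
  bad <- setdiff(unique(unlist(contrasts)), levels(part))
  if (length(bad))
    stop("config names unknown group(s): ", paste(bad, collapse = ", "))
  focal <- config$focal_group
  if (!is.null(focal) && !focal %in% levels(part))
    stop("config names unknown focal group: ", focal)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(name) {
    p <- file.path(config$out_dir, name)
    written <<- c(written, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  hdr <- function(path, stage_name, params) {
    cat(sprintf("# domssr %s | %s\n", stage_name, params), file = path)
  }

  stage("stats", {
    tab <- stats_table(x, c(list(all = rownames(x)),
                            lapply(setNames(nm = levels(part)),
                                   function(g) names(part)[part == g])))
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], function(v) round(v, 3))
    p <- emit("stats.csv")
    hdr(p, "stats", "indices rounded to 3 dp")
    suppressWarnings(utils::write.table(tab, p, sep = ",", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
  })

  stage("accounting", {
    led <- allele_ledger(x, part, focal_group = focal)
    sumdf <- data.frame(group = names(led$presence),
                        present = led$present_counts,
                        exclusive = vapply(led$exclusive, `[[`, integer(1), "count"),
                        exclusive_pct = round(vapply(led$exclusive, `[[`,
                                                     numeric(1), "pct"), 2))
    p <- emit("accounting_summary.csv")
    hdr(p, "accounting", paste0("total_bands=", led$total_bands))
    suppressWarnings(utils::write.table(sumdf, p, sep = ",", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
    excl <- do.call(rbind, lapply(names(led$exclusive), function(g) {
      b <- led$exclusive[[g]]$bands
      if (length(b)) data.frame(group = g, band = b)
    }))
    if (is.null(excl)) excl <- data.frame(group = character(0), band = character(0))
    utils::write.csv(excl, emit("exclusive_bands.csv"), row.names = FALSE,
                     quote = FALSE)
  })

  D <- stage("distance", {
    D <- jaccard_matrix(x)
    write_distance_matrix(D, emit("distance.csv"), "square-csv")
    gs <- group_summary(D, part)
    utils::write.csv(round(gs$between, 4), emit("group_dissimilarity.csv"),
                     quote = FALSE)
    D
  })

  stage("amova", {
    tabs <- pairwise_group_amovas(x, part, contrasts,
                                  n_permutations = perms, seed = seed + 1L)
    rows <- do.call(rbind, lapply(names(tabs), function(nm) {
      t <- tabs[[nm]]
      cbind(contrast = nm, t$strata,
            phi_st = round(t$phi_st, 4), p_value = t$p_value)
    }))
    p <- emit("amova.csv")
    hdr(p, "amova", sprintf("perms=%d seed=%d", perms, seed + 1L))
    suppressWarnings(utils::write.table(rows, p, sep = ",", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
  })

  stage("tree", {
    tr <- suppressWarnings(bootstrap_nj(x, B = boots, seed = seed + 2L))
    ape::write.tree(tr, emit("tree.nwk"))
  })

  stage("pcoa", {
    pc <- pcoa(D)
    utils::write.csv(round(pc$coordinates, 6), emit("pcoa_coordinates.csv"),
                     quote = FALSE)
    utils::write.csv(data.frame(eigenvalue = round(pc$eigenvalues, 8)),
                     emit("pcoa_eigenvalues.csv"), row.names = FALSE,
                     quote = FALSE)
  })

  mstar <- stage("sufficiency", {
    grid <- seq(step, ncol(x), by = step)
    curve <- cv_curve(x, grid = grid, B = reps, seed = seed + 3L)
    # tiny or degenerate panels (many constant pairs) may leave too few
    # positive CV points to fit; the curve is still reported
    fit <- tryCatch(suppressWarnings(fit_decay(curve)),
                    error = function(e) NULL)
    mstar <- if (is.null(fit)) NA else
      tryCatch(markers_for_threshold(fit, thr), error = function(e) NA)
    p <- emit("sufficiency.csv")
    hdr(p, "sufficiency",
        sprintf("B=%d seed=%d a=%s b=%s m*=%s", reps, seed + 3L,
                if (is.null(fit)) "NA" else sprintf("%.5g", fit$a),
                if (is.null(fit)) "NA" else sprintf("%.5g", fit$b),
                as.character(mstar)))
    suppressWarnings(utils::write.table(
      data.frame(m = curve$grid, median_cv_pct = round(curve$cv, 4),
                 fitted_cv_pct = if (is.null(fit)) NA else
                   round(fit$fitted, 4)),
      p, sep = ",", quote = FALSE, row.names = FALSE, append = TRUE))
    mstar
  })

  manifest <- list(
    package = "domssr",
    version = as.character(utils::packageVersion("domssr")),
    seed = seed,
    stage_seeds = list(amova = seed + 1L, tree = seed + 2L,
                       sufficiency = seed + 3L),
    parameters = list(perms = perms, boots = boots, suff_step = step,
                      suff_reps = reps, threshold = thr,
                      contrasts = lapply(contrasts, paste, collapse = ":"),
                      focal_group = focal),
    inputs = list(genotypes = config$genotypes, groups = config$groups,
                  individuals = nrow(x), bands = ncol(x),
                  primers = length(primer_names(x))),
    sufficiency_mstar = mstar,
    artifacts = basename(written))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
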