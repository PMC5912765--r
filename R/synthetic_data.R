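#' Configuration for the synthetic dominant-marker panel generator
#'
#' Defaults emulate the structure of a large sugarcane germplasm panel:
#' three core groups of 81 (cultivars), 19 and 26 accessions plus 11
#' admixed hybrid individuals, 12 primers amplifying between 10 and 43
#' bands each (roughly 285 bands in total), a fifth of the bands
#' private to a single group, and a low missing-call rate.
#'
#' @param group_sizes integer vector of core group sizes (one group per
#'   entry; labels G1, G2, ...).
#' @param n_primers number of SSR primer pairs.
#' @param bands_per_primer length-2 integer range; each primer's band
#'   count is drawn uniformly from it (min must be >= 2).
#' @param baseline_beta shape1/shape2 of the Beta distribution for
#'   baseline within-group band presence frequencies.
#' @param divergence number in [0,1]; 0 makes all groups share the
#'   baseline frequencies, 1 gives each group independent frequencies.
#' @param private_band_fraction fraction of bands forced private to a
#'   single group (frequency 0 elsewhere).
#' @param n_hybrids number of admixed individuals appended as their own
#'   "HYB" group.
#' @param hybrid_mixture mixture weights over the core groups for
#'   hybrid band-presence probabilities (default equal weights).
#' @param missing_rate per-cell independent missing probability in
#'   [0, 1).
#' @param seed integer seed; the panel is fully reproducible from it.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(group_sizes = c(81L, 19L, 26L),
                       n_primers = 12L,
                       bands_per_primer = c(10L, 43L),
                       baseline_beta = c(1.2, 3),
                       divergence = 0.35,
                       private_band_fraction = 0.2,
                       n_hybrids = 11L,
                       hybrid_mixture = NULL,
                       missing_rate = 0.01,
                       seed = 1L) {
  G <- length(group_sizes)
  if (G < 1L || any(group_sizes < 1L)) stop("group sizes must be positive")
  if (n_primers < 1L) stop("need at least one primer")
  if (length(bands_per_primer) != 2L || bands_per_primer[1] < 2L ||
      bands_per_primer[2] < bands_per_primer[1])
    stop("bands_per_primer must be an increasing range with min >= 2")
  if (any(baseline_beta <= 0)) stop("Beta shapes must be positive")
  if (divergence < 0 || divergence > 1) stop("divergence must be in [0,1]")
  if (private_band_fraction < 0 || private_band_fraction > 1)
    stop("private_band_fraction must be in [0,1]")
  if (n_hybrids < 0L) stop("n_hybrids must be >= 0")
  if (is.null(hybrid_mixture)) hybrid_mixture <- rep(1 / G, G)
  if (length(hybrid_mixture) != G || any(hybrid_mixture < 0) ||
      abs(sum(hybrid_mixture) - 1) > 1e-9)
    stop("hybrid_mixture must be ", G, " non-negative weights summing to 1")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0,1)")
  structure(list(group_sizes = as.integer(group_sizes),
                 n_primers = as.integer(n_primers),
                 bands_per_primer = as.integer(bands_per_primer),
                 baseline_beta = baseline_beta,
                 divergence = divergence,
                 private_band_fraction = private_band_fraction,
                 n_hybrids = as.integer(n_hybrids),
                 hybrid_mixture = hybrid_mixture,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a dominant-marker panel with known truth
#'
#' Each band b in group g has a latent presence probability
#' f_gb = (1 - divergence) * p_b + divergence * t_gb, where p_b is a
#' shared baseline draw and t_gb an independent per-group draw from the
#' same Beta distribution. A fraction of bands is made private: the
#' owner group keeps a moderate-to-high frequency, all other groups get
#' exactly 0. Non-degenerate frequencies are truncated to [0.02, 0.98]
#' to avoid accidental monomorphism; exact 0/1 values are kept so that
#' fixed differences stay fixed. Hybrids draw each band with
#' probability sum_g w_g f_gb and are appended as group "HYB". Cells
#' are set missing independently; bands ending up with no present call
#' are dropped and recorded in the truth.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return A list with \code{matrix} (\code{ssr_matrix}),
#'   \code{partition} (\code{ssr_partition}) and \code{truth} (latent
#'   frequencies, private-band table, hybrid identities and mixture,
#'   dropped bands, the config).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  G <- length(cfg$group_sizes)
  groups <- paste0("G", seq_len(G))

  nb <- sample(seq(cfg$bands_per_primer[1], cfg$bands_per_primer[2]),
               cfg$n_primers, replace = TRUE)
  primers <- sprintf("P%02d", seq_len(cfg$n_primers))
  band_ids <- unlist(lapply(seq_len(cfg$n_primers), function(i)
    format_band_id(rep(primers[i], nb[i]), 100L + 2L * seq_len(nb[i]))))
  L <- length(band_ids)

  # shapes at or below 0.01 are treated as the limiting point-mass
  # mixture (Bernoulli on {0,1}), so maximal-differentiation panels
  # with exactly fixed bands are expressible
  draw_freq <- function(n) {
    s <- cfg$baseline_beta
    if (all(s <= 0.01)) as.numeric(runif(n) < s[1] / (s[1] + s[2]))
    else rbeta(n, s[1], s[2])
  }
  p0 <- draw_freq(L)
  f <- matrix(NA_real_, G, L, dimnames = list(groups, band_ids))
  for (g in seq_len(G)) {
    tg <- draw_freq(L)
    f[g, ] <- (1 - cfg$divergence) * p0 + cfg$divergence * tg
  }

  n_priv <- round(cfg$private_band_fraction * L)
  priv <- data.frame(band = character(0), owner = character(0))
  if (n_priv > 0L) {
    priv_idx <- sample.int(L, n_priv)
    owner <- sample(groups, n_priv, replace = TRUE)
    f[, priv_idx] <- 0
    for (k in seq_len(n_priv))
      f[owner[k], priv_idx[k]] <- runif(1, 0.3, 0.9)
    priv <- data.frame(band = band_ids[priv_idx], owner = owner,
                       stringsAsFactors = FALSE)
  }
  # keep exact fixation (private absences, point-mass limits); nudge
  # everything else away from accidental monomorphism
  f[f > 0 & f < 0.02] <- 0.02
  f[f < 1 & f > 0.98] <- 0.98

  ind_names <- unlist(lapply(seq_len(G), function(g)
    sprintf("%s_%03d", groups[g], seq_len(cfg$group_sizes[g]))))
  rows <- lapply(seq_len(G), function(g) {
    n <- cfg$group_sizes[g]
    matrix(rbinom(n * L, 1L, rep(f[g, ], each = n)), n, L)
  })
  part_labels <- rep(groups, cfg$group_sizes)
  hybrid_ids <- character(0)
  if (cfg$n_hybrids > 0L) {
    fh <- as.numeric(cfg$hybrid_mixture %*% f)
    hybrid_ids <- sprintf("HYB_%03d", seq_len(cfg$n_hybrids))
    rows <- c(rows, list(matrix(rbinom(cfg$n_hybrids * L, 1L,
                                       rep(fh, each = cfg$n_hybrids)),
                                cfg$n_hybrids, L)))
    ind_names <- c(ind_names, hybrid_ids)
    part_labels <- c(part_labels, rep("HYB", cfg$n_hybrids))
  }
  vals <- do.call(rbind, rows)
  dimnames(vals) <- list(ind_names, band_ids)

  if (cfg$missing_rate > 0) {
    vals[runif(length(vals)) < cfg$missing_rate] <- NA_integer_
  }

  keep <- colSums(vals == 1L, na.rm = TRUE) > 0L
  dropped <- band_ids[!keep]
  vals <- vals[, keep, drop = FALSE]

  part <- ssr_partition(setNames(part_labels, ind_names))
  m <- ssr_matrix(vals)
  truth <- list(freq = f[, keep, drop = FALSE],
                private_bands = priv[priv$band %in% colnames(vals), , drop = FALSE],
                hybrid_ids = hybrid_ids,
                hybrid_mixture = cfg$hybrid_mixture,
                dropped_bands = dropped,
                config = cfg)
  list(matrix = m, partition = part, truth = truth)
}

#' The fixed six-individual worked-example panel
#'
#' Two groups of three individuals, two primers, five bands. Small
#' enough that every downstream statistic can be checked by hand.
#'
#' @return A list with \code{matrix} and \code{partition}.
#' @examples
#' toy6()$matrix
#' @export
toy6 <- function() {
  bands <- c("P1.0100", "P1.0110", "P1.0120", "P2.0200", "P2.0210")
  vals <- rbind(
    A1 = c(1L, 1L, 0L, 1L, 0L),
    A2 = c(1L, 1L, 0L, 1L, 0L),
    A3 = c(1L, 0L, 0L, 1L, 0L),
    B1 = c(0L, 0L, 1L, 0L, 1L),
    B2 = c(0L, 1L, 1L, 0L, 1L),
    B3 = c(0L, 0L, 1L, 0L, 1L))
  colnames(vals) <- bands
  part <- ssr_partition(setNames(rep(c("A", "B"), each = 3), rownames(vals)))
  list(matrix = ssr_matrix(vals), partition = part)
}
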