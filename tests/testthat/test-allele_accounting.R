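t6 <- toy6()

test_that("group presence, exclusivity and absence on the worked example", {
  pres <- group_presence(t6$matrix, t6$partition)
  expect_equal(pres$A, c("P1.0100", "P1.0110", "P2.0200"))
  expect_equal(pres$B, c("P1.0110", "P1.0120", "P2.0210"))
  excl <- exclusive_alleles(pres, 5)
  expect_equal(excl$A$bands, c("P1.0100", "P2.0200"))
  expect_equal(excl$A$pct, 40)
  expect_equal(excl$B$bands, c("P1.0120", "P2.0210"))
  ab <- absence_report(pres, "A", 5)
  expect_setequal(ab$bands$band, c("P1.0120", "P2.0210"))
  expect_equal(ab$pct, 40)
  expect_equal(ab$bands$exclusive_to, c("B", "B"))
  # printed percentage convention: 39 exclusive of 285 total
  expect_equal(round(100 * 39 / 285, 2), 13.68)
  expect_equal(round(100 * 119 / 285, 1), 41.8)
})

test_that("single-group partition owns every band; dominated groups own none", {
  x <- t6$matrix
  one <- ssr_partition(setNames(rep("all", 6), rownames(x)))
  expect_equal(group_presence(x, one)$all, colnames(x))
  # a group holding all bands leaves nothing exclusive to the rest
  vals <- rbind(big1 = c(1L, 1L, 1L), big2 = c(1L, 1L, 1L),
                sm1 = c(1L, 0L, 0L), sm2 = c(0L, 1L, 0L))
  colnames(vals) <- sprintf("Z.%04d", 1:3)
  m <- ssr_matrix(vals)
  p <- ssr_partition(setNames(c("big", "big", "small", "small"),
                              rownames(vals)))
  excl <- exclusive_alleles(group_presence(m, p), 3)
  expect_equal(excl$small$count, 0)
})

test_that("classification invariants hold on simulated panels", {
  s <- simulate_panel(sim_config(group_sizes = c(20, 20, 20), n_primers = 3,
                                 bands_per_primer = c(6, 12),
                                 n_hybrids = 5, missing_rate = 0.02,
                                 seed = 21))
  pres <- group_presence(s$matrix, s$partition)
  total <- ncol(s$matrix)
  # every band present somewhere
  expect_setequal(unique(unlist(pres)), colnames(s$matrix))
  excl <- exclusive_alleles(pres, total)
  sets <- lapply(excl, `[[`, "bands")
  # exclusive sets pairwise disjoint and bounded by presence sets
  for (g in names(sets)) {
    expect_true(all(sets[[g]] %in% pres[[g]]))
    for (h in setdiff(names(sets), g))
      expect_length(intersect(sets[[g]], sets[[h]]), 0)
  }
  n_excl <- sum(lengths(sets))
  # exclusive-to-one plus shared-by->=2 partitions the band set
  shared <- total - n_excl
  occupancy <- rowSums(vapply(pres, function(s_) colnames(s$matrix) %in% s_,
                              logical(total)))
  expect_equal(sum(occupancy == 1), n_excl)
  expect_equal(sum(occupancy >= 2), shared)
  for (g in levels(s$partition)) {
    ab <- absence_report(pres, g, total)
    expect_equal(length(pres[[g]]) + ab$count, total)
  }
})

test_that("exclusive alleles recover the simulated truth with no missing data", {
  s <- simulate_panel(sim_config(group_sizes = c(30, 30, 30), n_primers = 4,
                                 bands_per_primer = c(8, 14),
                                 private_band_fraction = 0.25,
                                 n_hybrids = 0, missing_rate = 0, seed = 5))
  excl <- exclusive_alleles(group_presence(s$matrix, s$partition),
                            ncol(s$matrix))
  truth <- s$truth$private_bands
  expect_gt(nrow(truth), 0)
  for (k in seq_len(nrow(truth)))
    expect_true(truth$band[k] %in% excl[[truth$owner[k]]]$bands)
})

test_that("trace_exclusive finds source-private bands inside the target group", {
  # worked example plus one mosaic individual carrying a group-A private
  # band: exclusivity is judged among the non-target groups only
  x <- rbind(unclass(t6$matrix), H1 = c(1L, 0L, 1L, 0L, 0L))
  m <- ssr_matrix(x)
  p <- ssr_partition(setNames(c(rep(c("A", "B"), each = 3), "C"),
                              rownames(x)))
  tr <- trace_exclusive(m, p, "A", "C")
  expect_equal(tr$band, "P1.0100")
  expect_equal(tr$individual, "H1")
  # no signal -> empty table with the same shape (disjoint band sets)
  dis <- rbind(x1 = c(1L, 1L, 0L), x2 = c(1L, 0L, 0L),
               y1 = c(0L, 0L, 1L), y2 = c(0L, 0L, 1L))
  colnames(dis) <- sprintf("D.%04d", 1:3)
  md <- ssr_matrix(dis)
  pd <- ssr_partition(setNames(rep(c("X", "Y"), each = 2), rownames(dis)))
  tr0 <- trace_exclusive(md, pd, "X", "Y")
  expect_equal(nrow(tr0), 0)
  expect_named(tr0, c("band", "individual"))
  expect_error(trace_exclusive(m, p, "A", "Z"), "unknown group")
  expect_error(trace_exclusive(m, p, "A", "A"), "must differ")
})

test_that("traced carriers match hybrid provenance on simulated panels", {
  # hybrids mix G1 and G2; bands private to G1 among the core groups can
  # surface in hybrids, and every traced carrier must genuinely carry
  # the band
  s <- simulate_panel(sim_config(group_sizes = c(25, 25), n_primers = 3,
                                 bands_per_primer = c(8, 12),
                                 private_band_fraction = 0.3,
                                 n_hybrids = 10,
                                 hybrid_mixture = c(0.5, 0.5),
                                 missing_rate = 0, seed = 13))
  tr <- trace_exclusive(s$matrix, s$partition, "G1", "HYB")
  if (nrow(tr) > 0) {
    expect_true(all(tr$individual %in% s$truth$hybrid_ids))
    for (k in seq_len(nrow(tr)))
      expect_equal(s$matrix[tr$individual[k], tr$band[k]], 1L,
                   ignore_attr = TRUE)
    # a band traced from G1 must be absent from every G2 individual
    g2 <- names(s$partition)[s$partition == "G2"]
    expect_true(all(s$matrix[g2, unique(tr$band)] == 0L))
  }
  expect_true(nrow(trace_exclusive(s$matrix, s$partition, "G2", "HYB")) >= 0)
})
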