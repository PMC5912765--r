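t6 <- toy6()
x6 <- t6$matrix

test_that("band frequencies divide occurrences by the primer total", {
  expect_equal(unname(band_frequencies(x6, "P1")), rep(1 / 3, 3))
  expect_equal(unname(band_frequencies(x6, "P2", c("A1", "A2", "A3"))),
               c(1, 0))
  expect_equal(sum(band_frequencies(x6, "P1")), 1)
  expect_error(band_frequencies(x6, "P9"), "unknown primer")
  expect_error(band_frequencies(x6, "P2", character(0)), "empty subset")
})

test_that("PIC follows the Botstein closed form", {
  expect_equal(pic(1), 0)
  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_equal(pic(rep(1 / 3, 3)), 16 / 27)
  # permutation invariance and upper bound on random frequency vectors
  set.seed(1)
  for (k in 1:20) {
    p <- runif(sample(2:8, 1))
    p <- p / sum(p)
    expect_equal(pic(p), pic(sample(p)))
    expect_lt(pic(p), 1)
  }
  expect_error(pic(c(0.5, 0.4)), "sum to 1")
})

test_that("multiplex ratios and E = n * beta on the worked example", {
  m1 <- multiplex_and_effective(x6, "P1")
  expect_equal(m1$n, 1.5) # row band counts 2,2,1,1,2,1
  expect_equal(m1$beta, 1)
  expect_equal(m1$E, 1.5)
  m2 <- multiplex_and_effective(x6, "P2")
  expect_equal(m2$n, 1)
  expect_equal(m2$E, 1)
  # a monomorphic-present band contributes beta = 0
  y <- ssr_matrix(cbind(x6, matrix(1L, 6, 1,
                                   dimnames = list(NULL, "P3.0300"))))
  m3 <- multiplex_and_effective(y, "P3")
  expect_equal(m3$beta, 0)
  expect_equal(m3$E, 0)
  # individuals with a missing call at the primer are excluded from n
  z <- unclass(x6)
  z["A1", "P1.0100"] <- NA
  z <- ssr_matrix(z)
  expect_equal(multiplex_and_effective(z, "P1")$n, 7 / 5)
})

test_that("marker index is the exact PIC x E product", {
  expect_equal(round(marker_index(0.720, 2.938), 3), 2.115)
  expect_equal(marker_index(0, 99), 0)
  expect_equal(marker_index(16 / 27, 1.5), 8 / 9)
})

test_that("resolving power sums per-band information contents", {
  expect_equal(resolving_power(x6, "P1")$Rp, 3) # all M = 0.5
  y <- random_panel(10, 15, seed = 5)
  colnames(y) <- sprintf("PB.%04d", 100 + seq_len(ncol(y)))
  ys <- ssr_matrix(y)
  # brute-force recount oracle
  M <- colMeans(y == 1L)
  expect_equal(resolving_power(ys, "PB")$Rp, sum(1 - 2 * abs(0.5 - M)))
  expect_equal(unname(resolving_power(ys, "PB")$Ib),
               unname(1 - 2 * abs(0.5 - M)))
})

test_that("profile discrimination counts distinct complete fingerprints", {
  pr <- profile_discrimination(x6, "P1")
  expect_equal(pr$distinct_profiles, 4) # 110, 100, 001, 011
  expect_equal(pr$profile_pct, 100 * 4 / 6)
  # the denominator stays the full individual count when individuals
  # are dropped for missing data
  z <- unclass(x6)
  z["A1", "P1.0100"] <- NA
  pr2 <- profile_discrimination(ssr_matrix(z), "P1")
  expect_equal(pr2$profile_pct, 100 * pr2$distinct_profiles / 6)
  # all-identical fingerprints collapse to one profile
  w <- ssr_matrix(matrix(1L, 4, 2,
                         dimnames = list(paste0("i", 1:4),
                                         c("Q.0001", "Q.0002"))))
  expect_equal(profile_discrimination(w, "Q")$distinct_profiles, 1)
})

test_that("gene diversity is 1 - sum p^2 per primer, averaged", {
  gd <- gene_diversity(x6, t6$partition, "A")
  expect_equal(unname(gd$D["P1"]), 0.48) # within-A counts 3,2,0
  expect_equal(unname(gd$D["P2"]), 0)
  expect_equal(gd$mean_D, 0.24)
  # k equifrequent bands give 1 - 1/k
  for (k in c(2, 5, 8)) {
    vals <- diag(k)
    storage.mode(vals) <- "integer"
    dimnames(vals) <- list(paste0("i", 1:k),
                           sprintf("EQ.%04d", seq_len(k)))
    m <- ssr_matrix(vals)
    part <- ssr_partition(setNames(rep("g", k), rownames(vals)))
    expect_equal(unname(gene_diversity(m, part, "g")$D["EQ"]), 1 - 1 / k)
  }
  expect_error(gene_diversity(x6, t6$partition, "Z"), "unknown group")
})

test_that("stats_table bundles per-primer rows with a Total/Mean footer", {
  tab <- stats_table(x6)
  expect_equal(nrow(tab), 4) # 2 primers + Total + Mean
  body <- tab[tab$primer %in% c("P1", "P2"), ]
  expect_equal(tab$N[tab$primer == "Total"], 5)
  expect_equal(tab$N[tab$primer == "Mean"], 2.5)
  # stored identities hold exactly, pre-rounding
  expect_equal(body$E, body$n * body$beta)
  expect_equal(body$MI, body$PIC * body$E)
  # multiple subsets stack
  tab2 <- stats_table(x6, list(all = rownames(x6), A = paste0("A", 1:3)))
  expect_equal(nrow(tab2), 8)
  expect_equal(tab2$PIC[tab2$subset == "A" & tab2$primer == "P2"], 0)
})

test_that("stats_table identities hold on simulated panels", {
  s <- simulate_panel(sim_config(group_sizes = c(15, 15), n_primers = 4,
                                 bands_per_primer = c(5, 10), n_hybrids = 0,
                                 missing_rate = 0.02, seed = 9))
  tab <- stats_table(s$matrix)
  body <- tab[!tab$primer %in% c("Total", "Mean"), ]
  expect_equal(body$E, body$n * body$beta)
  expect_equal(body$MI, body$PIC * body$E)
  expect_true(all(body$Rp >= 0 & body$Rp <= body$N))
  expect_true(all(body$distinct_profiles <=
                    pmin(nrow(s$matrix), 2^body$N)))
  for (pr in primer_names(s$matrix))
    expect_equal(sum(band_frequencies(s$matrix, pr)), 1)
})
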