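t6 <- toy6()

test_that("squared distance is the (rescaled) mismatch count", {
  x6 <- t6$matrix
  expect_equal(squared_distance(x6["A1", ], x6["A1", ]), 0)
  expect_equal(squared_distance(x6["A1", ], x6["B1", ]), 5)
  expect_equal(squared_distance(x6["A1", ], x6["A3", ]), 1)
  # missing rescale: 2 mismatches over 4 compared of 5 total
  a <- c(1L, 0L, 1L, 0L, NA)
  b <- c(0L, 0L, 0L, 0L, 1L)
  expect_equal(squared_distance(a, b), 5 * 2 / 4)
  expect_error(squared_distance(c(NA, NA), c(1L, 0L)), "undefined")
})

test_that("AMOVA equals the brute-force oracle on small instances", {
  # TOY6 plus random instances with N <= 8, two or three groups,
  # with and without missing data
  cases <- list(list(x = unclass(t6$matrix),
                     g = as.character(t6$partition)))
  for (seed in 1:12) {
    n <- sample(4:8, 1)
    x <- random_panel(n, 10, p = 0.4, miss = if (seed %% 3 == 0) 0.1 else 0,
                      seed = 200 + seed)
    G <- if (n >= 6 && seed %% 2 == 0) 3 else 2
    repeat {
      g <- sample(paste0("g", seq_len(G)), n, replace = TRUE)
      if (all(table(factor(g, paste0("g", seq_len(G)))) >= 2)) break
    }
    cases <- c(cases, list(list(x = x, g = g)))
  }
  for (cs in cases) {
    m <- ssr_matrix(cs$x)
    part <- ssr_partition(setNames(cs$g, rownames(cs$x)))
    got <- amova(m, part, n_permutations = 99, seed = 1)
    want <- oracle_amova(cs$x, cs$g)
    expect_equal(got$strata$SS[3], want$ss_total, tolerance = 1e-9)
    expect_equal(got$strata$SS[1], want$ss_among, tolerance = 1e-9)
    expect_equal(got$strata$SS[2], want$ss_within, tolerance = 1e-9)
    expect_equal(got$strata$variance[1], want$sigma_among, tolerance = 1e-9)
    expect_equal(got$strata$variance[2], want$sigma_within, tolerance = 1e-9)
    expect_equal(got$phi_st, want$phi, tolerance = 1e-9)
    # table invariants
    expect_equal(got$strata$df[1] + got$strata$df[2], nrow(cs$x) - 1)
    expect_equal(sum(got$strata$pct_variation[1:2]), 100, tolerance = 1e-6)
    expect_equal(got$strata$pct_variation[1], 100 * got$phi_st,
                 tolerance = 1e-9)
    expect_gte(got$p_value, 1 / 100)
    expect_lte(got$p_value, 1)
  }
})

test_that("fixed differences give Phi = 1 at the minimal p-value", {
  vals <- rbind(matrix(rep(c(1L, 1L, 0L, 0L), each = 8), 8, 4),
                matrix(rep(c(0L, 0L, 1L, 1L), each = 8), 8, 4))
  dimnames(vals) <- list(c(paste0("a", 1:8), paste0("b", 1:8)),
                         sprintf("F.%04d", 1:4))
  m <- ssr_matrix(vals)
  p <- ssr_partition(setNames(rep(c("a", "b"), each = 8), rownames(vals)))
  res <- amova(m, p, n_permutations = 99, seed = 3)
  expect_equal(res$phi_st, 1)
  expect_equal(res$strata$SS[2], 0)
  # only a permutation recreating the exact split can tie Phi = 1; none
  # occurs at this seed, so p sits at the 1/(P+1) floor
  expect_equal(res$p_value, 1 / 100)
})

test_that("guards: singleton groups, degenerate matrices, bad contrasts", {
  x6 <- t6$matrix
  p_bad <- ssr_partition(setNames(c("a", "a", "a", "a", "a", "s"),
                                  rownames(x6)))
  expect_error(amova(x6, p_bad, 99), "singleton")
  same <- ssr_matrix(matrix(1L, 4, 2,
                            dimnames = list(paste0("i", 1:4),
                                            c("S.0001", "S.0002"))))
  ps <- ssr_partition(setNames(c("a", "a", "b", "b"), paste0("i", 1:4)))
  expect_error(amova(same, ps, 99), "identical")
  expect_error(pairwise_group_amovas(x6, t6$partition, list(c("A", "A"))),
               "itself")
  expect_error(pairwise_group_amovas(x6, t6$partition, list(c("A", "Z"))),
               "unknown group")
})

test_that("pairwise contrasts subset individuals and stay additive", {
  s <- simulate_panel(sim_config(group_sizes = c(10, 10, 10), n_primers = 3,
                                 bands_per_primer = c(6, 10),
                                 divergence = 0.6, n_hybrids = 0,
                                 missing_rate = 0, seed = 17))
  tabs <- pairwise_group_amovas(s$matrix, s$partition,
                                list(c("G1", "G2"), c("G1", "G3")),
                                n_permutations = 99, seed = 2)
  expect_named(tabs, c("G1_vs_G2", "G1_vs_G3"))
  for (t_ in tabs) {
    expect_equal(t_$strata$SS[1] + t_$strata$SS[2], t_$strata$SS[3],
                 tolerance = 1e-9)
    expect_equal(sum(t_$group_sizes), 20)
  }
})

test_that("seeded permutation tests are reproducible", {
  s <- simulate_panel(sim_config(group_sizes = c(8, 8), n_primers = 2,
                                 bands_per_primer = c(5, 8),
                                 divergence = 0.3, n_hybrids = 0,
                                 missing_rate = 0, seed = 4))
  r1 <- amova(s$matrix, s$partition, n_permutations = 199, seed = 11)
  r2 <- amova(s$matrix, s$partition, n_permutations = 199, seed = 11)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("permutation p-values are uniform under the null", {
  # one panmictic pool split arbitrarily in two; Kolmogorov-Smirnov on
  # 200 seeded replicates at alpha = 0.01 (scaled to the test budget:
  # 199 permutations on 12 x 15 panels)
  pvals <- vapply(1:200, function(seed) {
    x <- random_panel(12, 15, p = 0.35, seed = 3000 + seed)
    g <- rep(c("a", "b"), each = 6)
    m <- ssr_matrix(x)
    part <- ssr_partition(setNames(g, rownames(x)))
    amova(m, part, n_permutations = 199, seed = seed)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(pvals) - 0.5), 0.1)
})
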