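test_that("size factors recover planted library scalings", {
  # identical columns -> unit factors
  m <- matrix(rep(c(10, 40, 90, 25, 60), 4), ncol = 4)
  expect_equal(unname(size_factors(m)), rep(1, 4))

  # doubling one column doubles its factor relative to the others
  # (raw factors shift together through the geometric-mean reference)
  m2 <- m
  m2[, 3] <- m2[, 3] * 2
  sf2 <- size_factors(m2)
  expect_equal(unname(sf2 / median(sf2)), c(1, 1, 2, 1))

  # planted factors on a 5-gene x 4-sample matrix, zero-dispersion expectation
  base <- c(10, 20, 50, 100, 200)
  f <- c(0.5, 1, 1, 2)
  planted <- outer(base, f)
  sf <- size_factors(planted)
  sf <- sf / median(sf)
  expect_true(all(abs(sf / f - 1) < 0.1))

  # ratios to the per-gene geometric mean cancel a global rescaling exactly,
  # so the factors encode relative depth only
  expect_equal(unname(size_factors(3 * m2)), unname(size_factors(m2)))

  # every gene hits a zero -> no reference gene
  zm <- matrix(c(0, 5, 5, 0), 2, 2)
  expect_error(size_factors(zm), "filter")
})

test_that("size factors agree with an established median-of-ratios oracle", {
  skip_if_not_installed("DESeq2")
  set.seed(42)
  m <- matrix(rnbinom(300, mu = 80, size = 20), nrow = 50)
  m <- sweep(m, 2, c(0.6, 0.9, 1, 1.1, 1.4, 2), "*")
  ours <- unname(size_factors(m))
  ref <- unname(DESeq2::estimateSizeFactorsForMatrix(m))
  # same method up to median-vs-geometric interpolation details
  expect_true(all(abs(ours / ref - 1) < 0.02))
})

test_that("moment dispersion matches hand computations and floors", {
  # zero within-group variance -> floor
  g0 <- matrix(100, 2, 3)
  expect_equal(as.numeric(estimate_dispersion(list(g0, g0))), rep(1e-8, 2))

  # groups (90,100,110) and (95,100,105): variance below mean -> floor
  g1 <- matrix(c(90, 100, 110), 1)
  g2 <- matrix(c(95, 100, 105), 1)
  expect_equal(as.numeric(estimate_dispersion(list(g1, g2))), 1e-8)

  # mean 100, within-group variance 600 -> (600 - 100) / 100^2 = 0.05
  a <- sqrt(600)
  g3 <- matrix(c(100 - a, 100, 100 + a), 1)
  expect_equal(as.numeric(estimate_dispersion(list(g3, g3))), 0.05,
               tolerance = 1e-12)

  # degrees of freedom accumulate over groups
  expect_equal(attr(estimate_dispersion(list(g0, g0, g0)), "df"), 6L)
  expect_error(estimate_dispersion(list(matrix(1, 1, 1))), "2 replicates")
})

test_that("de_test handles degenerate and hand-computable cases", {
  fe <- flat_experiment()
  tab <- de_test(fe$counts, fe$design, "A", 2, "morning")
  expect_equal(tab$log_fc, rep(0, nrow(tab)))
  expect_equal(tab$p_raw, rep(1, nrow(tab)))
  expect_false(any(tab$is_deg))

  # planted normalized means 8 (LD) vs 2 (SD), pseudocount 0 -> logFC = 2
  fe2 <- flat_experiment()
  ld <- subset(fe2$design, genotype == "A" & day == 2 &
                 time_of_day == "morning" & photoperiod == "LD")$sample_id
  sd_ <- subset(fe2$design, genotype == "A" & day == 2 &
                  time_of_day == "morning" & photoperiod == "SD")$sample_id
  fe2$counts["gene001", ld] <- 8L
  fe2$counts["gene001", sd_] <- 2L
  tab2 <- de_test(fe2$counts, fe2$design, "A", 2, "morning", pseudocount = 0)
  expect_equal(tab2$log_fc[tab2$gene_id == "gene001"], 2)

  # genes below the base-mean floor are not tested
  fe3 <- flat_experiment()
  fe3$counts["gene002", ] <- 0L
  fe3$counts["gene002", ld[1]] <- 1L
  tab3 <- de_test(fe3$counts, fe3$design, "A", 2, "morning")
  expect_equal(tab3$p_raw[tab3$gene_id == "gene002"], 1)

  # absent group is reported by its cell
  d_noSD <- subset(fe$design, !(photoperiod == "SD" & genotype == "A" &
                                  day == 2 & time_of_day == "morning"))
  expect_error(de_test(fe$counts[, d_noSD$sample_id], d_noSD,
                       "A", 2, "morning"),
               "SD, A, day 2, morning")
})

test_that("label swap negates logFC and preserves p-values", {
  sim <- simulate_experiment(tiny_config(n_genes = 120, seed = 21))
  tab <- de_test(sim$counts, sim$design, "A", 15, "morning")
  flipped <- sim$design
  flipped$photoperiod <- ifelse(flipped$photoperiod == "LD", "SD", "LD")
  tab_fl <- de_test(sim$counts, flipped, "A", 15, "morning")
  expect_equal(tab_fl$log_fc, -tab$log_fc)
  expect_equal(tab_fl$p_raw, tab$p_raw)
  expect_equal(tab_fl$fdr, tab$fdr)
})

test_that("a global rescaling of counts does not change DE conclusions", {
  # exact invariance cannot hold on the count scale (the logFC pseudocount
  # and the base-mean floor are count-denominated), but for genes above the
  # low-expression floor the results are stable to a depth change
  sim <- simulate_experiment(tiny_config(n_genes = 100, n_low = 0, seed = 22))
  tab <- de_test(sim$counts, sim$design, "B", 21, "afternoon")
  scaled <- sim$counts * 5L
  tab_sc <- de_test(scaled, sim$design, "B", 21, "afternoon")
  expect_identical(tab_sc$is_deg, tab$is_deg)
  expect_lt(max(abs(tab_sc$log_fc - tab$log_fc)), 0.02)
  expect_lt(max(abs(tab_sc$p_raw - tab$p_raw)), 0.05)
})

test_that("BH adjustment matches the step-up oracle and its bounds", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(31)
  for (i in 1:5) {
    p <- switch(i,
                runif(50),
                rbeta(200, 0.3, 1),        # enriched near 0
                rep(0.5, 10),              # massive ties
                c(0, runif(20), 1),
                runif(3))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p))
    expect_true(all(adj >= 0 & adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})
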