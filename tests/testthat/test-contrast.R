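test_that("expression filters drop low and fluctuating genes", {
  fe <- flat_experiment(n_genes = 10)
  # gene001: all zero -> excluded by the mean filter
  fe$counts["gene001", ] <- 0L
  # gene002: one condition with wildly fluctuating replicates (CV > 1)
  s <- subset(fe$design, genotype == "A" & photoperiod == "LD" & day == 2 &
                time_of_day == "morning")$sample_id
  fe$counts["gene002", s] <- c(1L, 100L, 1L)
  eligible <- filter_genes(fe$counts, fe$design)
  expect_false("gene001" %in% eligible)
  expect_false("gene002" %in% eligible)
  # gene003: mean 100, identical replicates (CV 0) -> retained
  fe$counts["gene003", ] <- 100L
  expect_true("gene003" %in% filter_genes(fe$counts, fe$design))
})

test_that("direction-aware ranking orders DEGs as specified", {
  tab <- data.frame(gene_id = c("a", "b", "c"),
                    log_fc = c(2, -1, 0.5),
                    stringsAsFactors = FALSE)
  expect_equal(rank_by_logfc(tab, "LD_first"), c(a = 1L, c = 2L, b = 3L))
  expect_equal(rank_by_logfc(tab, "SD_first"), c(b = 1L, c = 2L, a = 3L))
  # exact logFC ties break lexicographically by gene id
  tie <- data.frame(gene_id = c("b", "a"), log_fc = c(1, 1),
                    stringsAsFactors = FALSE)
  expect_equal(rank_by_logfc(tie, "LD_first"), c(a = 1L, b = 2L))
  empty <- tab[0, ]
  expect_length(rank_by_logfc(empty, "LD_first"), 0)
})

test_that("the best-contrast gene attains the minimum possible score", {
  tabs <- random_table_quartet(30, deg_prob = 1)
  # make gene g0001 extreme in the contrast-consistent direction everywhere
  for (k in 1:4) {
    i <- which(tabs[[k]]$gene_id == "g0001")
    tabs[[k]]$log_fc[i] <- if (k <= 2) 99 else -99
  }
  sc <- contrast_score(tabs)
  expect_equal(sc$gene_id[1], "g0001")
  expect_equal(sc$score[1], 4L)
  expect_equal(unlist(sc[1, paste0("rank_", 1:4)], use.names = FALSE),
               rep(1L, 4))
})

test_that("contrast scores equal the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:10) {
    n <- sample(20:120, 1)
    tabs <- random_table_quartet(n, deg_prob = runif(1, 0.3, 0.9))
    for (policy in c("intersection", "penalty")) {
      ours <- contrast_score(tabs, universe_policy = policy)
      bf <- bf_contrast_score(tabs, policy = policy)
      expect_equal(ours$gene_id, bf$gene_id)
      expect_equal(ours$score, bf$score)
      expect_equal(ours$rank_1, bf$rank_1)
      expect_equal(ours$rank_4, bf$rank_4)
    }
  }
})

test_that("genes missing from one DEG set follow the universe policy", {
  tabs <- random_table_quartet(20, deg_prob = 1)
  drop <- which(tabs[[2]]$gene_id == "g0005")
  tabs[[2]]$is_deg[drop] <- FALSE
  inter <- contrast_score(tabs, universe_policy = "intersection")
  expect_false("g0005" %in% inter$gene_id)
  pen <- contrast_score(tabs, universe_policy = "penalty")
  expect_true("g0005" %in% pen$gene_id)
  # in the comparison it misses, the gene carries rank N_c + 1
  n_c <- sum(tabs[[2]]$is_deg)
  expect_equal(pen$rank_2[pen$gene_id == "g0005"], n_c + 1L)
})

test_that("scores are invariant to row permutations of the input tables", {
  set.seed(55)
  tabs <- random_table_quartet(50)
  shuffled <- lapply(tabs, function(t) {
    out <- t[sample.int(nrow(t)), , drop = FALSE]
    rownames(out) <- NULL
    for (a in c("genotype", "day", "time_of_day"))
      attr(out, a) <- attr(t, a)
    out
  })
  expect_equal(contrast_score(tabs), contrast_score(shuffled),
               ignore_attr = TRUE)
})

test_that("ranks are invariant under monotone transforms of one comparison's logFC", {
  set.seed(66)
  tabs <- random_table_quartet(40)
  warped <- tabs
  warped[[3]]$log_fc <- warped[[3]]$log_fc^3 + 0.2 * warped[[3]]$log_fc
  a <- contrast_score(tabs)
  b <- contrast_score(warped)
  for (col in c("gene_id", "rank_1", "rank_2", "rank_3", "rank_4", "score"))
    expect_equal(a[[col]], b[[col]])
})

test_that("scores respect the rank-sum bounds", {
  set.seed(77)
  for (i in 1:5) {
    tabs <- random_table_quartet(sample(10:60, 1))
    sc <- contrast_score(tabs)
    n <- nrow(sc)
    if (n == 0) next
    expect_true(all(sc$score >= 4))
    expect_true(all(sc$score <= 4 * n))
  }
})

test_that("table compatibility is enforced", {
  tabs <- random_table_quartet(10)
  expect_error(contrast_score(tabs[1:3]), "four")
  bad_tod <- tabs
  attr(bad_tod[[4]], "time_of_day") <- "afternoon"
  expect_error(contrast_score(bad_tod), "time-of-day")
  bad_geno <- tabs
  attr(bad_geno[[1]], "genotype") <- "B"
  expect_error(contrast_score(bad_geno), "genotype-A")
})

test_that("candidate selection applies the sign gate before truncation", {
  tabs <- random_table_quartet(30, deg_prob = 1)
  sc <- contrast_score(tabs)
  expect_error(select_candidates(sc, 0), "top_k")
  expect_error(select_candidates(sc, -3), "top_k")

  sel <- select_candidates(sc, top_k = 5)
  expect_lte(nrow(sel), 5)
  if (nrow(sel) > 0) {
    expect_true(all(sel$lfc_1 > 0 & sel$lfc_2 > 0))
    expect_true(all(sel$lfc_3 < 0 & sel$lfc_4 < 0))
  }

  # a minimal-score gene with the wrong sign in a genotype-B comparison is
  # excluded under the gate and kept without it
  sc2 <- sc
  sc2$lfc_3[1] <- abs(sc2$lfc_3[1]) + 1
  gated <- select_candidates(sc2, top_k = nrow(sc2))
  expect_false(sc2$gene_id[1] %in% gated$gene_id)
  ungated <- select_candidates(sc2, top_k = nrow(sc2),
                               require_sign_consistency = FALSE)
  expect_true(sc2$gene_id[1] %in% ungated$gene_id)
})
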