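# Independent oracles, deliberately implemented with plain loops and sorting,
# not via the package's ranking code.

# Textbook BH step-up: adj_(i) = min_{j >= i} p_(j) * m / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(sorted[i:m] * m / (i:m))
  }
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Brute-force contrast score: sort each comparison's data frame independently
# and read off positions.
bf_positions <- function(tab, ids, ld_first) {
  tab <- tab[tab$gene_id %in% ids, , drop = FALSE]
  if (ld_first) {
    tab <- tab[order(-tab$log_fc, tab$gene_id), , drop = FALSE]
  } else {
    tab <- tab[order(tab$log_fc, tab$gene_id), , drop = FALSE]
  }
  stats::setNames(seq_len(nrow(tab)), tab$gene_id)
}

bf_contrast_score <- function(tables, eligible = NULL,
                              policy = "intersection") {
  genos <- vapply(tables, function(t) as.character(attr(t, "genotype")), "")
  days <- vapply(tables, function(t) as.numeric(attr(t, "day")), 1)
  tables <- tables[order(genos, days)]
  genos <- genos[order(genos, days)]
  degs <- lapply(tables, function(t) {
    ids <- t$gene_id[t$is_deg]
    if (!is.null(eligible)) ids <- ids[ids %in% eligible]
    ids
  })
  if (policy == "intersection") {
    univ <- degs[[1]]
    for (k in 2:4) univ <- univ[univ %in% degs[[k]]]
    pos <- lapply(1:4, function(k)
      bf_positions(tables[[k]], univ, genos[k] == "A"))
  } else {
    univ <- unique(c(degs[[1]], degs[[2]], degs[[3]], degs[[4]]))
    pos <- lapply(1:4, function(k) {
      p <- bf_positions(tables[[k]], degs[[k]], genos[k] == "A")
      missing <- univ[!univ %in% names(p)]
      c(p, stats::setNames(rep(length(p) + 1L, length(missing)), missing))
    })
  }
  univ <- sort(univ)
  if (length(univ) == 0L)
    return(data.frame(gene_id = character(0), rank_1 = integer(0),
                      rank_2 = integer(0), rank_3 = integer(0),
                      rank_4 = integer(0), score = integer(0)))
  score <- integer(length(univ))
  rk <- matrix(0L, length(univ), 4)
  for (i in seq_along(univ)) {
    for (k in 1:4) rk[i, k] <- pos[[k]][[univ[i]]]
    score[i] <- sum(rk[i, ])
  }
  out <- data.frame(gene_id = univ, rank_1 = rk[, 1], rank_2 = rk[, 2],
                    rank_3 = rk[, 3], rank_4 = rk[, 4], score = score,
                    stringsAsFactors = FALSE)
  out[order(out$score, out$gene_id), , drop = FALSE]
}
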