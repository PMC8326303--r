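# 6 genes x 6 samples with a hand-computable class contrast.
rank_fixture <- function() {
  m <- rbind(up    = c(3, 1, 2, 1, -1, 0),   # snr = 2/(1+1) = 1
             flat  = c(5, 5, 5, 5, 5, 5),    # constant: metric 0
             equal = c(1, 2, 3, 1, 2, 3))    # equal class means: metric 0
  colnames(m) <- paste0("s", 1:6)
  list(x = make_expr(m), labels = rep(c("T", "R"), each = 3))
}

test_that("signal-to-noise ranking matches hand computation", {
  fx <- rank_fixture()
  r <- rank_genes(fx$x, fx$labels, "T")
  expect_equal(r$metric[r$gene == "up"], 1)      # (2-0)/(1+1)
  expect_equal(r$metric[r$gene == "equal"], 0)
  expect_equal(r$metric[r$gene == "flat"], 0)    # sd floor, not NaN
  expect_equal(r$gene[1], "up")
  # ties broken by gene symbol
  expect_equal(r$gene[2:3], c("equal", "flat"))
  expect_error(rank_genes(fx$x, c("T", rep("R", 5)), "T"), "at least 3")
})

test_that("enrichment score hits the closed-form extremes", {
  ranked <- data.frame(gene = paste0("g", 1:5), metric = c(2, 1, 0, -1, -2))
  class(ranked) <- c("ranked_genes", "data.frame")
  top2 <- enrichment_score(ranked, c("g1", "g2"), weight_p = 0)
  expect_equal(top2$es, 1.0)
  expect_equal(top2$leading_edge, c("g1", "g2"))
  bot1 <- enrichment_score(ranked, "g5", weight_p = 0)
  expect_equal(bot1$es, -1.0)
  expect_equal(bot1$leading_edge, "g5")
  expect_error(enrichment_score(ranked, "absent"), "no genes")
  expect_error(enrichment_score(ranked, paste0("g", 1:5)), "every ranked")
})

test_that("the running sum is bounded and returns to zero", {
  set.seed(21)
  for (i in 1:20) {
    inst <- random_es_instance()
    es <- enrichment_score(inst$ranked, inst$set, weight_p = inst$p)
    expect_true(es$es >= -1 && es$es <= 1)
    expect_equal(es$running_sum[length(es$running_sum)], 0,
                 tolerance = 1e-12)
  }
})

test_that("enrichment score equals the brute-force running-sum oracle", {
  set.seed(22)
  for (i in 1:100) {
    inst <- random_es_instance()
    es <- enrichment_score(inst$ranked, inst$set, weight_p = inst$p)
    expect_equal(es$es, brute_es(inst$ranked$metric, inst$hit, inst$p),
                 tolerance = 1e-12)
  }
})

test_that("enrichment score agrees with an independent implementation", {
  skip_if_not_installed("fgsea")
  set.seed(23)
  for (i in 1:25) {
    n <- sample(10:50, 1)
    stats <- sort(rnorm(n), decreasing = TRUE)
    names(stats) <- paste0("g", seq_len(n))
    sel <- sort(sample(n, sample(2:8, 1)))
    mine <- enrichment_score(
      structure(data.frame(gene = names(stats), metric = stats),
                class = c("ranked_genes", "data.frame")),
      names(stats)[sel], weight_p = 1)
    ref <- fgsea::calcGseaStat(stats, selectedStats = sel, gseaParam = 1)
    expect_equal(mine$es, ref, tolerance = 1e-8)
  }
})

gsea_cohort <- function(n_per_class = 20, seed) {
  set.seed(seed)
  n <- 2 * n_per_class
  labels <- rep(c("T", "R"), each = n_per_class)
  m <- matrix(rnorm(60 * n, 0, 1), 60, n,
              dimnames = list(paste0("g", 1:60), paste0("s", 1:n)))
  m[1:10, labels == "T"] <- m[1:10, labels == "T"] + 1  # planted up block
  list(x = make_expr(m), labels = setNames(labels, colnames(m)))
}

test_that("a planted up-regulated set is detected with small p", {
  co <- gsea_cohort(20, seed = 24)
  sets <- list(planted = paste0("g", 1:10),
               random = paste0("g", 31:45))
  res <- gsea(co$x, co$labels, "T", sets, n_perm = 999, seed = 25)
  expect_gt(res$es[res$gene_set == "planted"], 0)
  expect_lte(res$p_perm[res$gene_set == "planted"], 0.01)
  expect_true(all(res$p_perm >= 1 / 1000, na.rm = TRUE))
  expect_true(all(res$q_bh >= res$p_perm - 1e-15, na.rm = TRUE))
})

test_that("permutation GSEA is bit-identical under a fixed seed", {
  co <- gsea_cohort(10, seed = 26)
  sets <- list(a = paste0("g", 1:8), b = paste0("g", 40:50))
  r1 <- gsea(co$x, co$labels, "T", sets, n_perm = 101, seed = 7)
  r2 <- gsea(co$x, co$labels, "T", sets, n_perm = 101, seed = 7)
  expect_identical(r1, r2)
})

test_that("sets failing preconditions are skipped, not fatal", {
  co <- gsea_cohort(10, seed = 27)
  sets <- list(ok = paste0("g", 1:5), absent = c("zz1", "zz2"))
  res <- gsea(co$x, co$labels, "T", sets, n_perm = 101, seed = 8)
  expect_false(res$skipped[res$gene_set == "ok"])
  expect_true(res$skipped[res$gene_set == "absent"])
  expect_true(is.na(res$es[res$gene_set == "absent"]))
})

test_that("a random set on permuted labels rejects at the nominal rate", {
  co <- gsea_cohort(12, seed = 28)
  set.seed(29)
  hits <- logical(200)
  for (b in 1:200) {
    perm_labels <- setNames(sample(co$labels), names(co$labels))
    gs <- list(s = paste0("g", sample(60, 10)))
    res <- gsea(co$x, perm_labels, "T", gs, n_perm = 119, seed = b)
    hits[b] <- res$p_perm[1] < 0.05
  }
  expect_lt(abs(mean(hits) - 0.05), 0.045)
})

test_that("marker contrast and separation index behave by construction", {
  # luminal-class samples: luminal markers +1, basal -1; vice versa
  n <- 40
  ids <- paste0("s", 1:n)
  cls <- rep(c("L", "B"), each = n / 2)
  m <- rbind(lm1 = ifelse(cls == "L", 1, -1),
             lm2 = ifelse(cls == "L", 1, -1),
             bm1 = ifelse(cls == "L", -1, 1),
             bm2 = ifelse(cls == "L", -1, 1))
  colnames(m) <- ids
  asn <- mk_assign(ids, cls)
  ms <- marker_separation(make_expr(m), asn, c("lm1", "lm2"), c("bm1", "bm2"),
                          luminal_classes = "L", basal_classes = "B")
  # raw contrast is +/-2; gene-wise z-scoring rescales each marker row by
  # its sample sd sqrt(n/(n-1)), so delta = +/- 2 * sqrt((n-1)/n)
  d <- 2 * sqrt((n - 1) / n)
  expect_equal(sort(unique(ms$per_sample$delta)), c(-d, d))
  expect_equal(ms$per_subtype$mean_delta[ms$per_subtype$class == "L"], d)
  expect_error(marker_separation(make_expr(m), asn, "zz", "bm1"), "marker")
})

test_that("random expression and labels give a near-zero separation index", {
  set.seed(30)
  n <- 300
  ids <- paste0("s", 1:n)
  m <- matrix(rnorm(20 * n), 20, n,
              dimnames = list(c(paste0("lm", 1:5), paste0("bm", 1:5),
                                paste0("x", 1:10)), ids))
  asn <- mk_assign(ids, sample(c("L1", "L2", "B1"), n, replace = TRUE))
  ms <- marker_separation(make_expr(m), asn, paste0("lm", 1:5),
                          paste0("bm", 1:5),
                          luminal_classes = c("L1", "L2"),
                          basal_classes = "B1")
  expect_lt(abs(ms$separation_index), 0.2)
})

test_that("a scheme isolating a mixed class separates better than one merging it", {
  # lineage: 40 luminal, 40 basal, 40 mixed (both marker panels elevated)
  set.seed(31)
  n <- 120
  ids <- paste0("s", 1:n)
  lineage <- rep(c("lum", "bas", "mix"), each = 40)
  m <- matrix(rnorm(10 * n, 0, 0.5), 10, n,
              dimnames = list(c(paste0("lm", 1:5), paste0("bm", 1:5)), ids))
  m[1:5, lineage == "lum"] <- m[1:5, lineage == "lum"] + 1
  m[6:10, lineage == "bas"] <- m[6:10, lineage == "bas"] + 1
  m[, lineage == "mix"] <- m[, lineage == "mix"] + 0.5
  x <- make_expr(m)
  # scheme 1 isolates the mixed class; scheme 2 merges it into luminal
  s1 <- mk_assign(ids, c(lum = "L", bas = "B", mix = "M")[lineage])
  s2 <- mk_assign(ids, c(lum = "L", bas = "B", mix = "L")[lineage])
  args <- list(luminal_markers = paste0("lm", 1:5),
               basal_markers = paste0("bm", 1:5))
  idx1 <- do.call(marker_separation,
                  c(list(x, s1, luminal_classes = "L", basal_classes = "B"),
                    args))$separation_index
  idx2 <- do.call(marker_separation,
                  c(list(x, s2, luminal_classes = "L", basal_classes = "B"),
                    args))$separation_index
  expect_gt(idx1, idx2)
})
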