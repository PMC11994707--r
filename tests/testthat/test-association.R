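make_pt <- function(ratios, ids = sprintf("P%02d", seq_along(ratios))) {
  tpm <- rbind(CXCL9 = ratios, SPP1 = rep(1, length(ratios)))
  colnames(tpm) <- ids
  cs_ratio_bulk(tpm)
}

test_that("patients are ranked by CS ratio with documented tie-breaks", {
  pt <- make_pt(c(2, 0.5, 1), ids = c("p1", "p2", "p3"))
  expect_identical(rank_patients(pt), c("p1", "p3", "p2"))
  expect_identical(rank_patients(pt, decreasing = FALSE),
                   c("p2", "p3", "p1"))
  tie <- make_pt(c(1, 1, 2), ids = c("pb", "pa", "pc"))
  expect_identical(rank_patients(tie), c("pc", "pa", "pb"))
})

test_that("a gene tracking the CS ratio is the top association", {
  sc <- generate_sc_cohort(synthetic_config(n_patients = 12,
                                            cells_per_patient = 100,
                                            n_genes = 30, seed = 41))
  am <- compute_adjusted_means(sc$dataset)
  pt <- cs_ratio_sc(am)
  # CXCL9's own adjusted mean moves with the ratio by construction
  res <- gene_polarity_correlation(am, pt)
  r_cx <- res$r[res$gene == "CXCL9"]
  expect_gt(r_cx, 0.8)
  expect_true(res$associated[res$gene == "CXCL9"])
  expect_lt(res$r[res$gene == "SPP1"], 0)
  expect_true(attr(res, "fraction_associated") >= 0 &&
                attr(res, "fraction_associated") <= 1)
})

test_that("pure-noise genes rarely pass the dual association threshold", {
  fracs <- numeric(0)
  for (i in 1:30) {
    set.seed(700 + i)
    n_pat <- 20
    counts <- matrix(rpois(40 * n_pat * 5, 2), nrow = 40)
    counts[1, ] <- rpois(n_pat * 5, 3)  # CXCL9 noise too
    ds <- toy_dataset(counts, patient = rep(sprintf("P%02d", 1:n_pat),
                                            each = 5),
                      cell_type = rep("TAM", n_pat * 5),
                      gene_ids = c("CXCL9", "SPP1", paste0("g", 1:38)))
    am <- compute_adjusted_means(ds)
    pt <- cs_ratio_sc(am)
    res <- gene_polarity_correlation(
      am, pt, genes = paste0("g", 1:38))
    fracs <- c(fracs, attr(res, "fraction_associated"))
  }
  expect_lt(mean(fracs), 0.05)
})

test_that("coupled cell types are recovered by the association scan", {
  hits <- 0
  for (i in 1:10) {
    sc <- generate_sc_cohort(synthetic_config(n_patients = 15,
                                              cells_per_patient = 120,
                                              n_genes = 30,
                                              seed = 800 + i))
    am_tam <- compute_adjusted_means(sc$dataset)
    am_t <- suppressWarnings(
      compute_adjusted_means(sc$dataset, cell_type = "T_cell"))
    pt <- cs_ratio_sc(am_tam)
    res <- gene_polarity_correlation(list(TAM = am_tam, T_cell = am_t), pt)
    r <- res$r[res$cell_type == "T_cell" & res$gene == "CXCL9"]
    hits <- hits + (length(r) == 1 && !is.na(r) && r > 0)
  }
  expect_gte(hits / 10, 0.9)
})

test_that("group differential expression finds a planted shift", {
  set.seed(5)
  n <- 20
  tpm <- matrix(rlnorm(50 * 2 * n, 3, 1), nrow = 50,
                dimnames = list(paste0("g", 1:50),
                                paste0("s", 1:(2 * n))))
  groups <- setNames(rep(c("high", "low"), each = n),
                     colnames(tpm))
  tpm["g1", groups == "high"] <- tpm["g1", groups == "high"] * exp(10)
  res <- de_between_groups(tpm, groups)
  expect_lt(res$q[res$gene == "g1"], 0.05)
  expect_equal(res$direction[res$gene == "g1"], 1)
  # a constant gene is reported with p = 1
  tpm["g2", ] <- 7
  res2 <- de_between_groups(tpm, groups)
  expect_equal(res2$p[res2$gene == "g2"], 1)
})

test_that("rank-sum p for a single-sample group matches enumeration", {
  # with one 'high' sample its pooled rank is uniform under H0, so the exact
  # two-sided p is 2 * min(r, n - r + 1) / n capped at 1
  oracle_p <- function(x, y) {
    r <- rank(c(x, y))[1]
    n <- 1 + length(y)
    min(1, 2 * min(r, n - r + 1) / n)
  }
  set.seed(8)
  for (i in 1:20) {
    m <- sample(3:7, 1)
    tpm <- matrix(exp(rnorm(3 * (m + 1), 3, 1)), nrow = 3,
                  dimnames = list(paste0("g", 1:3),
                                  paste0("s", seq_len(m + 1))))
    groups <- setNames(c("high", rep("low", m)), colnames(tpm))
    res <- de_between_groups(tpm, groups)
    for (g in rownames(tpm)) {
      lx <- log1p(tpm[g, ])
      expect_equal(res$p[res$gene == g], oracle_p(lx[1], lx[-1]),
                   tolerance = 1e-10)
    }
  }
})

test_that("label permutations give a uniform-looking DE null", {
  set.seed(9)
  tpm <- matrix(rlnorm(30 * 16, 3, 1), nrow = 30,
                dimnames = list(paste0("g", 1:30), paste0("s", 1:16)))
  ps <- replicate(30, {
    groups <- setNames(sample(rep(c("high", "low"), each = 8)),
                       colnames(tpm))
    de_between_groups(tpm, groups)$p
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("enrichment score has the KS properties at weight 0", {
  stats <- setNames(seq(2, -2, length.out = 50), paste0("g", 1:50))
  top10 <- paste0("g", 1:10)
  res <- preranked_enrichment(stats, list(top = top10), n_perm = 200,
                              weight = 0, seed = 1)
  expect_gt(res$es, 0)
  expect_lte(abs(res$es), 1)
  # the top-k set maximizes the score among random same-size sets
  set.seed(2)
  rand_es <- replicate(200, {
    s <- sample(names(stats), 10)
    cspolar:::gsea_es(stats, names(stats) %in% s, weight = 0)
  })
  expect_true(all(rand_es <= res$es + 1e-12))
  # reversing the ranking flips the sign exactly at weight 0
  rev_stats <- setNames(rev(unname(stats)), names(stats))
  res_rev <- preranked_enrichment(rev_stats, list(top = top10),
                                  n_perm = 50, weight = 0, seed = 1)
  expect_equal(res_rev$es, -res$es, tolerance = 1e-12)
  # running sum starts and ends at zero: cumulative increments cancel
  run <- cumsum(ifelse(names(stats) %in% top10, 1 / 10, -1 / 40))
  expect_equal(run[50], 0, tolerance = 1e-12)
})

test_that("random sets on null rankings give calibrated enrichment p", {
  set.seed(3)
  ps <- replicate(30, {
    stats <- setNames(rnorm(60), paste0("g", 1:60))
    preranked_enrichment(stats, list(s = sample(names(stats), 8)),
                         n_perm = 99, weight = 1, seed = 4)$p
  })
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  stats_const <- setNames(rep(1, 20), paste0("g", 1:20))
  expect_error(preranked_enrichment(stats_const, list(s = paste0("g", 1:6))),
               "no ranking")
  stats <- setNames(rnorm(20), paste0("g", 1:20))
  expect_error(preranked_enrichment(stats, list(s = paste0("g", 1:3))),
               "at least 5")
})

test_that("weighted ES agrees with an independent implementation", {
  skip_if_not_installed("fgsea")
  set.seed(6)
  stats <- setNames(rnorm(100), paste0("g", 1:100))
  set_members <- sample(names(stats), 15)
  es <- cspolar:::gsea_es(sort(stats, decreasing = TRUE),
                          names(sort(stats, decreasing = TRUE)) %in%
                            set_members, weight = 1)
  ref <- fgsea::calcGseaStat(sort(stats, decreasing = TRUE),
                             which(names(sort(stats, decreasing = TRUE))
                                   %in% set_members),
                             gseaParam = 1)
  expect_equal(es, ref, tolerance = 1e-6)
})

test_that("GMT gene sets and shipped signatures load correctly", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4\tg5"), path)
  sets <- read_gmt(path)
  expect_identical(sets, list(setA = c("g1", "g2", "g3"),
                              setB = c("g4", "g5")))
  m1 <- load_signature("m1")
  m2 <- load_signature("m2")
  expect_true("CXCL9" %in% m1)
  expect_gt(length(m2), 5)
  expect_length(intersect(m1, m2), 0)
  expect_error(load_signature("nope"), "no signature")
})

test_that("BH adjustment matches the reference step-up construction", {
  step_up <- function(p) {
    n <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(n / (n:1) * p[o]))[ro]
  }
  set.seed(7)
  for (i in 1:5) {
    p <- runif(sample(10:1000, 1))
    expect_equal(p.adjust(p, "BH"), step_up(p), tolerance = 1e-12)
  }
})
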