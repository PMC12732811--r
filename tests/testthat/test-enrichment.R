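# GMT parsing, pre-ranked GSEA and single-sample ssGSEA.

test_that("read_gmt parses, uppercases and de-duplicates; errors are located", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tCDH1\tvim\tCDH1", "S2\tdesc\tFN1\tZEB1"), f)
  sets <- read_gmt(f)
  expect_setequal(sets$S1, c("CDH1", "VIM"))
  expect_equal(length(sets$S2), 2)
  writeLines(c("S1\tdesc\tA", "S1\tdesc\tB"), f)
  expect_error(read_gmt(f), "lines 1 and 2")
  writeLines(c("S1\tonlydesc"), f)
  expect_error(read_gmt(f), "fewer than 3")
  # round trip
  write_gmt(list(A = c("X", "Y"), B = c("Z")), f)
  expect_equal(unclass(read_gmt(f))[], list(A = c("X", "Y"), B = "Z"),
               ignore_attr = TRUE)
})

test_that("ranked_list orders descending with lexicographic tie-break", {
  rl <- ranked_list(c("b", "a", "c"), c(1, 1, 5))
  expect_equal(names(rl), c("C", "A", "B"))
  expect_error(ranked_list(c("a", "a"), c(1, 2)), "unique")
})

test_that("ES hits +-1 on block placements and negation reverses its sign", {
  rl <- ranked_list(paste0("G", 1:50), 50:1)
  expect_equal(gsea_preranked(rl, paste0("G", 1:10), n_perm = 50,
                              seed = 1)$es, 1)
  expect_equal(gsea_preranked(rl, paste0("G", 41:50), n_perm = 50,
                              seed = 1)$es, -1)
  # negating the metric and reversing the order negates ES exactly
  set.seed(4)
  met <- rnorm(50)
  rl1 <- ranked_list(paste0("G", 1:50), met)
  rl2 <- ranked_list(paste0("G", 1:50), -met)
  set <- paste0("G", sample(50, 12))
  e1 <- gsea_preranked(rl1, set, n_perm = 10, seed = 1)$es
  e2 <- gsea_preranked(rl2, set, n_perm = 10, seed = 1)$es
  expect_equal(e1, -e2, tolerance = 1e-12)
  expect_true(abs(e1) <= 1)
  expect_error(gsea_preranked(rl1, c("NOPE"), n_perm = 10), "no overlap")
})

test_that("weight-0 ES equals the classical two-CDF statistic", {
  set.seed(9)
  for (i in 1:30) {
    N <- sample(10:60, 1)
    genes <- paste0("G", seq_len(N))
    rl <- ranked_list(genes, rnorm(N))
    set <- sample(genes, sample(2:min(10, N - 1), 1))
    es <- gsea_preranked(rl, set, weight = 0, n_perm = 5, seed = 1)$es
    expect_equal(es, ks_es_oracle(names(rl), toupper(set)), tolerance = 1e-12)
  }
})

test_that("tiny-problem p values equal exhaustive enumeration", {
  rl <- ranked_list(paste0("G", 1:5), c(3, 2, 1, -1, -2))
  r <- gsea_preranked(rl, c("G1", "G2"), weight = 0, n_perm = 1000, seed = 2)
  # oracle: enumerate the 10 placements of a size-2 set at weight 0
  placements <- utils::combn(5, 2, simplify = FALSE)
  es_all <- vapply(placements, function(pos) {
    hit <- seq_len(5) %in% pos
    run <- cumsum(ifelse(hit, 1 / 2, -1 / 3))
    run[which.max(abs(run))]
  }, numeric(1))
  same <- es_all[es_all >= 0] # matching-sign nulls; observed ES is positive
  p_oracle <- mean(abs(same) >= abs(r$es) - 1e-12)
  expect_equal(r$p, p_oracle, tolerance = 1e-12)
  expect_equal(sign(r$nes), sign(r$es))
})

test_that("the weighted ES agrees with the fgsea reference implementation", {
  skip_if_not_installed("fgsea")
  set.seed(14)
  for (i in 1:20) {
    N <- sample(30:150, 1)
    met <- rnorm(N, 0, 2)
    rl <- ranked_list(paste0("G", seq_len(N)), met)
    pos <- sort(sample(N, sample(5:20, 1)))
    mine <- gsea_preranked(rl, names(rl)[pos], weight = 1, n_perm = 5,
                           seed = 1)$es
    ref <- fgsea::calcGseaStat(stats = stats::setNames(unname(rl), names(rl)),
                               selectedStats = pos, gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("permutation p values are seeded and shrink-consistent", {
  set.seed(10)
  rl <- ranked_list(paste0("G", 1:200), rnorm(200))
  set <- paste0("G", sample(200, 20))
  a <- gsea_preranked(rl, set, n_perm = 300, seed = 7)
  b <- gsea_preranked(rl, set, n_perm = 300, seed = 7)
  expect_identical(a, b)
  big <- gsea_preranked(rl, set, n_perm = 4000, seed = 7)
  expect_lt(abs(a$p - big$p), 0.05)
})

test_that("gsea_collection filters by size and detects planted enrichment", {
  sim <- make_bulk_expression(bulk_sim_params(n_genes = 400, n_de = 60,
                                              lfc_magnitude = 3, seed = 17))
  de <- differential_expression(sim$expression)
  rl <- ranked_list(de$gene, de$log2FC)
  up <- sim$truth$de_genes$gene[sim$truth$de_genes$sign > 0]
  sets <- list(SMALL = rownames(sim$expression$values)[1:10],
               PLANTED_UP = up,
               NULL_SET = setdiff(rownames(sim$expression$values),
                                  sim$truth$de_genes$gene)[1:40])
  er <- gsea_collection(rl, sets, min_size = 25, max_size = 500,
                        n_perm = 300, seed = 5)
  expect_false("SMALL" %in% er$set) # below the size window
  planted <- er[er$set == "PLANTED_UP", ]
  expect_gt(planted$nes, 0)
  expect_lt(planted$p, 0.05)
  expect_true(all(er$q >= er$p - 1e-12))
  lead <- strsplit(planted$leading_edge, ",")[[1]]
  expect_true(all(lead %in% toupper(up)))
  expect_warning(gsea_collection(rl, list(S = c("G0001")), min_size = 25),
                 "size filter")
})

test_that("ssGSEA is deterministic, rank-dominant and uniform at alpha 0", {
  set.seed(21)
  v <- matrix(rnorm(200 * 3, 8), 200, 3,
              dimnames = list(sprintf("G%03d", 1:200), c("s1", "s2", "s3")))
  v[, 2] <- v[, 1] # identical samples
  top_set <- rownames(v)[order(-v[, 1])][1:15]
  sc <- ssgsea_scores(v, list(TOP = top_set))
  expect_equal(sc["TOP", "s1"], sc["TOP", "s2"])
  # the top-ranked set dominates random same-size sets
  rand <- replicate(100, {
    ssgsea_scores(v[, 1, drop = FALSE],
                  list(R = sample(rownames(v), 15)))[1, 1]
  })
  expect_true(all(sc["TOP", "s1"] >= rand))
  # alpha = 0: score depends only on member positions
  pos_set <- rownames(v)[order(-v[, 3])][seq(2, 30, 2)]
  s0 <- ssgsea_scores(v[, 3, drop = FALSE], list(S = pos_set), alpha = 0)
  w <- 10 * v[, 3, drop = FALSE] + 5
  s0b <- ssgsea_scores(w, list(S = pos_set), alpha = 0)
  expect_equal(s0, s0b, tolerance = 1e-12)
  expect_warning(
    out <- ssgsea_scores(v, list(TOP = top_set, NONE = c("ZZZ"))),
    "no overlap")
  expect_true(all(is.na(out["NONE", ])))
  expect_error(ssgsea_scores(v, list(NONE = "ZZZ")), "no gene set overlaps")
})
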