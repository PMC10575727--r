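toyTables <- function() {
  baseline <- DeContrastTable("disease_vs_healthy", data.frame(
    gene = c("g1", "g2", "g3", "g4"),
    log2fc = c(-2.0, -2.0, 1.0, 3.0),
    padj = c(0.01, 0.01, 0.20, 0.001),
    basemean = c(100, 100, 100, 5)))
  treatment <- DeContrastTable("treated_vs_disease", data.frame(
    gene = c("g1", "g2", "g3", "g4"),
    log2fc = c(1.5, -1.0, -1.0, -2.0),
    padj = c(0.02, 0.01, 0.01, 0.001),
    basemean = c(100, 100, 100, 5)))
  list(baseline = baseline, treatment = treatment)
}

test_that("the opposite-direction predicate admits and rejects correctly", {
  tt <- toyTables()
  hits <- oppositeDirectionFilter(tt$baseline, tt$treatment)
  g <- rescueGenes(hits)
  # g1: significant both, opposite signs -> in; g2 same direction;
  # g3 baseline not significant; g4 in (significant, opposite)
  expect_setequal(g$gene, c("g1", "g4"))
  expect_equal(g$direction[g$gene == "g1"], "down_up")
  expect_equal(g$direction[g$gene == "g4"], "up_down")
  expect_identical(sort(g$gene),
                   oracle_rescue(contrastData(tt$baseline),
                                 contrastData(tt$treatment)))
  empty <- DeContrastTable("e", data.frame(gene = character(),
                                           log2fc = numeric(),
                                           padj = numeric(),
                                           basemean = numeric()))
  expect_error(oppositeDirectionFilter(empty, empty), "empty")
  disjoint <- DeContrastTable("d", data.frame(gene = "zz", log2fc = 1,
                                              padj = 0.01, basemean = 10))
  expect_error(oppositeDirectionFilter(tt$baseline, disjoint),
               "share no genes")
})

test_that("the filter is symmetric under a global sign flip", {
  de <- genDeTables(syntheticDeConfig(nGenes = 500, nRescue = 20,
                                      seed = 13))
  flip <- function(tbl) {
    d <- contrastData(tbl)
    d$log2fc <- -d$log2fc
    DeContrastTable(tbl@contrast, d)
  }
  a <- rescueGenes(oppositeDirectionFilter(de$baseline, de$treatment))
  b <- rescueGenes(oppositeDirectionFilter(flip(de$baseline),
                                           flip(de$treatment)))
  expect_identical(a$gene, b$gene)
  expect_equal(a$baseline_log2fc, -b$baseline_log2fc)
})

test_that("the filter matches the row-predicate oracle on random tables", {
  for (s in 1:3) {
    de <- genDeTables(syntheticDeConfig(nGenes = 1000, nRescue = 30,
                                        seed = s))
    hits <- oppositeDirectionFilter(de$baseline, de$treatment)
    expect_identical(sort(rescueGenes(hits)$gene),
                     oracle_rescue(contrastData(de$baseline),
                                   contrastData(de$treatment)),
                     info = paste("seed", s))
  }
})

test_that("prioritization thresholds drop and rank as documented", {
  tt <- toyTables()
  hits <- oppositeDirectionFilter(tt$baseline, tt$treatment)
  # default base mean floor (10) drops g4 (basemean 5)
  pr <- prioritizeRescueGenes(hits)
  expect_equal(rescueGenes(pr)$gene, "g1")
  # permissive thresholds keep everything, ranked by |treatment lfc|
  all <- prioritizeRescueGenes(hits, 0, 1, 0)
  expect_equal(rescueGenes(all)$gene, c("g4", "g1"))
  # effect-size threshold above all members empties the set
  none <- prioritizeRescueGenes(hits, 10, 1, 0)
  expect_equal(nrow(rescueGenes(none)), 0)
  expect_error(prioritizeRescueGenes(hits, -1), "non-negative")
})

test_that("planted rescue genes are fully recovered and ranked on top", {
  res <- vapply(1:10, function(s) {
    de <- genDeTables(syntheticDeConfig(seed = s))
    planted <- truthOf(de$truth)$rescueGenes
    pr <- prioritizeRescueGenes(
      oppositeDirectionFilter(de$baseline, de$treatment))
    g <- rescueGenes(pr)
    isPlanted <- g$gene %in% planted
    allAbove <- !any(isPlanted) ||
      max(which(isPlanted)) <= sum(isPlanted)
    c(sens = mean(planted %in% g$gene), allAbove = allAbove)
  }, numeric(2))
  expect_gte(median(res["sens", ]), 0.95)
  # in the typical run every planted gene outranks every surviving null
  expect_gte(median(res["allAbove", ]), 1)
})

test_that("2^-ddCt follows the worked arithmetic", {
  w <- rbind(
    data.frame(sample = "ref", gene = "G", cq = 26, role = "target"),
    data.frame(sample = "ref", gene = "HK", cq = 20,
               role = "housekeeping"),
    data.frame(sample = "tst", gene = "G", cq = 24, role = "target"),
    data.frame(sample = "tst", gene = "HK", cq = 20,
               role = "housekeeping"))
  res <- deltaDeltaCt(QpcrPlate(w), "ref")
  expect_equal(res$fold[res$sample == "tst"], 4)
  expect_equal(res$delta_delta_ct[res$sample == "tst"], -2)
  expect_equal(res$fold[res$sample == "ref"], 1)
  # identical Cq everywhere -> fold 1
  w2 <- w
  w2$cq <- 25
  expect_equal(deltaDeltaCt(QpcrPlate(w2), "ref")$fold, c(1, 1))
  # ddCt = -1 -> fold 2
  w3 <- w
  w3$cq[w3$sample == "tst" & w3$role == "target"] <- 25
  expect_equal(deltaDeltaCt(QpcrPlate(w3), "ref")$fold[2], 2)
  # triplicates are averaged
  trip <- rbind(w, transform(w, cq = cq + 0.3),
                transform(w, cq = cq - 0.3))
  expect_equal(deltaDeltaCt(QpcrPlate(trip), "ref")$fold,
               res$fold[order(res$gene, res$sample)])
  noHk <- w[w$role == "target", ]
  expect_error(deltaDeltaCt(QpcrPlate(noHk), "ref"), "housekeeping")
  expect_error(deltaDeltaCt(QpcrPlate(w), "nope"), "not on the plate")
})

test_that("fold change is invariant to a per-sample Cq shift", {
  w <- rbind(
    data.frame(sample = "ref", gene = "G", cq = 26, role = "target"),
    data.frame(sample = "ref", gene = "HK", cq = 20,
               role = "housekeeping"),
    data.frame(sample = "tst", gene = "G", cq = 23.5, role = "target"),
    data.frame(sample = "tst", gene = "HK", cq = 19,
               role = "housekeeping"))
  base <- deltaDeltaCt(QpcrPlate(w), "ref")$fold
  w2 <- w
  w2$cq[w2$sample == "tst"] <- w2$cq[w2$sample == "tst"] + 3.7
  expect_equal(deltaDeltaCt(QpcrPlate(w2), "ref")$fold, base)
})
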