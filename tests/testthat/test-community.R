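makeTinySE <- function(counts, lineages = NULL) {
  tax <- if (!is.null(lineages))
    data.frame(asv_id = rownames(counts), lineage = lineages)
  if (!is.null(tax)) tax <- cbind(tax["asv_id"],
                                  BacMetNet:::splitLineage(tax$lineage))
  makeAsvExperiment(counts, taxonomy = tax)
}

test_that("lineage filtering is case-insensitive substring over all ranks", {
  m <- matrix(5L, nrow = 5, ncol = 3,
              dimnames = list(paste0("A", 1:5), paste0("S", 1:3)))
  lin <- c("Bacteria;Cyanobacteria;Cyanobacteriia;Chloroplast;;",
           "Bacteria;Proteobacteria;Alphaproteobacteria;SAR11_clade;;",
           "Bacteria;Proteobacteria;Alphaproteobacteria;Rickettsiales;Mitochondria;",
           "Bacteria;Bacteroidota;Bacteroidia;Flavobacteriales;;",
           "Bacteria;Cyanobacteria;Cyanobacteriia;chloroplast;;")  # lower case
  se <- makeTinySE(m, lin)
  out <- removeLineages(se, c("Chloroplast", "Mitochondria"))
  expect_setequal(rownames(out), c("A2", "A4"))
  expect_equal(ncol(out), 3)
  # no banned labels present -> identity
  out2 <- removeLineages(se, "Archaea")
  expect_equal(dim(out2), dim(se))
  # single banned label
  expect_equal(nrow(removeLineages(se, "Chloroplast")), 3)
})

test_that("rarefaction hits the exact depth, is seeded, drops shallow samples", {
  set.seed(3)
  m <- matrix(rpois(60, 40), nrow = 6,
              dimnames = list(paste0("A", 1:6), paste0("S", 1:10)))
  m[, 10] <- 0L; m[1, 10] <- 3L                   # shallow sample
  storage.mode(m) <- "integer"
  r1 <- rarefyAsvTable(m, depth = 50, seed = 42)
  expect_true(all(colSums(r1) == 50))
  expect_equal(attr(r1, "dropped"), "S10")
  r2 <- rarefyAsvTable(m, depth = 50, seed = 42)
  expect_identical(unclass(r1), unclass(r2))
  expect_false(identical(unclass(r1),
                         unclass(rarefyAsvTable(m, depth = 50, seed = 43))))
  # totals exactly at depth pass through unchanged
  v <- matrix(c(7L, 13L), ncol = 1, dimnames = list(c("A1", "A2"), "S1"))
  expect_equal(unname(asSums <- rarefyAsvTable(v, 20, 1)[, 1]), c(7, 13))
  # depth 1 leaves exactly one read
  expect_equal(sum(rarefyAsvTable(v, 1, 1)), 1)
  expect_error(rarefyAsvTable(v, 0), ">= 1")
})

test_that("rarefaction subsampling matches the hypergeometric expectation", {
  m <- matrix(c(100L, 900L), ncol = 1, dimnames = list(c("A1", "A2"), "S1"))
  draws <- vapply(1:300, function(s) rarefyAsvTable(m, 100, s)["A2", 1],
                  numeric(1))
  # E[ASV2] = 100 * 900/1000 = 90; SE of the mean over 300 draws ~ 0.17
  expect_equal(mean(draws), 90, tolerance = 0.02)
})

test_that("richness and Shannon follow their definitions", {
  expect_equal(richness(c(5, 0, 1)), 2)
  expect_equal(richness(c(0, 0)), 0)
  expect_equal(richness(rep(1, 4)), 4)
  expect_error(richness(integer(0)), "empty")
  expect_equal(shannonIndex(c(0, 7, 0)), 0)
  expect_equal(shannonIndex(rep(3, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannonIndex(c(1, 1, 2)),
               -(0.25 * log(0.25) * 2 + 0.5 * log(0.5)), tolerance = 1e-12)
  expect_equal(shannonIndex(c(1, 1, 2)), 1.0397, tolerance = 1e-4)
  expect_error(shannonIndex(c(0, 0)), "> 0")
  expect_equal(shannonIndex(c(2, 2), base = 2), 1)
  # H <= ln(S), equality iff uniform
  set.seed(5)
  for (i in 1:200) {
    v <- rpois(8, 4)
    if (sum(v) == 0) next
    expect_lte(shannonIndex(v), log(richness(v)) + 1e-12)
  }
})

test_that("Bray-Curtis matches its formula and vegan on fuzz cases", {
  expect_equal(brayCurtis(c(3, 1), c(3, 1)), 0)
  expect_equal(brayCurtis(c(5, 0), c(0, 2)), 1)
  expect_equal(brayCurtis(c(2, 0), c(1, 1)), 0.5)
  expect_error(brayCurtis(1:3, 1:2), "equal length")
  set.seed(9)
  for (i in 1:200) {
    x <- rpois(12, 5); y <- rpois(12, 5)
    if (sum(x) == 0 || sum(y) == 0) next
    d <- brayCurtis(x, y)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, brayCurtis(y, x))
    expect_equal(d, as.numeric(vegan::vegdist(rbind(x, y))),
                 tolerance = 1e-12)
  }
})

test_that("classical scaling reproduces geometry and flags asymmetry", {
  # three collinear points
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3)
  out <- pcoa(d)
  expect_equal(ncol(out$coordinates), 1)
  got <- sort(out$coordinates[, 1])
  expect_equal(got - mean(got), c(-1, 0, 1), tolerance = 1e-8,
               ignore_attr = TRUE)
  # duplicate samples land on identical coordinates
  d2 <- as.matrix(dist(c(0, 0, 3)))
  out2 <- pcoa(d2)
  expect_equal(out2$coordinates[1, ], out2$coordinates[2, ],
               tolerance = 1e-10, ignore_attr = TRUE)
  # Euclidean distances of a cloud are reproduced exactly
  set.seed(21)
  pts <- matrix(rnorm(40), ncol = 4)
  de <- as.matrix(dist(pts))
  oe <- pcoa(de)
  expect_equal(as.matrix(dist(oe$coordinates)), de, tolerance = 1e-8,
               ignore_attr = TRUE)
  # agreement with the standard cmdscale implementation (up to sign)
  cs <- stats::cmdscale(de, k = 2, eig = TRUE)
  expect_equal(abs(oe$coordinates[, 1:2]), abs(cs$points),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PERMANOVA matches vegan's pseudo-F and exact enumeration", {
  set.seed(13)
  pts <- matrix(rnorm(24), ncol = 2)
  grp <- rep(c("a", "b"), each = 6)
  d <- as.matrix(dist(pts))
  res <- permanova(d, grp, n_perm = 199, seed = 1)
  ad <- vegan::adonis2(as.dist(d) ~ grp, permutations = 99)
  expect_equal(res$f, ad$F[1], tolerance = 1e-8)

  # exhaustive label-permutation oracle at n = 6 (two balanced groups)
  set.seed(31)
  pts6 <- matrix(rnorm(12), ncol = 2)
  pts6[1:3, ] <- pts6[1:3, ] + 1.5
  d6 <- as.matrix(dist(pts6))^2
  g6 <- rep(c("a", "b"), each = 3)
  f_obs <- BacMetNet:::permanovaF(d6, g6)
  combs <- utils::combn(6, 3)
  f_all <- apply(combs, 2, function(idx) {
    lab <- rep("b", 6); lab[idx] <- "a"
    BacMetNet:::permanovaF(d6, lab)
  })
  p_exact <- mean(f_all >= f_obs - 1e-12)
  res6 <- permanova(sqrt(d6), g6, n_perm = 9999, seed = 7)
  expect_lt(abs(res6$p - p_exact), 0.02)

  # two tight, well-separated groups: observed F is maximal, so only
  # permutations recreating the original partition can tie it
  pts2 <- rbind(matrix(0.001 * rnorm(16), ncol = 2),
                matrix(0.001 * rnorm(16), ncol = 2) + 10)
  dd <- as.matrix(dist(pts2))
  g2 <- rep(c("a", "b"), each = 8)
  rs <- permanova(dd, g2, n_perm = 199, seed = 3)
  expect_equal(rs$p, 1 / 200)
  expect_error(permanova(dd, rep("a", 16), n_perm = 199), "2 groups")
})

test_that("Wilcoxon rank-sum matches exact enumeration and separates", {
  same <- wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p, 0.9)
  sep <- wilcoxonRankSum(1:10, 101:110)
  expect_lt(sep$p, 0.001)
  # brute-force oracle over C(8,4) assignments, small integers, no ties
  x <- c(1, 4, 6, 9); y <- c(2, 3, 11, 14)
  got <- wilcoxonRankSum(x, y)
  expect_true(got$exact)
  pool <- c(x, y)
  r <- rank(pool)
  w_obs <- sum(r[1:4])
  combs <- utils::combn(8, 4)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- mean(w_all)
  p_exact <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
  expect_equal(got$p, p_exact, tolerance = 1e-12)
  expect_equal(got$w, w_obs)
  # ties fall back to the corrected normal approximation
  tied <- wilcoxonRankSum(c(1, 2, 2, 3), c(2, 3, 3, 4))
  expect_false(tied$exact)
  expect_true(tied$p > 0 && tied$p <= 1)
  expect_error(wilcoxonRankSum(numeric(0), 1), "non-empty")
})

test_that("taxonomic aggregation yields relative abundances summing to one", {
  m <- matrix(c(40L, 28L, 16L, 16L,
                10L, 10L, 10L, 10L), ncol = 2,
              dimnames = list(paste0("A", 1:4), c("S1", "S2")))
  lin <- c("Bacteria;Proteobacteria;Alphaproteobacteria;;;",
           "Bacteria;Cyanobacteria;Cyanobacteriia;;;",
           "Bacteria;Proteobacteria;Gammaproteobacteria;;;",
           "Bacteria;Proteobacteria;Gammaproteobacteria;;;")
  se <- makeTinySE(m, lin)
  rel <- aggregateTaxa(se, "class")
  expect_equal(unname(rowSums(rel)), c(1, 1), tolerance = 1e-12)
  expect_equal(rel["S1", "Gammaproteobacteria"], 0.32)  # 16+16 pooled
  expect_equal(rel["S2", "Alphaproteobacteria"], 0.25)
  # community-share arithmetic at survey-like proportions
  m2 <- matrix(c(407L, 287L, 160L, 146L), ncol = 1,
               dimnames = list(paste0("B", 1:4), "S1"))
  lin2 <- c("Bacteria;Proteobacteria;Alphaproteobacteria;;;",
            "Bacteria;Cyanobacteria;Cyanobacteriia;;;",
            "Bacteria;Proteobacteria;Gammaproteobacteria;;;",
            "Bacteria;Bacteroidota;Bacteroidia;;;")
  rel2 <- aggregateTaxa(makeTinySE(m2, lin2), "class")
  expect_equal(unname(rel2[1, c("Alphaproteobacteria", "Cyanobacteriia",
                                "Gammaproteobacteria")]),
               c(0.407, 0.287, 0.160), tolerance = 1e-12)
  # unannotated ASVs pool into Unassigned; unknown rank errors
  lin3 <- c(lin2[1:3], ";;;;;")
  rel3 <- aggregateTaxa(makeTinySE(m2, lin3), "class")
  expect_equal(rel3[1, "Unassigned"], 0.146)
  expect_error(aggregateTaxa(makeTinySE(m2, lin2), "kingdom"), "unknown rank")
})

test_that("ASV tables round-trip through TSV in either orientation", {
  m <- matrix(1:6, nrow = 3,
              dimnames = list(paste0("A", 1:3), c("S1", "S2")))
  f1 <- tempfile(); f2 <- tempfile()
  write.table(data.frame(asv_id = rownames(m), m, check.names = FALSE),
              f1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = colnames(m), t(m), check.names = FALSE),
              f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(readAsvTable(f1), readAsvTable(f2))
  bad <- tempfile()
  write.table(data.frame(id = rownames(m), m), bad, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(readAsvTable(bad), "asv_id")
})
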