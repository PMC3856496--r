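test_that("module F1 follows set arithmetic over the three namespaces", {
  a <- mkModule(1, paste0("g", 1:40), paste0("c", 1:40), paste0("t", 1:10))
  expect_equal(moduleF1(a, a), 1.0)

  b <- mkModule(2, paste0("h", 1:40), paste0("d", 1:40), paste0("s", 1:10))
  expect_equal(moduleF1(a, b), 0.0)

  # found recovers only the 40 genes of a 40+40+10-element truth module:
  # precision 40/40 = 1, recall 40/90, F1 = 2*(40/90)/(1 + 40/90) = 8/13
  g <- mkModule(3, paste0("g", 1:40), character(0), character(0))
  expect_equal(moduleF1(g, a), 2 * (40 / 90) / (1 + 40 / 90))
  expect_equal(moduleF1(g, a), 8 / 13)

  # empty found module scores 0 without error
  e <- mkModule(4, character(0), character(0), character(0))
  expect_equal(moduleF1(e, a), 0)

  # same gene label in the gene and condition namespaces must not collide
  x <- mkModule(5, "m1", character(0), character(0))
  y <- mkModule(6, character(0), "m1", character(0))
  expect_equal(moduleF1(x, y), 0)
})

test_that("fscore is the matched mean F1, invariant to module order", {
  truth <- list(mkModule(1, paste0("g", 1:5), paste0("c", 1:5), "t1"),
                mkModule(2, paste0("g", 6:10), paste0("c", 6:10), "t2"))
  found <- truth[c(2, 1)]
  expect_equal(moduleFscore(found, truth), 1.0)
  expect_equal(moduleFscore(truth, truth), 1.0)

  empty <- list(mkModule(1, character(0), character(0), character(0)),
                mkModule(2, character(0), character(0), character(0)))
  expect_equal(moduleFscore(empty, truth), 0.0)

  # crossed overlap: the matching must pick the better of both assignments,
  # verified by enumerating both permutations of a 2x2 F1 matrix
  f1 <- matrix(0, 2, 2)
  foundX <- list(mkModule(1, paste0("g", 1:4), paste0("c", 1:5), "t1"),
                 mkModule(2, paste0("g", c(1, 6:8)), paste0("c", 6:10), "t2"))
  for (i in 1:2) for (j in 1:2) f1[i, j] <- moduleF1(foundX[[i]], truth[[j]])
  bestAssign <- max(f1[1, 1] + f1[2, 2], f1[1, 2] + f1[2, 1]) / 2
  expect_equal(moduleFscore(foundX, truth), bestAssign)
})

test_that("fscore is monotone in correct members of a matched module", {
  truth <- list(mkModule(1, paste0("g", 1:6), paste0("c", 1:4), "t1"))
  partial <- list(mkModule(1, paste0("g", 1:3), paste0("c", 1:4), "t1"))
  fuller <- list(mkModule(1, paste0("g", 1:4), paste0("c", 1:4), "t1"))
  expect_gte(moduleFscore(fuller, truth), moduleFscore(partial, truth))
})

test_that("NMI matches a hand-checked contingency computation", {
  # 10-element universe; labelings x = (1,1,1,2,2,2,0,0,0,0) and
  # y = (1,1,2,2,2,0,0,0,0,1); value frozen from an independent
  # contingency-table evaluation of I(X;Y)/sqrt(H(X)H(Y))
  uni <- paste0("gene:g", 1:10)
  found <- list(mkModule(1, paste0("g", 1:3), character(0), character(0)),
                mkModule(2, paste0("g", 4:6), character(0), character(0)))
  truth <- list(mkModule(1, paste0("g", c(1, 2, 10)), character(0),
                         character(0)),
                mkModule(2, paste0("g", 3:5), character(0), character(0)))
  expect_equal(moduleNMI(found, truth, universe = uni), 0.4427012833460499,
               tolerance = 1e-12)
})

test_that("NMI honors its boundary conventions", {
  uni <- paste0("gene:g", 1:8)
  part <- list(mkModule(1, paste0("g", 1:4), character(0), character(0)),
               mkModule(2, paste0("g", 5:8), character(0), character(0)))
  expect_equal(moduleNMI(part, part, universe = uni), 1.0)
  # permutation of module order on one side changes nothing
  expect_equal(moduleNMI(part[c(2, 1)], part, universe = uni), 1.0)

  allbg <- list(mkModule(1, character(0), character(0), character(0)))
  expect_equal(moduleNMI(allbg, part, universe = uni), 0.0)
  expect_equal(moduleNMI(allbg, allbg, universe = uni), 1.0)
})

test_that("scores stay in [0, 1] on random module sets", {
  set.seed(77)
  labs <- paste0("g", 1:12)
  for (trial in 1:25) {
    found <- lapply(1:2, function(k)
      mkModule(k, sample(labs, sample(0:6, 1)), character(0), character(0)))
    truth <- lapply(1:2, function(k)
      mkModule(k, sample(labs, sample(1:6, 1)), character(0), character(0)))
    fs <- moduleFscore(found, truth)
    nm <- moduleNMI(found, truth, universe = paste0("gene:", labs))
    expect_gte(fs, 0); expect_lte(fs, 1)
    expect_gte(nm, 0); expect_lte(nm, 1)
    # Fscore is permutation-invariant even for overlapping modules
    expect_equal(moduleFscore(found[c(2, 1)], truth[c(2, 1)]), fs)

    # NMI permutation invariance holds for disjoint module sets (with
    # overlapping found modules the index tie-break is order-dependent by
    # construction, which is why fits pass their factors for resolution)
    split1 <- sample(labs, 8)
    split2 <- sample(labs, 8)
    dfound <- list(mkModule(1, split1[1:4], character(0), character(0)),
                   mkModule(2, split1[5:8], character(0), character(0)))
    dtruth <- list(mkModule(1, split2[1:4], character(0), character(0)),
                   mkModule(2, split2[5:8], character(0), character(0)))
    nmd <- moduleNMI(dfound, dtruth, universe = paste0("gene:", labs))
    expect_equal(moduleNMI(dfound[c(2, 1)], dtruth[c(2, 1)],
                           universe = paste0("gene:", labs)), nmd)
  }
})

test_that("evaluateModules bundles scores with the matching table", {
  sim <- generatePlantedTensor(n1 = 20, n2 = 20, n3 = 10, K = 2,
                               genesPerModule = 6, conditionsPerModule = 6,
                               intervalLength = 3, noiseDensity = 0, seed = 6)
  rep <- evaluateModules(truthModules(sim$truth), sim$truth)
  expect_equal(rep$fscore, 1.0)
  expect_equal(rep$nmi, 1.0)
  expect_equal(nrow(rep$matching), 2L)
  expect_equal(sort(rep$matching$truth), 1:2)
  expect_equal(unname(rep$perModuleF1), c(1, 1))
})
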