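# Identity-selectivity screen, encoded-identity criterion, SI/MI
# classification and summaries.

test_that("constant units are non-selective and groups must have >= 2", {
  r <- rbind(rep(1, 30), rnorm(30))
  a <- ActivationSet(r, rep(letters[1:10], each = 3))
  p <- anovaScreen(a)
  expect_equal(p@pAnova[1], 1)
  expect_false(p@selective[1])
  bad <- ActivationSet(matrix(rnorm(10), 2, 5),
                       c("a", "a", "b", "b", "c"))
  expect_error(anovaScreen(bad), "at least 2 stimuli")
})

test_that("screen p-value equals the direct F-test oracle", {
  set.seed(77)
  x <- rnorm(80)
  g <- factor(rep(1:8, each = 10))
  x[g == 7] <- x[g == 7] + 3
  a <- ActivationSet(matrix(x, 1, 80), g)
  p <- anovaScreen(a)@pAnova
  want <- oneway.test(x ~ g, var.equal = TRUE)$p.value
  expect_lt(p, 0.01)
  expect_equal(p, want, tolerance = 1e-10)
})

test_that("null units are flagged at the nominal rate", {
  set.seed(5)
  X <- matrix(rnorm(800 * 100), 800, 100)
  a <- ActivationSet(X, rep(sprintf("i%02d", 1:20), each = 5))
  p <- anovaScreen(a, alpha = 0.01)
  expect_lt(abs(mean(p@selective) - 0.01), 3 * sqrt(0.01 * 0.99 / 800))
})

test_that("encoded identities follow the k-SD criterion exactly", {
  id <- rep(sprintf("i%02d", 1:10), each = 3)
  expect_identical(encodedIdentities(rep(2, 30), id), character(0))
  r <- rnorm(30, sd = 0.01)
  r[id == "i04"] <- 50
  expect_identical(encodedIdentities(r, id), "i04")
  expect_error(encodedIdentities(rnorm(4), rep(c("a", "b"), 2)),
               "at least 3")

  # direct criterion oracle on a fixed-seed draw with two planted means
  set.seed(12)
  means <- rnorm(50)
  means[c(7, 31)] <- means[c(7, 31)] + 3 * sd(means[-c(7, 31)])
  ids <- sprintf("i%02d", 1:50)
  resp <- rep(means, each = 2)                   # two identical stimuli each
  got <- encodedIdentities(resp, rep(ids, each = 2))
  thr <- mean(means) + 2 * sd(means)
  expect_identical(got, sort(ids[means > thr]))
})

test_that("encoded-identity criterion is independent of alpha and scale", {
  g <- smallExperiment(seed = 6)
  a <- g$layers[[1]]
  p1 <- selectivityProfile(a, alpha = 0.01)
  p2 <- selectivityProfile(a, alpha = 0.2)
  sel <- p1@selective & p2@selective
  expect_identical(p1@encoded[sel], p2@encoded[sel])
  # scale invariance: multiplying a unit's responses by c > 0
  X <- responses(a)
  X[3, ] <- X[3, ] * 7.5
  aS <- ActivationSet(X, identities(a))
  pS <- selectivityProfile(aS)
  expect_equal(pS@pAnova[3], p1@pAnova[3], tolerance = 1e-9)
  expect_identical(pS@encoded[[3]], p1@encoded[[3]])
})

test_that("classes partition units and recover strong planted structure", {
  g <- genActivations(syntheticSpec(unitsPerLayer = 300, nIdentities = 30,
                                    nPerIdentity = 8, fracSelective = 0.3,
                                    fracMulti = 0.5, effectSize = 4,
                                    seed = 55))
  a <- g$layers[[1]]
  prof <- selectivityProfile(a)
  expect_setequal(unique(prof@unitClass),
                  intersect(c("SI", "MI", "selective-other",
                              "non-selective"), prof@unitClass))
  expect_equal(sum(table(prof@unitClass)), 300)
  truth <- g$truth
  recallSI <- mean(prof@unitClass[truth$class == "SI"] == "SI")
  recallMI <- mean(prof@unitClass[truth$class == "MI"] == "MI")
  expect_gte(recallSI, 0.9)
  expect_gte(recallMI, 0.9)
  # recovered encoded sets match the planted ones for recovered units
  hit <- which(truth$class == "SI" & prof@unitClass == "SI")
  expect_identical(prof@encoded[hit], truth$encoded[hit])
})

test_that("SI+MI false-positive rate on null data stays below alpha", {
  set.seed(9)
  X <- matrix(rnorm(600 * 100), 600, 100)
  a <- ActivationSet(X, rep(sprintf("i%02d", 1:20), each = 5))
  prof <- selectivityProfile(a, alpha = 0.01)
  expect_lte(mean(prof@unitClass %in% c("SI", "MI")), 0.01)
})

test_that("layer summaries are exact recounts", {
  # hand-built profile: 10 units, 3 SI, 2 MI with |encoded| 2 and 4
  enc <- c(replicate(3, "a", simplify = FALSE),
           list(c("a", "b"), c("a", "b", "c", "d")),
           replicate(5, character(0), simplify = FALSE))
  prof <- new("SelectivityProfile",
              unitId = paste0("u", 1:10),
              pAnova = c(rep(0.001, 5), rep(0.5, 5)),
              selective = c(rep(TRUE, 5), rep(FALSE, 5)),
              encoded = enc,
              unitClass = c(rep("SI", 3), rep("MI", 2),
                            rep("non-selective", 5)),
              alpha = 0.01, kSd = 2, layerId = "L")
  s <- layerSummary(prof)
  expect_equal(s$pct_selective, 50)
  expect_equal(s$pct_SI, 30)
  expect_equal(s$pct_MI, 20)
  expect_equal(s$mean_encoded_MI, 3)
  expect_equal(s$max_encoded_MI, 4)

  # a layer without MI units reports absent MI statistics, not zero
  prof0 <- new("SelectivityProfile",
               unitId = "u1", pAnova = 1, selective = FALSE,
               encoded = list(character(0)),
               unitClass = "non-selective",
               alpha = 0.01, kSd = 2, layerId = "L0")
  s0 <- layerSummary(prof0)
  expect_true(is.na(s0$mean_encoded_MI) && is.na(s0$max_encoded_MI))
  expect_equal(s0$pct_selective, 0)

  # multi-layer synthetic set equals a direct recount
  g <- genActivations(syntheticSpec(nLayers = 2, unitsPerLayer = 60,
                                    nIdentities = 10, nPerIdentity = 4,
                                    seed = 3))
  profs <- lapply(g$layers, selectivityProfile)
  s2 <- layerSummary(profs)
  for (l in 1:2) {
    cls <- profs[[l]]@unitClass
    expect_equal(s2$pct_SI[l], 100 * mean(cls == "SI"))
    expect_equal(s2$pct_MI[l], 100 * mean(cls == "MI"))
  }
})

test_that("proportion comparison matches the hand-computed chi-square", {
  expect_equal(compareProportions(50, 100, 50, 100)$pCorrected, 1)
  r <- compareProportions(90, 100, 10, 100)
  # Pearson chi-square of a 2x2 table, by hand:
  # N (ad - bc)^2 / (r1 r2 c1 c2) = 200 * (8100-100)^2 / 100^4 = 128
  expect_equal(r$chisq, 128, tolerance = 1e-10)
  expect_lt(r$p, 0.001)
  r20 <- compareProportions(60, 100, 45, 100, nComparisons = 20)
  expect_equal(r20$pCorrected, min(1, r20$p * 20))
  expect_error(compareProportions(5, 3, 1, 10), "exceed")
})
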