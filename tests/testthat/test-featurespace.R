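# Embeddings, density maps and the region-based feature-coding detector.

# planted embedding: identity clusters on a ring, stimuli jittered around
# their identity center
plantedEmbedding <- function(nId = 8, per = 10, spread = 0.05, seed = 3) {
  set.seed(seed)
  ang <- 2 * pi * seq_len(nId) / nId
  centers <- cbind(cos(ang), sin(ang))
  co <- centers[rep(seq_len(nId), each = per), ] +
    matrix(rnorm(nId * per * 2, sd = spread), ncol = 2)
  list(emb = buildEmbedding(co, method = "precomputed", coords = co),
       identity = rep(sprintf("i%02d", seq_len(nId)), each = per),
       centers = centers)
}

test_that("PCA embeddings are exact, seed-free and dimension-checked", {
  set.seed(41)
  co <- matrix(rnorm(60), 30, 2)
  emb <- buildEmbedding(co, method = "pca")
  # 2-d input: PCA coordinates equal the input up to rotation/sign
  d1 <- as.matrix(dist(co))
  d2 <- as.matrix(dist(coordinates(emb)))
  expect_equal(d1, d2, tolerance = 1e-10)
  expect_identical(coordinates(buildEmbedding(co, method = "pca")),
                   coordinates(emb))
  expect_error(buildEmbedding(co, d = 4), "2 or 3")
  expect_error(buildEmbedding(co[1:2, ]), "at least 3")
  expect_error(buildEmbedding(co, method = "tsne"), "fun")
  # pluggable stochastic embedding is seeded and tagged
  fakeTsne <- function(features, d, seed, ...)
    features[, 1:d] + matrix(rnorm(nrow(features) * d, sd = 0.01),
                             ncol = d)
  e1 <- buildEmbedding(co, method = "tsne", fun = fakeTsne, seed = 5)
  e2 <- buildEmbedding(co, method = "tsne", fun = fakeTsne, seed = 5)
  expect_identical(coordinates(e1), coordinates(e2))
  expect_identical(e1@method, "tsne")
})

test_that("embedding preserves planted cluster structure", {
  g <- genActivations(syntheticSpec(unitsPerLayer = 60, nIdentities = 6,
                                    nPerIdentity = 10, fracSelective = 0.8,
                                    effectSize = 6, seed = 47))
  a <- g$layers[[1]]
  emb <- buildEmbedding(t(responses(a)), method = "pca")
  co <- coordinates(emb)
  id <- as.character(identities(a))
  # 1-NN identity accuracy above chance
  d <- as.matrix(dist(co)); diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  expect_gt(mean(id[nn] == id), 3 / 6)
})

test_that("density maps match a brute-force KDE oracle", {
  co <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(0.5, 0.5))
  emb <- buildEmbedding(co, method = "precomputed", coords = co)
  w <- c(1, 2, 0.5, 0, 3)
  g <- 20L
  dm <- densityMap(emb, w, gridSize = g, kernelSd = 2)
  # independent per-pixel Gaussian-sum oracle in grid units
  px <- co * (g - 1) + 1
  half <- 0.2 * g / 2
  want <- matrix(0, g, g)
  for (i in seq_len(g)) for (j in seq_len(g)) for (s in 1:5) {
    dx <- i - px[s, 1]; dy <- j - px[s, 2]
    if (abs(dx) <= half && abs(dy) <= half)
      want[i, j] <- want[i, j] + w[s] * exp(-(dx^2 + dy^2) / (2 * 4))
  }
  expect_equal(dm@grid, want, tolerance = 1e-8)

  # all weight on one stimulus: maximum at that stimulus's pixel
  dm1 <- densityMap(emb, c(0, 0, 0, 0, 1), gridSize = g, kernelSd = 2)
  ix <- which(dm1@grid == max(dm1@grid), arr.ind = TRUE)
  expect_equal(unname(ix[1, ]), round(px[5, ]))

  # uniform rescaling of coordinates leaves the map unchanged
  emb10 <- buildEmbedding(co * 10, method = "precomputed",
                          coords = co * 10)
  dm10 <- densityMap(emb10, w, gridSize = g, kernelSd = 2)
  expect_equal(dm10@grid, dm@grid, tolerance = 1e-10)

  # zero weights: flagged zero map
  dm0 <- densityMap(emb, rep(0, 5), gridSize = g)
  expect_true(all(dm0@grid == 0))
  expect_true(isTRUE(attr(dm0, "zeroWeight")))
  expect_error(densityMap(emb, c(-1, 1, 1, 1, 1)), "non-negative")
})

test_that("connected components are labelled with 8-connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE          # diagonal touch: one component
  m[5, 5] <- TRUE                           # far corner: another
  lab <- idcoding:::labelComponents(m)
  expect_equal(max(lab), 2)
  expect_equal(lab[1, 1], lab[2, 2])
  expect_true(lab[5, 5] != lab[1, 1])
  lab4 <- idcoding:::labelComponents(m, connectivity = 4L)
  expect_equal(max(lab4), 3)
})

test_that("tuning-region detector recovers planted tuning and stays quiet
           on null units", {
  pe <- plantedEmbedding()
  co <- coordinates(pe$emb)
  # planted unit: Gaussian tuning centered on identity 1's cluster center
  ctr <- pe$centers[1, ]
  d2 <- (co[, 1] - ctr[1])^2 + (co[, 2] - ctr[2])^2
  w <- exp(-d2 / (2 * 0.08^2)) * 10
  g <- 50L
  tr <- tuningRegion(pe$emb, w, nPerm = 250, alpha = 0.04, gridSize = g,
                     seed = 4)
  expect_false(is.null(tr))
  # detected region contains the planted center
  geom <- idcoding:::gridGeometry(pe$emb, g)
  cpx <- round((ctr - geom$lo) / (geom$hi - geom$lo) * (g - 1) + 1)
  expect_true(tr$mask[cpx[1], cpx[2]])
  expect_lt(tr$areaFraction, 0.5)
  # all-zero unit: no region
  expect_null(tuningRegion(pe$emb, rep(0, nrow(co)), nPerm = 250,
                           alpha = 0.04, gridSize = g))
  expect_error(tuningRegion(pe$emb, w, nPerm = 100, alpha = 0.01),
               "nPerm")   # alpha resolution rule: nPerm >= 10 / alpha
  # label-exchangeable units under the cluster-permutation control are
  # flagged at no more than the cluster-level alpha
  set.seed(9)
  hits <- vapply(1:25, function(i) {
    !is.null(tuningRegion(pe$emb, sample(w), nPerm = 250, alpha = 0.05,
                          clusterRule = "nullmax", gridSize = g, seed = i))
  }, TRUE)
  expect_lte(mean(hits), 0.05 + 3 * sqrt(0.05 * 0.95 / 25))
})

test_that("feature-MI classification separates adjacent from dispersed
           encoded sets", {
  pe <- plantedEmbedding(nId = 8, per = 8, seed = 6)
  co <- coordinates(pe$emb)
  nStim <- nrow(co)
  ids <- sprintf("i%02d", 1:8)
  # adjacent pair (1, 2) on the ring vs opposite pair (1, 5)
  dAdj <- normalizedIdentityDistance(pe$emb, pe$identity, ids[c(1, 2)])
  dFar <- normalizedIdentityDistance(pe$emb, pe$identity, ids[c(1, 5)])
  expect_lt(dAdj, dFar)
  expect_gte(dAdj, 0); expect_lte(dFar, 1)
  # two identities at opposite bounding-box corners: distance 1
  sq <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1), c(0.5, 0.4), c(0.5, 0.6))
  embSq <- buildEmbedding(sq, method = "precomputed", coords = sq)
  idsSq <- c("a", "a", "b", "b", "c", "c")
  expect_equal(normalizedIdentityDistance(embSq, idsSq, c("a", "b")), 1)
  expect_equal(normalizedIdentityDistance(embSq, idsSq, c("c", "c")), 0)
  expect_warning(nd <- normalizedIdentityDistance(embSq, idsSq, "a"),
                 "fewer than 2")
  expect_true(is.na(nd))
  # 3-identity hand geometry: centroids (0,0), (1,1), (0.5, 0.5)
  want <- mean(c(sqrt(2), sqrt(0.5), sqrt(0.5))) / sqrt(2)
  expect_equal(normalizedIdentityDistance(embSq, idsSq, c("a", "b", "c")),
               want, tolerance = 1e-12)
})

test_that("region statistics are pixel recounts", {
  mask <- matrix(TRUE, 10, 10)
  r1 <- structure(list(mask = rbind(matrix(TRUE, 5, 10),
                                    matrix(FALSE, 5, 10))),
                  class = "TuningRegion")
  s1 <- regionStatistics(list(r1), mask)
  expect_equal(s1$areaFraction, 0.5)
  expect_equal(s1$coverage, 0.5)
  # two disjoint quarter regions
  q1 <- matrix(FALSE, 10, 10); q1[1:5, 1:5] <- TRUE
  q2 <- matrix(FALSE, 10, 10); q2[6:10, 6:10] <- TRUE
  s2 <- regionStatistics(list(structure(list(mask = q1),
                                        class = "TuningRegion"),
                              structure(list(mask = q2),
                                        class = "TuningRegion"),
                              NULL),
                         mask)
  expect_equal(s2$coverage, 0.5)
  expect_equal(max(s2$overlap), 1)
  expect_equal(s2$areaFraction, c(0.25, 0.25))
  # random region set equals a direct recount
  set.seed(13)
  regs <- replicate(4, structure(list(
    mask = matrix(runif(100) < 0.3, 10, 10)), class = "TuningRegion"),
    simplify = FALSE)
  s3 <- regionStatistics(regs, mask)
  un <- Reduce(`|`, lapply(regs, `[[`, "mask"))
  expect_equal(s3$coverage, mean(un))
})
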