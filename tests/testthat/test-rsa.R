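# Representational dissimilarity matrices, geometry correlations and
# permutation tests.

test_that("identity means are exact recounts", {
  set.seed(21)
  X <- matrix(rnorm(12 * 4), 12, 4)
  id <- rep(c("a", "b", "c"), each = 4)
  m <- identityMeans(X, id)
  expect_equal(m["b", ], colMeans(X[5:8, ]))
  # duplicated stimuli leave the means unchanged
  m2 <- identityMeans(rbind(X, X), c(id, id))
  expect_equal(m, m2)
  # single stimulus per identity: rows equal stimulus rows
  m1 <- identityMeans(X[1:3, ], c("a", "b", "c"))
  expect_equal(unname(m1), unname(X[1:3, ]))
  expect_error(identityMeans(X, id[1:5]), "one identity per stimulus")
})

test_that("RDM entries are 1 - Pearson r with hand-checked values", {
  m <- matrix(rnorm(20), 4, 5,
              dimnames = list(paste0("i", 1:4), NULL))
  m[2, ] <- 2 * m[1, ] + 3                 # perfectly correlated pair
  m[3, ] <- -(m[1, ] - mean(m[1, ])) + 1   # perfectly anticorrelated
  rdm <- buildRDM(m)
  D <- dissimilarities(rdm)
  expect_equal(D["i1", "i2"], 0, tolerance = 1e-12)
  expect_equal(D["i1", "i3"], 2, tolerance = 1e-12)
  expect_equal(diag(D), setNames(rep(0, 4), paste0("i", 1:4)))
  expect_equal(D, t(D))
  # hand computation on a 3 x 4 toy matrix
  t3 <- matrix(c(1, 2, 3, 4,
                 2, 1, 4, 3,
                 4, 3, 2, 1), 3, 4, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), NULL))
  D3 <- dissimilarities(buildRDM(t3))
  expect_equal(D3["a", "b"], 1 - cor(t3[1, ], t3[2, ]), tolerance = 1e-12)
  expect_equal(D3["a", "c"], 1 - cor(t3[1, ], t3[3, ]), tolerance = 1e-12)
  # zero-variance rows are flagged NA
  t3[2, ] <- 5
  Dz <- dissimilarities(buildRDM(t3))
  expect_true(all(is.na(Dz["b", c("a", "c")])))
  expect_false(anyNA(Dz["a", "c"]))
})

test_that("RDMs are invariant to global affine transforms of responses", {
  set.seed(31)
  m <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("i", 1:8), NULL))
  D1 <- dissimilarities(buildRDM(m))
  D2 <- dissimilarities(buildRDM(3.2 * m + 7))
  expect_equal(D1, D2, tolerance = 1e-10)
})

test_that("RDM correlation uses the upper triangle with rank ties", {
  set.seed(32)
  m <- matrix(rnorm(30), 6, 5, dimnames = list(paste0("i", 1:6), NULL))
  A <- buildRDM(m)
  expect_equal(rdmCorrelation(A, A), 1)
  # rank reversal: B = 2 - A entries realized through anticorrelated rows
  ut <- upper.tri(dissimilarities(A))
  B <- A
  B@D <- 2 - A@D; diag(B@D) <- 0
  expect_equal(rdmCorrelation(A, B), -1)
  # direct rank-correlation oracle on a 4-identity pair
  m2 <- matrix(rnorm(20), 4, 5, dimnames = list(paste0("i", 1:4), NULL))
  A4 <- buildRDM(m[1:4, , drop = FALSE]); B4 <- buildRDM(m2)
  want <- cor(A4@D[upper.tri(A4@D)], B4@D[upper.tri(B4@D)],
              method = "spearman")
  expect_equal(rdmCorrelation(A4, B4), want)
  # identity mismatch
  C <- buildRDM(m2[c(2, 1, 3, 4), , drop = FALSE])
  expect_error(rdmCorrelation(A4, C), "match")
})

test_that("permutation p-values follow the add-one rule and boundaries", {
  g <- smallExperiment(seed = 42)
  a <- g$layers[[1]]
  X <- t(responses(a))
  # test population identical to reference: observed beats every null draw
  r <- rdmPermutationTest(X, X, identity = identities(a), nPerm = 200,
                          seed = 1)
  expect_equal(r$rho, 1)
  expect_equal(r$p, 1 / 201)
  expect_true(r$significant)
  expect_length(r$null, 200)
  expect_warning(rdmPermutationTest(X, X, identity = identities(a),
                                    nPerm = 50, seed = 1), "unstable")
})

test_that("independent populations are significant at the nominal rate", {
  g <- smallExperiment(seed = 43)
  a <- g$layers[[1]]
  X <- t(responses(a))
  hits <- vapply(1:60, function(s) {
    set.seed(s + 500)
    Y <- matrix(rnorm(nrow(X) * 30), nrow(X), 30,
                dimnames = list(rownames(X), NULL))
    rdmPermutationTest(X, Y, identity = identities(a), nPerm = 120,
                       seed = s)$significant
  }, TRUE)
  expect_lt(abs(mean(hits) - 0.05), 3 * sqrt(0.05 * 0.95 / 60) + 0.01)
})

test_that("layer correction behaves like the stated procedures", {
  r <- correctLayers(c(0.001, 0.04, 0.2), method = "bonferroni", q = 0.05)
  expect_identical(r$flag, c(TRUE, FALSE, FALSE))
  expect_true(correctLayers(0.01, method = "bonferroni")$flag)
  expect_true(correctLayers(0.01, method = "fdr_bh")$flag)
  expect_false(any(correctLayers(rep(1, 4), method = "fdr_bh")$flag))
  expect_error(correctLayers(c(0.5, 0)), "\\(0, 1\\]")
  # Bonferroni flags are a subset of FDR flags
  set.seed(33)
  for (i in 1:20) {
    p <- runif(8)^2
    bf <- correctLayers(p, "bonferroni")$flag
    fd <- correctLayers(p, "fdr_bh")$flag
    expect_true(all(fd[bf]))
  }
})

test_that("top encoded identities are ranked by neuron counts", {
  mk <- function(encList) {
    n <- length(encList)
    new("SelectivityProfile", unitId = paste0("u", seq_len(n)),
        pAnova = rep(0.001, n), selective = rep(TRUE, n),
        encoded = encList,
        unitClass = ifelse(lengths(encList) == 1, "SI",
                    ifelse(lengths(encList) >= 2, "MI",
                           "selective-other")),
        alpha = 0.01, kSd = 2, layerId = "L")
  }
  prof <- mk(list("a", c("a", "b"), c("a", "c"), "b"))
  expect_identical(topEncodedSubset(prof, k = 2), c("a", "b"))
  expect_warning(all3 <- topEncodedSubset(prof, k = 10), "only 3")
  expect_identical(all3, c("a", "b", "c"))
  empty <- mk(list(character(0), character(0)))
  expect_warning(none <- topEncodedSubset(empty), "no identity")
  expect_identical(none, character(0))
  # planted frequencies equal a recount
  set.seed(34)
  ids <- sprintf("i%02d", 1:8)
  encList <- replicate(40, sample(ids, sample(0:3, 1)), simplify = FALSE)
  prof2 <- mk(lapply(encList, sort))
  counts <- sort(table(unlist(encList)), decreasing = TRUE)
  got <- topEncodedSubset(prof2, k = 5)
  cnt <- table(unlist(encList))
  expect_true(all(cnt[got] >= max(cnt[setdiff(names(cnt), got)])))
})

test_that("temporal correspondence respects latency and degenerates safely", {
  g <- smallExperiment(seed = 45)
  a <- g$layers[[1]]
  st <- genPseudoNeurons(40, a, coupling = 0.9, latencyMs = 250, seed = 2)
  bins <- humanBins()[c(1, 2, 10, 15), ]       # subset for speed
  tc <- temporalCorrespondence(st, a, bins, nPerm = 150, seed = 3,
                               pad = TRUE)
  pre <- tc$end <= 250
  expect_false(any(tc$significant[pre]))
  expect_true(any(tc$significant[!pre]))
  # constant-rate neurons: undefined everywhere, never significant
  sp <- data.frame(neuron_id = "n1",
                   trial_id = rep(seq_len(ncol(responses(a))), each = 2),
                   t_ms = rep(c(100, 500), ncol(responses(a))))
  trs <- data.frame(trial_id = seq_len(ncol(responses(a))),
                    stimulus_id = colnames(responses(a)),
                    identity = as.character(identities(a)))
  stc <- SpikeTrains(sp, trs)
  tcc <- temporalCorrespondence(stc, a, bins, nPerm = 150, seed = 3,
                                pad = TRUE)
  expect_true(all(is.na(tcc$rho)))
  expect_false(any(tcc$significant))
})
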