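# Shared fixtures, built in code at test time.

# small activation experiment with planted structure
smallExperiment <- function(units = 100, ids = 20, per = 5,
                            fracSel = 0.2, fracMulti = 0.3, d = 3,
                            seed = 2) {
  genActivations(syntheticSpec(unitsPerLayer = units, nIdentities = ids,
                               nPerIdentity = per, fracSelective = fracSel,
                               fracMulti = fracMulti, effectSize = d,
                               seed = seed))
}

# independent naive 2D Gaussian filter with symmetric (reflective)
# boundary handling: direct per-pixel double loop, no shared code with
# gaussianBlur()
naiveGaussianBlur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k1 <- exp(-(-r:r)^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  n <- nrow(img); m <- ncol(img)
  mirror <- function(i, n) {
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- mirror(i + di, n); jj <- mirror(j + dj, m)
      acc <- acc + k2[di + r + 1, dj + r + 1] * img[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# independent direct convolution oracle: 3x3, stride 1, zero padding 1,
# plain quadruple loop
naiveConv3x3 <- function(x, weights, bias) {
  # x: h x w x inC (single image); weights 3x3xinCxoutC
  h <- dim(x)[1]; w <- dim(x)[2]; inC <- dim(x)[3]
  outC <- dim(weights)[4]
  out <- array(0, c(h, w, outC))
  for (oc in seq_len(outC)) for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- bias[oc]
    for (ic in seq_len(inC)) for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w)
        acc <- acc + weights[di + 2, dj + 2, ic, oc] * x[ii, jj, ic]
    }
    out[i, j, oc] <- acc
  }
  out
}

# Monte-Carlo oracle for one-way ANOVA power with one group shifted by
# d standard deviations (matches a planted SI unit): direct simulation
# of the F test through stats::oneway.test
anovaPowerOracle <- function(k, n, d, alpha = 0.01, nSim = 400,
                             seed = 99) {
  set.seed(seed)
  hits <- vapply(seq_len(nSim), function(i) {
    x <- rnorm(k * n)
    x[seq_len(n)] <- x[seq_len(n)] + d
    g <- factor(rep(seq_len(k), each = n))
    oneway.test(x ~ g, var.equal = TRUE)$p.value < alpha
  }, TRUE)
  mean(hits)
}
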