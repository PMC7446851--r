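test_that("FeatureConfig arithmetic: F, N, p, effective-width guard", {
  cfg <- FeatureConfig(cutoff = 15, feRatio = 0.5, binSize = 0.5)
  expect_equal(filtrationMax(cfg), 7.5)
  expect_equal(nBins(cfg), 15L)
  expect_equal(nFeatures(cfg), 4L * 2L * 15L)

  # rounding: F = 6, f = 0.8 -> N = round(7.5) = 8, width 0.75 (within 25%)
  cfg2 <- FeatureConfig(cutoff = 12, feRatio = 0.5, binSize = 0.8)
  expect_equal(nBins(cfg2), 8L)

  # N floors at 1 when f >= F (width F within 25% of f required)
  expect_error(FeatureConfig(cutoff = 2, feRatio = 0.5, binSize = 10),
               "effective bin width")
  # a mildly off width is accepted
  expect_silent(FeatureConfig(cutoff = 2, feRatio = 0.5, binSize = 1.1))

  # element order is fixed C, N, O, P regardless of input order
  cfg3 <- FeatureConfig(elements = c("P", "C"))
  expect_identical(cfg3@elements, c("C", "P"))
  expect_error(FeatureConfig(feRatio = 1.5), "feRatio")
  expect_error(FeatureConfig(cutoff = -1), "cutoff")
})

test_that("extractLocalRegion selects by element and always keeps the centre", {
  atoms <- data.frame(chain = "A", resno = 1:5, resid = "A",
                      elety = c("C1'", "C2", "N9", "O5'", "P"),
                      element = c("C", "C", "N", "O", "P"),
                      x = c(0, 1, 2, 10, 3), y = 0, z = 0, b = 1)
  center <- atoms[1, ]
  cC <- extractLocalRegion(atoms, center, cutoff = 5, element = "C")
  expect_equal(nrow(cC), 2L)            # centre selects itself, no duplicate
  cN <- extractLocalRegion(atoms, center, cutoff = 5, element = "N")
  expect_equal(nrow(cN), 2L)            # N9 plus appended centre
  expect_true(any(cN[, 1] == 0 & cN[, 2] == 0 & cN[, 3] == 0))
  cO <- extractLocalRegion(atoms, center, cutoff = 5, element = "O")
  expect_equal(nrow(cO), 1L)            # O5' is out of range; centre alone
  # boundary is inclusive
  cO2 <- extractLocalRegion(atoms, center, cutoff = 10, element = "O")
  expect_equal(nrow(cO2), 2L)
})

test_that("binBarcode matches the counting definition exactly", {
  # F = 2, N = 4, grid 0.5 1.0 1.5 2.0
  bars <- data.frame(birth = c(0, 0.5, 1.2), death = c(0.7, Inf, 1.5))
  expect_identical(binBarcode(bars, 2, 4L), c(2L, 1L, 2L, 1L))
  # inclusive at births and deaths
  edge <- data.frame(birth = 0.5, death = 1.0)
  expect_identical(binBarcode(edge, 2, 4L), c(1L, 1L, 0L, 0L))
  # empty barcode -> zeros; infinite bar -> all ones
  expect_identical(binBarcode(data.frame(birth = numeric(0),
                                         death = numeric(0)), 2, 3L),
                   integer(3))
  expect_identical(binBarcode(data.frame(birth = 0, death = Inf), 2, 3L),
                   c(1L, 1L, 1L))
  # brute-force cross-check on random bars
  set.seed(19)
  for (i in 1:10) {
    nb <- sample(1:8, 1)
    b <- runif(nb, 0, 2); d <- b + rexp(nb)
    d[runif(nb) < 0.3] <- Inf
    bars <- data.frame(birth = b, death = d)
    N <- sample(2:9, 1)
    manual <- vapply(seq_len(N) * 2 / N, function(g)
      sum(b <= g & g <= d), integer(1))
    expect_identical(binBarcode(bars, 2, N), manual)
  }
})

test_that("featurizeSample layout is element-major, dimension-minor", {
  cfg <- FeatureConfig(cutoff = 6, feRatio = 0.5, binSize = 1)
  N <- nBins(cfg)
  expect_equal(N, 3L)
  # carbons form a unit square around the centre; no N/O/P atoms nearby
  sq <- rbind(c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  atoms <- data.frame(chain = "A", resno = 1:4, resid = "A",
                      elety = c("C1'", "C2", "C3", "C4"),
                      element = "C",
                      x = c(0, sq[, 1]), y = c(0, sq[, 2]),
                      z = c(0, sq[, 3]), b = 1)
  v <- featurizeSample(atoms, atoms[1, ], cfg)
  expect_length(v, nFeatures(cfg))
  expect_true(is.integer(v))
  # C block: dim0 then dim1, grid at 1, 2, 3
  cBlock <- v[1:(2 * N)]
  d0 <- cBlock[1:N]; d1 <- cBlock[(N + 1):(2 * N)]
  # square barcode: dim0 deaths (1,1,1,Inf); dim1 bar (1, sqrt 2)
  expect_identical(d0, c(4L, 1L, 1L))
  expect_identical(d1, c(1L, 0L, 0L))
  # N, O, P blocks come from the lone centre: dim0 all ones, dim1 zero
  for (k in 1:3) {
    blk <- v[(2 * N * k + 1):(2 * N * (k + 1))]
    expect_identical(blk, c(rep(1L, N), rep(0L, N)))
  }
})

test_that("feature vectors are invariant under rigid motion of the chain", {
  cfg <- FeatureConfig(cutoff = 10, feRatio = 0.5, binSize = 0.5)
  ss <- smallStructures(seed = 8L, nChains = 1L, nt = c(8L, 8L))[[1]]
  atoms <- chainAtoms(ss, chainIds(ss))
  heavy <- selectHeavyAtoms(atoms)
  center <- findSampleAtoms(atoms)[3, , drop = FALSE]
  v0 <- featurizeSample(heavy, center, cfg)
  set.seed(23)
  xyz <- as.matrix(heavy[, c("x", "y", "z")])
  M <- matrix(rnorm(9), 3); R <- qr.Q(qr(M))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- runif(3, -20, 20)
  moved <- sweep(xyz %*% R, 2, shift, "+")
  heavy2 <- heavy; heavy2$x <- moved[, 1]; heavy2$y <- moved[, 2]
  heavy2$z <- moved[, 3]
  cxyz <- c(center$x, center$y, center$z) %*% R + shift
  center2 <- center
  center2$x <- cxyz[1]; center2$y <- cxyz[2]; center2$z <- cxyz[3]
  expect_identical(featurizeSample(heavy2, center2, cfg), v0)
})

test_that("buildDataset assembles a coherent TopoDataset", {
  structs <- smallStructures(seed = 14L, nChains = 2L, nt = c(6L, 9L))
  cfg <- FeatureConfig(cutoff = 8, feRatio = 0.5, binSize = 0.5)
  ds <- buildDataset(structs, cfg)
  X <- featureMatrix(ds)
  y <- targets(ds)
  ch <- chainLabels(ds)
  expect_equal(ncol(X), nFeatures(cfg))
  expect_equal(nrow(X), length(y))
  expect_equal(length(ch), length(y))
  expect_equal(length(unique(ch)), 2L)
  expect_true(all(X >= 0))
  # per-chain targets are z-normalized: mean 0, population variance 1
  for (cid in unique(ch)) {
    z <- y[ch == cid]
    expect_lt(abs(mean(z)), 1e-12)
    expect_lt(abs(mean(z^2) - 1), 1e-12)
  }
  # rowData describes the layout
  rd <- SummarizedExperiment::rowData(ds)
  expect_identical(unique(as.character(rd$element)), c("C", "N", "O", "P"))
  expect_equal(max(rd$bin), nBins(cfg))
  expect_equal(max(rd$grid), filtrationMax(cfg))
  # the config rides along
  expect_equal(featureConfig(ds)@cutoff, 8)
})

test_that("buildDataset drops outlier samples and degenerate chains", {
  structs <- smallStructures(seed = 5L, nChains = 1L, nt = c(8L, 8L))
  ss <- structs[[1]]
  # plant a gross outlier on one C1'
  idx <- which(ss@atoms$elety == "C1'")[2]
  ss@atoms$b[idx] <- 1e5
  cfg <- FeatureConfig(cutoff = 6, feRatio = 0.5, binSize = 0.5)
  clean <- buildDataset(structs, cfg)
  dirty <- buildDataset(list(ss), cfg)
  expect_equal(ncol(dirty), ncol(clean) - 1L)
  expect_false(ss@atoms$resno[idx] %in%
                 SummarizedExperiment::colData(dirty)$resno)
  # a constant-B chain is skipped entirely
  const <- structs[[1]]
  const@atoms$b <- 7
  expect_warning(expect_error(buildDataset(list(const), cfg), "no usable"),
                 "zero-variance")
})

test_that("dataset CSV round trip preserves features, targets and config", {
  structs <- smallStructures(seed = 6L, nChains = 2L, nt = c(5L, 7L))
  cfg <- FeatureConfig(cutoff = 7, feRatio = 0.6, binSize = 0.7,
                       elements = c("C", "P"), dims = 0L)
  ds <- buildDataset(structs, cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  writeDataset(ds, path)
  back <- readDataset(path)
  expect_equal(featureMatrix(back), featureMatrix(ds), ignore_attr = TRUE)
  expect_equal(targets(back), targets(ds))
  expect_identical(chainLabels(back), chainLabels(ds))
  cfg2 <- featureConfig(back)
  expect_equal(cfg2@cutoff, cfg@cutoff)
  expect_equal(cfg2@feRatio, cfg@feRatio)
  expect_identical(cfg2@elements, cfg@elements)
  expect_identical(cfg2@dims, cfg@dims)
})
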