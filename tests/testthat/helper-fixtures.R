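# shared fixtures: all synthetic, generated in code at test time

# a small folded structure set (fast to featurize)
smallStructures <- function(seed = 11L, nChains = 3L, nt = c(8L, 12L),
                            noiseSd = 2) {
  cfg <- generatorConfig(nChains = nChains, nucleotides = nt,
                         noiseSd = noiseSd, seed = seed)
  generateStructures(cfg)$structures
}

# random point cloud in a box
randomCloud <- function(n, scale = 2) {
  matrix(stats::runif(n * 3, 0, scale), ncol = 3)
}

# a random rigid motion (proper rotation + translation)
rigidMotion <- function(points) {
  M <- matrix(stats::rnorm(9), 3)
  qrd <- qr(M)
  R <- qr.Q(qrd)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- stats::runif(3, -50, 50)
  sweep(points %*% R, 2, shift, "+")
}

# compare two barcodes as multisets of (dim, birth, death) within tol
expect_same_barcode <- function(a, b, tol = 1e-9) {
  expect_equal(nrow(a), nrow(b))
  a <- a[order(a$dim, a$birth, a$death), ]
  b <- b[order(b$dim, b$birth, b$death), ]
  expect_equal(a$dim, b$dim)
  expect_equal(is.infinite(a$death), is.infinite(b$death))
  fin <- is.finite(a$death)
  expect_lt(max(abs(a$birth - b$birth), 0), tol)
  if (any(fin)) expect_lt(max(abs(a$death[fin] - b$death[fin])), tol)
}
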