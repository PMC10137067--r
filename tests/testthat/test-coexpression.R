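make_blocks <- function(nPerBlock = 50, nNoise = 0, n = 100, rho = 0.8,
                        seed = 1) {
  set.seed(seed)
  f1 <- rnorm(n); f2 <- rnorm(n)
  mk <- function(f, k) t(vapply(seq_len(k), function(i)
    sqrt(rho) * f + sqrt(1 - rho) * rnorm(n), numeric(n)))
  X <- rbind(mk(f1, nPerBlock), mk(f2, nPerBlock))
  if (nNoise > 0) X <- rbind(X, matrix(rnorm(nNoise * n), nNoise, n))
  rownames(X) <- paste0("g", seq_len(nrow(X)))
  list(X = X, f1 = f1, f2 = f2)
}

test_that("signed adjacency and TOM match their closed forms", {
  x <- seq_len(10)
  up <- rbind(a = x, b = 2 * x + 3)        # cor = 1
  dn <- rbind(a = x, b = -x)               # cor = -1
  prm <- coexpressionParams(beta = 8)
  expect_equal(signedAdjacency(up, prm)["a", "b"], 1)
  expect_equal(signedAdjacency(dn, prm)["a", "b"], 0)
  set.seed(2)
  orth <- rbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))  # cor = 0
  expect_equal(signedAdjacency(orth, prm)["a", "b"], 0.5^8)

  A3 <- matrix(0.5, 3, 3); diag(A3) <- 1
  expect_equal(tomSimilarity(A3)[1, 2], (0.25 + 0.5) / (1 + 1 - 0.5))
  I4 <- diag(4)
  tomI <- tomSimilarity(I4)
  expect_true(all(tomI[upper.tri(tomI)] == 0))
  expect_equal(diag(tomI), rep(1, 4))

  # TOM stays in [0,1], symmetric, on random valid adjacencies
  for (s in 1:5) {
    set.seed(s)
    A <- matrix(runif(64), 8); A <- (A + t(A)) / 2; diag(A) <- 1
    tm <- tomSimilarity(A)
    expect_true(all(tm >= 0 & tm <= 1 + 1e-12))
    expect_equal(tm, t(tm))
  }
  expect_error(tomSimilarity(matrix(runif(9), 3)), "symmetric")
  expect_error(signedAdjacency(rbind(a = rep(1, 5), b = rnorm(5))),
               "zero-variance")
})

test_that("adjacency and TOM are invariant to sample order and affine
           gene rescaling", {
  bl <- make_blocks(nPerBlock = 10, n = 30, seed = 3)
  X <- bl$X
  A <- signedAdjacency(X)
  perm <- sample(ncol(X))
  expect_equal(signedAdjacency(X[, perm]), A, tolerance = 1e-12)
  X2 <- X
  X2[3, ] <- 5 * X2[3, ] - 7
  expect_equal(signedAdjacency(X2), A, tolerance = 1e-12)
  expect_equal(tomSimilarity(signedAdjacency(X2)), tomSimilarity(A),
               tolerance = 1e-12)
})

test_that("module detection recovers planted blocks and greys out noise", {
  ok <- vapply(1:3, function(s) {
    bl <- make_blocks(seed = s)
    mods <- detectModules(tomSimilarity(signedAdjacency(bl$X)))
    twoMods <- length(setdiff(unique(mods), "grey")) == 2
    pure1 <- length(unique(mods[1:50])) == 1
    pure2 <- length(unique(mods[51:100])) == 1
    noneGrey <- !"grey" %in% mods
    twoMods && pure1 && pure2 && noneGrey
  }, NA)
  expect_true(all(ok))

  noise <- vapply(1:5, function(s) {
    set.seed(100 + s)
    Xn <- matrix(rnorm(150 * 60), 150, 60,
                 dimnames = list(paste0("n", 1:150), NULL))
    mn <- suppressWarnings(detectModules(tomSimilarity(
      signedAdjacency(Xn))))
    all(mn == "grey")
  }, NA)
  expect_gte(mean(noise), 0.9)

  # a 10-gene block cannot reach the minimum module size
  bl <- make_blocks(nPerBlock = 10, nNoise = 40, n = 80, seed = 5)
  mods <- suppressWarnings(detectModules(tomSimilarity(
    signedAdjacency(bl$X)), coexpressionParams(minModuleSize = 30)))
  expect_true(all(mods[1:10] == "grey"))
})

test_that("eigengenes summarize modules with oriented unit variance", {
  x <- rnorm(40)
  X <- rbind(g1 = 2 * x + 1, g2 = -3 * x, g3 = 0.5 * x)
  mods <- setNames(rep("M1", 3), rownames(X))
  eg <- moduleEigengenes(X, mods)
  expect_equal(abs(cor(eg$eigengenes["M1", ], x)), 1)
  expect_equal(unname(eg$varExplained["M1"]), 1)
  expect_equal(sd(eg$eigengenes["M1", ]), 1)

  # sign orientation: negating all members negates the eigengene
  egNeg <- moduleEigengenes(-X, mods)
  expect_equal(egNeg$eigengenes["M1", ], -eg$eigengenes["M1", ],
               tolerance = 1e-12)

  # single-gene module falls back to the standardized gene
  eg1 <- moduleEigengenes(X[1, , drop = FALSE],
                          setNames("M1", "g1"))
  expect_equal(unname(eg1$eigengenes["M1", ]),
               as.numeric(scale(X[1, ])), tolerance = 1e-12)

  # factor-model variance explained near rho at large n
  bl <- make_blocks(nPerBlock = 40, n = 200, rho = 0.64, seed = 9)
  m2 <- setNames(rep(c("M1", "M2"), each = 40), rownames(bl$X))
  eg2 <- moduleEigengenes(bl$X, m2)
  expect_lt(max(abs(eg2$varExplained - 0.64)), 0.1)
})

test_that("module-trait correlation handles indicators and degeneracies", {
  bl <- make_blocks(nPerBlock = 20, n = 50, seed = 11)
  mods <- setNames(rep(c("M1", "M2"), each = 20), rownames(bl$X))
  eg <- moduleEigengenes(bl$X, mods)$eigengenes
  traits <- cbind(self = eg["M1", ],
                  ind1 = as.numeric(bl$f1 > 0),
                  ind2 = as.numeric(bl$f1 <= 0))
  mt <- moduleTraitCorrelation(eg, traits)
  self <- mt[mt$module == "M1" & mt$trait == "self", ]
  expect_equal(self$r, 1, tolerance = 1e-12)
  expect_lt(self$p, 1e-12)
  # complementary indicators: equal magnitude, opposite sign
  r1 <- mt$r[mt$module == "M1" & mt$trait == "ind1"]
  r2 <- mt$r[mt$module == "M1" & mt$trait == "ind2"]
  expect_equal(r1, -r2, tolerance = 1e-12)
  expect_error(moduleTraitCorrelation(eg, cbind(const = rep(1, 50))),
               "constant")
})
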