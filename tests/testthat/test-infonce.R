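test_that("cosine similarity behaves as a cosine", {
  expect_equal(cosine_sim(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_sim(c(1, 2, 3), -c(1, 2, 3)), -1)
  expect_equal(cosine_sim(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_sim(5 * c(1, 1), c(1, 1) / 3), 1)   # scale invariance
  expect_error(cosine_sim(c(0, 0), c(1, 1)), "zero")
})

test_that("the pair loss is zero for a single pair and log(2N-1) for identical embeddings", {
  set.seed(1)
  Z2 <- matrix(rnorm(6), 2, 3)
  expect_equal(infonce_pair_loss(1, 2, Z2, tau = 0.7), 0)
  expect_equal(infonce_batch_loss(Z2, tau = 0.7), 0)
  for (N in c(1, 2, 8, 64)) {
    Z <- matrix(rep(c(0.3, -1, 2), each = 2 * N), 2 * N, 3)
    expect_equal(infonce_batch_loss(Z, tau = 0.5), log(2 * N - 1),
                 tolerance = 1e-12)
    expect_equal(infonce_batch_loss(Z, tau = 3), log(2 * N - 1),
                 tolerance = 1e-12)
  }
})

test_that("the orthogonal two-pair batch reproduces the hand-derived value", {
  Z <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  expect_equal(infonce_pair_loss(1, 2, Z, tau = 1), log(1 + 2 / exp(1)),
               tolerance = 1e-12)
  # all four pair losses are equal by symmetry, so the batch loss matches
  expect_equal(infonce_batch_loss(Z, tau = 1), log(1 + 2 / exp(1)),
               tolerance = 1e-12)
})

test_that("the vectorized loss equals the naive double-loop oracle", {
  set.seed(11)
  for (N in c(2, 5, 16)) {
    for (tau in c(0.2, 0.5, 1)) {
      Z <- matrix(rnorm(2 * N * 8), 2 * N, 8)
      expect_equal(infonce_batch_loss(Z, tau), naive_batch_loss(Z, tau),
                   tolerance = 1e-6)
      expect_equal(infonce_pair_loss(1, 2, Z, tau), naive_pair_loss(1, 2, Z, tau),
                   tolerance = 1e-6)
    }
  }
})

test_that("the batch loss is invariant under permuting the recording pairs", {
  set.seed(12)
  N <- 6
  Z <- matrix(rnorm(2 * N * 4), 2 * N, 4)
  perm <- sample(N)
  rows <- as.vector(rbind(2 * perm - 1, 2 * perm))
  expect_equal(infonce_batch_loss(Z[rows, ], 0.5), infonce_batch_loss(Z, 0.5),
               tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  Z <- matrix(rnorm(8), 4, 2)
  expect_error(infonce_pair_loss(1, 5, Z, 0.5), "out of range")
  expect_error(infonce_pair_loss(2, 2, Z, 0.5), "i == j")
  expect_error(infonce_batch_loss(matrix(rnorm(9), 3, 3), 0.5), "odd")
  expect_error(infonce_batch_loss(rbind(c(0, 0), c(1, 1)), 0.5), "zero")
})

test_that("one gradient step pulls positive pairs together and pushes negatives apart", {
  # near-orthogonal pairs: positives not yet fully aligned
  Z <- rbind(c(1, 0.1), c(1, -0.1), c(0.1, 1), c(-0.1, 1))
  tau <- 1
  # numeric gradient of the batch loss wrt the raw embeddings
  g <- matrix(0, 4, 2)
  eps <- 1e-6
  for (i in 1:4) for (j in 1:2) {
    Zp <- Z; Zp[i, j] <- Zp[i, j] + eps
    Zm <- Z; Zm[i, j] <- Zm[i, j] - eps
    g[i, j] <- (infonce_batch_loss(Zp, tau) - infonce_batch_loss(Zm, tau)) / (2 * eps)
  }
  Z1 <- Z - 0.1 * g
  expect_gt(cosine_sim(Z1[1, ], Z1[2, ]), cosine_sim(Z[1, ], Z[2, ]))
  expect_gt(cosine_sim(Z1[3, ], Z1[4, ]), cosine_sim(Z[3, ], Z[4, ]))
  expect_lt(cosine_sim(Z1[1, ], Z1[3, ]), cosine_sim(Z[1, ], Z[3, ]))
  expect_lt(cosine_sim(Z1[2, ], Z1[4, ]), cosine_sim(Z[2, ], Z[4, ]))
})
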