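test_that("interpolate follows a + lam (b - a)", {
  expect_equal(interpolate(c(0, 0), c(2, 4), 0.5), c(1, 2))
  a <- c(3.2, -1, 7)
  expect_equal(interpolate(a, c(0, 0, 0), 0), a)
  expect_equal(interpolate(1, 5, 0.25), 2)
  expect_error(interpolate(c(1, 2), c(1, 2, 3), 0.5), "dimension mismatch")
  expect_error(interpolate(1, 2, 1.5), "\\[0, 1\\]")
})

test_that("random over-sampling copies uniformly chosen minority rows", {
  m <- rand_minority(10, 3, seed = 1)
  expect_equal(nrow(random_oversample(m, 0)$vectors), 0)

  one <- matrix(c(1, 2, 3), 1)
  b <- random_oversample(one, 5, seed = 2)
  expect_equal(b$vectors, matrix(rep(c(1, 2, 3), each = 5), 5))
  expect_true(all(b$lambdas == 0))
  expect_equal(b$parents[, 1], b$parents[, 2])

  # every replicate equals its source row; selection uniform within 4 sigma
  b2 <- random_oversample(m, 1000, seed = 7)
  expect_equal(b2$vectors, m[b2$parents[, 1], ], ignore_attr = TRUE)
  freq <- tabulate(b2$parents[, 1], nbins = 10)
  bound <- 4 * sqrt(1000 * 0.1 * 0.9)   # binomial sd at p = 1/10
  expect_true(all(abs(freq - 100) <= bound))

  expect_error(random_oversample(matrix(numeric(0), 0, 2), 1), "empty")
})

test_that("knn_minority matches the exhaustive oracle and tie rule", {
  m <- matrix(c(0, 1, 10), 3)
  expect_equal(knn_minority(m, 1, 1), 2L)

  tie <- matrix(c(0, -1, 1), 3)   # rows 2 and 3 equidistant from row 1
  expect_equal(knn_minority(tie, 1, 1), 2L)

  set.seed(42)
  for (rep in 1:100) {
    n <- sample(5:50, 1); d <- sample(1:8, 1)
    m <- matrix(rnorm(n * d), n, d)
    i <- sample.int(n, 1); k <- sample.int(n - 1, 1)
    expect_identical(knn_minority(m, i, k), oracle_knn(m, i, k))
  }

  expect_error(knn_minority(m, 1, nrow(m)), "k must satisfy")
})

test_that("SMOTE synthesises on segments toward true k-nearest neighbours", {
  same <- rbind(c(1, 2), c(1, 2))
  b <- smote(same, k = 1, n_synth = 7, seed = 1)
  expect_true(all(apply(b$vectors, 1, function(v) all(v == c(1, 2)))))

  seg <- matrix(c(0, 1), 2)
  b2 <- smote(seg, k = 1, n_synth = 200, seed = 2)
  expect_true(all(b2$vectors >= 0 & b2$vectors <= 1))

  m <- rand_minority(20, 3, seed = 3)
  b3 <- smote(m, k = 3, n_synth = 100, seed = 4)
  for (j in seq_len(100)) {
    i <- b3$parents[j, 1]; nb <- b3$parents[j, 2]
    expect_true(nb %in% oracle_knn(m, i, 3))
    expect_equal(b3$vectors[j, ], m[i, ] + b3$lambdas[j] * (m[nb, ] - m[i, ]))
  }
  # round-robin allocation: counts differ by at most 1, remainder to early rows
  cnt <- tabulate(b3$parents[, 1], nbins = 20)
  expect_true(max(cnt) - min(cnt) <= 1)
  expect_true(all(cnt == 5))
  b4 <- smote(m, k = 3, n_synth = 23, seed = 5)
  expect_equal(tabulate(b4$parents[, 1], nbins = 20), c(rep(2L, 3), rep(1L, 17)))

  expect_error(smote(matrix(1, 1, 1), k = 1, n_synth = 1), "at least 2")
})

test_that("ADASYN plan reproduces hand-enumerated neighbourhoods", {
  expect_equal(adasyn_plan(rand_minority(2, 2, 1), rand_minority(6, 2, 2),
                           beta = 1, k = 3)$total_g, 4L)

  # hand-built 2-D configuration, k = 3:
  # minority M1=(0,0), M2=(10,0); majority A=(0.1,0), B=(0.2,0), C=(20,20),
  # D=(10.1,0), E=(10.2,0), F=(10.3,0)
  # M1 neighbours: A, B, then M2 (dist 10 < 10.1) -> Delta_1 = 2
  # M2 neighbours: D, E, F -> Delta_2 = 3
  minority <- rbind(c(0, 0), c(10, 0))
  majority <- rbind(c(0.1, 0), c(0.2, 0), c(20, 20),
                    c(10.1, 0), c(10.2, 0), c(10.3, 0))
  plan <- adasyn_plan(minority, majority, beta = 1, k = 3)
  expect_equal(plan$delta, c(2, 3))
  expect_equal(plan$weights, c(2, 3) / 5)          # Delta_i/k over Z = 5/3
  expect_equal(plan$total_g, 4L)                   # round(1 * (6 - 2))
  expect_equal(sum(plan$counts), 4L)
  expect_equal(plan$counts, c(2L, 2L))             # largest remainder on (1.6, 2.4)

  # degenerate Z: all-minority neighbourhoods fall back to uniform weights
  tight <- rand_minority(5, 2, 6) * 0.01
  far <- rand_minority(10, 2, 7) + 100
  plan2 <- expect_silent(adasyn_plan(tight, far, beta = 1, k = 3))
  expect_equal(plan2$delta, rep(0, 5))
  expect_equal(plan2$weights, rep(0.2, 5))
  expect_true(max(plan2$counts) - min(plan2$counts) <= 1L)
  expect_equal(sum(plan2$counts), plan2$total_g)

  expect_warning(adasyn_plan(rand_minority(5, 2, 8), rand_minority(3, 2, 9), k = 2),
                 "nothing to balance")
})

test_that("ADASYN plan weights are a distribution, counts monotone in delta", {
  set.seed(11)
  for (rep in 1:20) {
    minority <- matrix(rnorm(12 * 3), 12, 3)
    majority <- matrix(rnorm(40 * 3, 1), 40, 3)
    plan <- adasyn_plan(minority, majority, beta = runif(1, 0.3, 1), k = 5)
    expect_true(all(plan$weights >= 0))
    expect_equal(sum(plan$weights), 1, tolerance = 1e-9)
    expect_equal(sum(plan$counts), plan$total_g)
    # counts monotone (up to the 1-unit remainder) in the majority density
    for (a in seq_along(plan$delta)) for (b in seq_along(plan$delta)) {
      if (plan$delta[a] > plan$delta[b]) expect_gte(plan$counts[a], plan$counts[b] - 1L)
    }
  }
})

test_that("ADASYN synthesis honours the plan's per-parent counts", {
  minority <- rbind(c(0, 0), c(10, 0))
  majority <- rbind(c(0.1, 0), c(0.2, 0), c(20, 20),
                    c(10.1, 0), c(10.2, 0), c(10.3, 0))
  plan <- adasyn_plan(minority, majority, beta = 1, k = 3)
  b <- adasyn(minority, majority, beta = 1, k = 3, seed = 5)
  expect_equal(nrow(b$vectors), plan$total_g)
  expect_equal(tabulate(b$parents[, 1], nbins = 2), plan$counts)
  expect_convex(b, minority)

  # G = 0 gives an empty batch
  suppressWarnings(b0 <- adasyn(rand_minority(5, 2, 1), rand_minority(3, 2, 2)))
  expect_equal(nrow(b0$vectors), 0)

  # batch size equals G on random inputs
  set.seed(12)
  for (rep in 1:5) {
    mi <- matrix(rnorm(8 * 2), 8, 2); ma <- matrix(rnorm(30 * 2, 2), 30, 2)
    plan <- adasyn_plan(mi, ma, beta = 1, k = 4)
    expect_equal(nrow(adasyn(mi, ma, beta = 1, k = 4, seed = rep)$vectors),
                 plan$total_g)
  }
})

test_that("samplers are deterministic given the seed", {
  m <- rand_minority(15, 4, seed = 20)
  ma <- rand_minority(50, 4, seed = 21) + 1
  expect_identical(random_oversample(m, 30, seed = 9), random_oversample(m, 30, seed = 9))
  expect_identical(smote(m, 4, 30, seed = 9), smote(m, 4, 30, seed = 9))
  expect_identical(adasyn(m, ma, 1, 5, seed = 9), adasyn(m, ma, 1, 5, seed = 9))
  expect_false(identical(smote(m, 4, 30, seed = 9), smote(m, 4, 30, seed = 10)))
})

test_that("sampler calls do not disturb the caller's RNG stream", {
  m0 <- rand_minority(6, 2, 1)
  set.seed(99)
  before <- runif(3)
  set.seed(99)
  invisible(runif(1))
  invisible(smote(m0, 2, 10, seed = 5))
  after <- runif(2)
  expect_equal(c(before[1], after), before)
})
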