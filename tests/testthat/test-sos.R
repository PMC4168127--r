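# Replays the documented RNG stream of the SOS loop: per proposal, an index
# pair (sample.int(np, 2)) then a lambda (runif(1)).
replay_sos_stream <- function(np, n_attempts, seed) {
  out <- vector("list", n_attempts)
  set.seed(as.integer(seed))
  for (t in seq_len(n_attempts)) {
    pr <- sample.int(np, 2L)
    out[[t]] <- list(a = pr[1], b = pr[2], lam = runif(1))
  }
  out
}

make_sos_dataset <- function() {
  # minority at first coordinates 0 and 1; majority far away
  feats <- rbind(c(0, 5), c(1, 5), matrix(rep(c(8, 8), 6), 6, byrow = TRUE))
  labeled_dataset(feats, c(1, 1, rep(-1, 6)))
}

test_that("alpha = 1 synthesises nothing and returns the input unchanged", {
  ds <- gen_imbalanced(10, 40, d = 3, separation = 2, seed = 1)
  out <- sos(ds, mock_spec(function(x) 0.7), sos_config(alpha = 1, seed = 1))
  expect_equal(out$augmented, ds)
  expect_equal(nrow(out$batch$vectors), 0)
})

test_that("an always-in-interval mock accepts every proposal", {
  ds <- gen_imbalanced(12, 50, d = 4, separation = 2, seed = 2)
  out <- sos(ds, mock_spec(function(x) 0.7),
             sos_config(alpha = 2, c_low = 0.5, c_high = 0.95, seed = 3))
  expect_equal(sum(out$augmented$labels == 1), 24)
  expect_true(all(out$batch$confidences == 0.7))
  # majority rows bit-identical
  expect_identical(out$augmented$features[which(ds$labels == -1), , drop = FALSE],
                   ds$features[which(ds$labels == -1), , drop = FALSE])
  # accepted proposals are exactly the replayed stream (acceptance rate 1)
  stream <- replay_sos_stream(12, 12, seed = 3)
  expect_equal(out$batch$lambdas, vapply(stream, `[[`, numeric(1), "lam"))
  expect_equal(out$batch$parents[, 1], vapply(stream, `[[`, integer(1), "a"))
})

test_that("confidence filtering keeps only in-interval proposals (closed form)", {
  ds <- make_sos_dataset()
  # conf = first coordinate = lambda when a = row1, 1 - lambda when a = row2
  spec <- mock_spec(function(x) x[1])
  cfg <- sos_config(alpha = 11, c_low = 0.4, c_high = 0.6, seed = 17)
  out <- sos(ds, spec, cfg)    # n_target = ceil(10 * 2 / 2) = 20
  expect_equal(nrow(out$batch$vectors), 20)
  expect_true(all(out$batch$confidences >= 0.4 & out$batch$confidences <= 0.6))
  expect_true(all(out$batch$vectors[, 1] >= 0.4 & out$batch$vectors[, 1] <= 0.6))

  # replay: simulate the acceptance loop from the seed and compare exactly
  stream <- replay_sos_stream(2, 10000, seed = 17)
  acc <- Filter(function(p) {
    conf <- if (p$a == 1) p$lam else 1 - p$lam
    conf >= 0.4 && conf <= 0.6
  }, stream)[1:20]
  expect_equal(out$batch$lambdas, vapply(acc, `[[`, numeric(1), "lam"))
  expect_equal(out$batch$parents[, 1], vapply(acc, `[[`, integer(1), "a"))
  expect_equal(out$batch$parents[, 2], vapply(acc, `[[`, integer(1), "b"))
})

test_that("the interval [0,1] degenerates to unfiltered pair interpolation", {
  ds <- gen_imbalanced(8, 30, d = 3, separation = 1, seed = 5)
  out <- sos(ds, mock_spec(function(x) runif_like <- abs(sin(sum(x)))),
             sos_config(alpha = 3, c_low = 0, c_high = 1, seed = 6))
  n_target <- ceiling((3 - 1) * 8)
  expect_equal(nrow(out$batch$vectors), n_target)
  stream <- replay_sos_stream(8, n_target, seed = 6)
  expect_equal(out$batch$lambdas, vapply(stream, `[[`, numeric(1), "lam"))
  # pair indices are always distinct
  expect_true(all(out$batch$parents[, 1] != out$batch$parents[, 2]))
})

test_that("an unreachable interval raises the attempt-cap error", {
  ds <- gen_imbalanced(6, 20, d = 2, separation = 1, seed = 7)
  cfg <- sos_config(alpha = 2, c_low = 0.8, c_high = 0.9, max_attempts = 50, seed = 8)
  err <- expect_error(sos(ds, mock_spec(function(x) 0.2), cfg),
                      class = "sosampler_attempt_cap")
  expect_match(conditionMessage(err), "rate")
  expect_match(conditionMessage(err), "\\[0.8, 0.9\\]")
})

test_that("SOS validates degenerate inputs", {
  tiny <- labeled_dataset(matrix(rnorm(6), 3), c(1, -1, -1))
  expect_error(sos(tiny, mock_spec(function(x) 0.7), sos_config(alpha = 2)),
               "at least 2 minority")
  expect_error(sos_config(alpha = 0.5), "alpha")
  expect_error(sos_config(c_low = 0.9, c_high = 0.5), "confidence interval")
})

test_that("default alpha targets full class balance", {
  ds <- gen_imbalanced(10, 45, d = 3, separation = 2, seed = 9)
  out <- sos(ds, mock_spec(function(x) 0.7), sos_config(seed = 10))
  expect_equal(sum(out$augmented$labels == 1), 45)  # alpha = 45/10 -> 35 synthetic
  expect_identical(out$augmented$features[which(ds$labels == -1), , drop = FALSE],
                   ds$features[which(ds$labels == -1), , drop = FALSE])
})

test_that("sos is reproducible and a trained model filters soundly", {
  ds <- gen_imbalanced(15, 60, d = 3, separation = 3, seed = 11)
  spec <- classifier_spec("gaussian", c_grid = 4, gamma_grid = 0.3, seed = 1)
  cfg <- sos_config(alpha = 2, c_low = 0.3, c_high = 0.95, seed = 12)
  out1 <- sos(ds, spec, cfg)
  out2 <- sos(ds, spec, cfg)
  expect_equal(out1$batch, out2$batch)
  # recomputed confidences of accepted samples always lie in the interval
  re <- confidence(out1$model, out1$batch$vectors)
  expect_true(all(re >= 0.3 & re <= 0.95))
  expect_equal(re, out1$batch$confidences)
})
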