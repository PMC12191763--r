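test_that("sequence recovery is the fraction of matching tokens", {
  expect_equal(sequence_recovery(1:10, 1:10), 1)
  x <- 1:10; y <- x; y[4] <- 99L
  expect_equal(sequence_recovery(y, x), 0.9)
  expect_equal(sequence_recovery(rep(1L, 5), rep(2L, 5)), 0)
  expect_error(sequence_recovery(1:3, 1:4), class = "cheap_bad_shape")
})

test_that("RMSD vanishes under rigid motions and matches raw deviations", {
  st <- gen_toy_structures(n = 1, length = 20, seed = 3, rigid_copies = 1)
  expect_equal(rmsd(st[[1]], st[[1]]), 0)
  expect_lt(rmsd(st[[2]], st[[1]], superimpose = TRUE), 1e-6)
  # raw deviation without superposition: both atoms displaced by 2
  a <- rbind(c(0, 0, 0), c(1, 0, 0))
  b <- sweep(a, 2, c(2, 0, 0), "+")
  expect_equal(rmsd(a, b, superimpose = FALSE), 2)
  expect_error(rmsd(a, b, superimpose = TRUE), class = "cheap_bad_input")
})

test_that("Kabsch equals brute-force rotation search and the bio3d oracle", {
  withr::with_seed(10, {
    for (rep in 1:4) {
      n <- sample(3:5, 1)
      a <- matrix(rnorm(n * 3), n, 3)
      b <- matrix(rnorm(n * 3), n, 3)
      ours <- rmsd(a, b, superimpose = TRUE)
      brute <- brute_force_min_rmsd(a, b, seed = rep)
      expect_equal(ours, brute, tolerance = 1e-4)
      fitted <- suppressWarnings(  # bio3d notes the default all-atom fit
        bio3d::fit.xyz(fixed = as.vector(t(b)), mobile = as.vector(t(a))))
      oracle <- sqrt(mean(rowSums(
        (matrix(fitted, ncol = 3, byrow = TRUE) - b)^2)))
      expect_equal(ours, oracle, tolerance = 1e-6)
    }
  })
})

test_that("superposed RMSD never exceeds the unsuperposed value and is symmetric", {
  withr::with_seed(20, {
    for (rep in 1:5) {
      a <- matrix(rnorm(24), 8, 3)
      b <- a + matrix(rnorm(24, sd = 0.5), 8, 3)
      expect_lte(rmsd(a, b, superimpose = TRUE),
                 rmsd(a, b, superimpose = FALSE) + 1e-12)
      expect_equal(rmsd(a, b), rmsd(b, a), tolerance = 1e-9)
    }
  })
})

test_that("RMSPD is superposition-free, chirality-blind, and has closed forms", {
  st <- gen_toy_structures(n = 1, length = 15, seed = 5, rigid_copies = 1)
  expect_equal(rmspd(st[[1]], st[[2]]), 0, tolerance = 1e-10)
  mirrored <- st[[1]] %*% diag(c(-1, 1, 1))
  expect_equal(rmspd(st[[1]], mirrored), 0, tolerance = 1e-10)
  # uniform doubling: deviations equal the original distances
  tri <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0))
  expect_equal(rmspd(tri, 2 * tri), sqrt(mean(as.vector(dist(tri))^2)))
  # displacing one atom without superposition registers in RMSPD
  moved <- st[[1]]; moved[7, ] <- moved[7, ] + c(1, 0, 0)
  expect_gt(rmspd(st[[1]], moved), 0)
})

test_that("TM-score is 1 for self, uses the standard d0, and decays with noise", {
  helix <- gen_toy_structures(n = 1, length = 30, seed = 7)[[1]]
  expect_equal(tm_score(helix, helix), 1)
  expect_equal(tm_d0(30), 1.24 * 15^(1 / 3) - 1.8, tolerance = 1e-12)
  expect_equal(tm_d0(30), 1.2577, tolerance = 1e-3)
  expect_equal(tm_d0(10), 0.5)  # clamped for short chains
  withr::with_seed(9, {
    scores <- vapply(c(0.5, 2, 6), function(s) {
      tm_score(helix + matrix(rnorm(90, sd = s), 30, 3), helix)
    }, numeric(1))
  })
  expect_true(all(diff(scores) < 0))
  expect_true(all(scores > 0 & scores <= 1))
})

test_that("reconstruction reports tabulate per-sample and aggregate errors", {
  fx <- fixture_trained_model()
  rep <- reconstruction_report(fx$model, fx$data)
  expect_equal(nrow(rep), length(fx$data$embeddings))
  # aggregate equals the mask-weighted mean recomputed independently
  nv <- vapply(fx$data$masks, sum, numeric(1)) *
    vapply(fx$data$embeddings, ncol, integer(1))
  expect_equal(attr(rep, "aggregate")$masked_mse,
               sum(rep$masked_mse * nv) / sum(nv), tolerance = 1e-12)
  # per-sample MSEs agree with direct evaluation
  expect_equal(rep$masked_mse, eval_masked_mse(fx$model, fx$data),
               tolerance = 1e-12)
  expect_equal(rep$compression,
               compression_ratio(fx$model$cfg, rep$length))
})
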