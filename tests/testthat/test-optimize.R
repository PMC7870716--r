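test_that("weight vectors enforce sign and box constraints", {
  w <- cx_weights(1, 2, 3, -4, -5)
  expect_s3_class(w, "cx_weights")
  expect_error(cx_weights(-1, 1, 1, -1, -1), "excitatory")
  expect_error(cx_weights(1, 1, 101, -1, -1), "excitatory")
  expect_error(cx_weights(1, 1, 1, 1, -1), "inhibitory")
  expect_error(cx_weights(1, 1, 1, -101, -1), "inhibitory")
})

test_that("lesion zeroes one synapse class and is idempotent", {
  w <- cx_weights(1, 1, 1, -1, -1)
  l <- lesion(w, "P-EG->E-PG")
  expect_equal(unclass(l)[["w3"]], 0)
  expect_equal(unclass(l)[c("w1", "w2", "w4", "w5")],
               unclass(w)[c("w1", "w2", "w4", "w5")])
  expect_equal(lesion(l, "w3"), l)
  expect_error(lesion(w, "nonsense"), "unknown synapse class")
})

test_that("objective scores the two-checkpoint protocol per the weighted error sum", {
  cir <- fly_circuit()
  # zero weights: circuit cannot hold a bump; the small-weight penalty
  # dominates with p0 = 1 contributing N * p0 = 5
  ob0 <- ring_objective(rep(0, 5), cir, seed = 2)
  expect_equal(ob0$p0, 1)
  expect_gte(ob0$score, 5)
  # functional weights: bump near targets, score mostly the width terms
  obw <- ring_objective(working_weights(), cir, seed = 2)
  expect_lt(obw$score, 1)
  expect_lt(abs(((obw$h_a[1] - 0 + 180) %% 360) - 180), 25)
  expect_lt(abs(((obw$h_a[2] - 180 + 180) %% 360) - 180), 25)
  # the score recombines exactly from its reported components
  expect_equal(obw$score,
               4 * (obw$eps_h1 + obw$eps_h2) + obw$eps_w1 + obw$eps_w2 +
                 5 * obw$p0, tolerance = 1e-12)
  # a 90 deg heading miss contributes 4 * 90/360 = 1 to the score
  expect_equal(4 * (90 / 360), 1)
})

test_that("fit_weights respects budget, bounds and reproducibility", {
  cir <- fly_circuit()
  # budget 1 returns the evaluation of the prescribed initialization
  f1 <- fit_weights("pso", budget = 1, seed = 3, particles = 1, circuit = cir)
  expect_equal(unname(unclass(f1$weights)),
               c(0.01, 0.01, 0.01, -0.01, -0.01))
  expect_equal(f1$n_eval, 1L)
  # short searches stay feasible and never worsen the initialization
  f2 <- fit_weights("sann", budget = 25, seed = 3, circuit = cir)
  w2 <- unclass(f2$weights)
  expect_true(all(w2[1:3] >= 0 & w2[1:3] <= 100))
  expect_true(all(w2[4:5] <= 0 & w2[4:5] >= -100))
  expect_lte(f2$score, f2$trace[1])
  expect_true(all(diff(f2$trace) <= 1e-12)) # best-so-far is monotone
  f2b <- fit_weights("sann", budget = 25, seed = 3, circuit = cir)
  expect_identical(unclass(f2$weights), unclass(f2b$weights))
})

test_that("weights serialize with provenance", {
  fit <- list(weights = cx_weights(1, 2, 3, -4, -5), method = "pso",
              seed = 9L, n_eval = 10L, score = 0.5)
  class(fit) <- "cx_fit"
  f <- tempfile(fileext = ".json")
  write_weights_json(fit, f)
  back <- read_weights_json(f)
  expect_equal(unclass(back)[1:5], unclass(fit$weights)[1:5],
               ignore_attr = TRUE)
  expect_equal(attr(back, "provenance")$method, "pso")
  expect_equal(attr(back, "provenance")$seed, 9L)
})
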