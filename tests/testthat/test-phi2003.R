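# closed-form covariance for the 2-node single-edge system 1 -> 2 with
# weight w under the fixed-point (reference) solution, derived by hand:
# Q = [[1, w], [0, 1]], COV = t(Q) diag(d1^2, d2^2) Q
cov2_closed <- function(w, d1, d2) {
  rbind(c(d1^2, d1^2 * w),
        c(w * d1^2, w^2 * d1^2 + d2^2))
}

test_that("reference stationary covariance matches its closed forms", {
  expect_equal(stationary_covariance(matrix(0, 3, 3), noise = c(1, 2, 3)),
               diag(c(1, 4, 9)))
  for (w in c(0.1, 0.3, 0.45)) {
    con <- rbind(c(0, w), c(0, 0))
    expect_equal(stationary_covariance(con, noise = c(1, 1)),
                 cov2_closed(w, 1, 1))
    expect_equal(stationary_covariance(con, noise = c(1, 1e-5)),
                 cov2_closed(w, 1, 1e-5))
  }
})

test_that("reference covariance equals the settling-dynamics simulation", {
  # the fixed-point reading: noise drawn once per replicate, activity
  # iterated to convergence, covariance taken across replicates
  withr::with_seed(51, {
    con <- normalize_columns(random_adj(4, 0.5), 0.4)
    reps <- 20000
    noise <- matrix(stats::rnorm(reps * 4), reps, 4)
    xs <- matrix(0, reps, 4)
    for (it in 1:200) xs <- xs %*% con + noise
    emp <- crossprod(xs) / reps
    ana <- stationary_covariance(con, noise = 1)
    expect_lt(max(abs(emp - ana)), 6 * max(diag(ana)) / sqrt(reps) * 3)
  })
})

test_that("corrected covariance solves the time-stepped recursion", {
  # scalar AR(1) x_t = a x_{t-1} + e: variance 1/(1-a^2)
  a <- matrix(0.6, 1, 1)
  expect_equal(stationary_covariance(a, 1, mode = "corrected"),
               matrix(1 / (1 - 0.36), 1, 1))
  withr::with_seed(52, {
    con <- normalize_columns(random_adj(3, 0.6), 0.5)
    s <- stationary_covariance(con, 1, mode = "corrected")
    # Lyapunov identity under row-vector dynamics
    expect_equal(t(con) %*% s %*% con + diag(3), s)
    # long-run simulation of the recursion
    steps <- 150000
    x <- numeric(3)
    out <- matrix(0, steps, 3)
    e <- matrix(stats::rnorm((steps + 200) * 3), ncol = 3)
    for (t in 1:(steps + 200)) {
      x <- as.vector(x %*% con) + e[t, ]
      if (t > 200) out[t - 200, ] <- x
    }
    expect_lt(max(abs(crossprod(out) / steps - s)), 0.1)
  })
})

test_that("covariance guards report non-stationarity and singularity", {
  expect_error(stationary_covariance(diag(2) * 0 + 1.2 - diag(2) * 1.2,
                                     1), "spectral radius")
  expect_error(gaussian_entropy(rbind(c(1, 2), c(2, 1))), "eigenvalue")
})

test_that("Gaussian entropy follows its closed forms", {
  expect_equal(gaussian_entropy(matrix(1)), 0.5 * log(2 * pi * exp(1)))
  expect_equal(gaussian_entropy(diag(4)), 4 * 0.5 * log(2 * pi * exp(1)))
  s2 <- 6.25
  expect_equal(gaussian_entropy(matrix(s2)),
               0.5 * log(2 * pi * exp(1)) + 0.5 * log(s2))
})

test_that("mutual information matches the bivariate closed form", {
  expect_equal(gaussian_mutual_information(diag(c(1, 2, 3)), 1, 2:3), 0)
  for (rho in c(-0.7, 0.2, 0.9)) {
    cv <- rbind(c(1, rho), c(rho, 1))
    expect_equal(gaussian_mutual_information(cv, 1, 2),
                 -0.5 * log(1 - rho^2))
    expect_equal(gaussian_mutual_information(cv, 2, 1),
                 gaussian_mutual_information(cv, 1, 2))
  }
  expect_error(gaussian_mutual_information(diag(3), c(1, 2), c(2, 3)),
               "disjoint")
})

test_that("effective information matches the n = 2 symbolic closed form", {
  cp <- 1; ci <- 1e-5
  for (w in seq(0.1, 0.45, by = 0.05)) {
    con <- rbind(c(0, w), c(0, 0))
    # MI from cov2_closed: var2 = w^2 d1^2 + d2^2, det = d1^2 d2^2
    ei12 <- 0.5 * log((w^2 * cp^2 + ci^2) / ci^2)
    ei21 <- 0.5 * log((w^2 * ci^2 + cp^2) / cp^2)
    expect_equal(effective_information(con, 1, 2, cp, ci), ei12)
    expect_equal(effective_information(con, 2, 1, cp, ci), ei21)
    # information flows with the edge, not against it
    expect_gt(ei12, 1000 * ei21)
  }
})

test_that("effective information vanishes across a decoupling", {
  con <- matrix(0, 4, 4)
  con[1, 2] <- 0.4
  con[3, 4] <- 0.4   # two independent pairs
  expect_lt(abs(effective_information(con, c(1, 2), c(3, 4))), 1e-9)
  expect_lt(abs(effective_information(con, c(3, 4), c(1, 2))), 1e-9)
})

test_that("the MIB search matches an exhaustive independent scan", {
  withr::with_seed(53, {
    for (i in 1:5) {
      con <- normalize_columns(random_adj(4, 0.5), 0.5)
      r <- minimum_information_bipartition(con)
      # independent scan over all 7 unordered cuts via the public EI op
      hmax1 <- 0.5 * log(2 * pi * exp(1))
      cuts <- list(1, 2, 3, 4, c(1, 2), c(1, 3), c(1, 4))
      scores <- vapply(cuts, function(a) {
        b <- setdiff(1:4, a)
        ei <- effective_information(con, a, b) +
              effective_information(con, b, a)
        ei / (min(length(a), length(b)) * hmax1)
      }, numeric(1))
      expect_equal(r$ei_normalized, min(scores), tolerance = 1e-6)
      best <- cuts[[which.min(scores)]]
      expect_true(setequal(r$part_a, best) || setequal(r$part_b, best))
    }
  })
})

test_that("compiled and pure-R bipartition searches are identical", {
  withr::with_seed(54, {
    for (i in 1:4) {
      con <- normalize_columns(random_adj(5, 0.5), 0.5)
      for (mode in c("reference", "corrected")) {
        a <- minimum_information_bipartition(con, 1:5, mode = mode,
                                             use_cpp = TRUE)
        b <- minimum_information_bipartition(con, 1:5, mode = mode,
                                             use_cpp = FALSE)
        expect_equal(a$ei, b$ei, tolerance = 1e-6)
        expect_equal(a$ei_normalized, b$ei_normalized, tolerance = 1e-6)
        expect_identical(a$part_a, b$part_a)
      }
    }
  })
})

test_that("subset search finds decoupled modules and respects its cap", {
  con <- matrix(0, 4, 4)
  con[1, 2] <- 0.4; con[2, 1] <- 0.4   # module A
  con[3, 4] <- 0.4; con[4, 3] <- 0.4   # identical decoupled module B
  r <- phi_2003(con)
  expect_true(setequal(r$subset, c(1, 2)) || setequal(r$subset, c(3, 4)))
  whole <- minimum_information_bipartition(con, 1:4)
  expect_lt(abs(whole$phi), 1e-8)   # the whole decouples, Phi ~ 0
  expect_gt(r$phi, 1)
  expect_error(phi_2003(normalize_columns(complete_adj(13), 0.4)),
               "refused.*max_n")
})

test_that("subset scan equals per-subset calls and is relabel-invariant", {
  withr::with_seed(55, {
    con <- normalize_columns(random_adj(3, 0.7), 0.5)
    r <- phi_2003(con)
    manual <- c(
      minimum_information_bipartition(con, c(1, 2))$phi,
      minimum_information_bipartition(con, c(1, 3))$phi,
      minimum_information_bipartition(con, c(2, 3))$phi,
      minimum_information_bipartition(con, 1:3)$phi)
    expect_equal(r$phi, max(manual))
    perm <- c(3, 1, 2)
    expect_equal(phi_2003(con[perm, perm])$phi, r$phi, tolerance = 1e-6)
  })
})

test_that("sampled systems never yield negative Phi", {
  withr::with_seed(56, {
    pop <- sample_population(6, 8, scheme = "fixed_column", seed = 560)
    phis <- vapply(pop, function(g) phi_2003(g)$phi, numeric(1))
    expect_true(all(phis >= -1e-9))
    # determinism across repeated evaluation
    expect_equal(phi_2003(pop[[1]])$phi, phis[1], tolerance = 1e-6)
  })
})
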