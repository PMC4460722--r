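test_that("context windows span N/2 upstream through N/2-1 downstream", {
  seq100 <- strrep("ACGT", 25)
  win <- extract_context(seq100, 25, 40)
  expect_equal(nchar(win$bases), 40)
  expect_equal(win$focal_offset, 20)
  expect_equal(win$bases, substr(seq100, 6, 45)) # 0-based 5..44

  win4 <- extract_context("ACGTAC", 2, 4)
  expect_equal(win4$bases, "ACGT")
  expect_equal(win4$focal_offset, 2)

  expect_error(extract_context(seq100, 10, 40),
               class = "stackbias_context_unavailable")
  expect_error(extract_context(seq100, 81, 40),
               class = "stackbias_context_unavailable")
  expect_error(extract_context("ACGNACGT", 4, 4),
               class = "stackbias_window_rejected")
})

test_that("free energy is the weighted dinucleotide sum", {
  # zero energies
  p0 <- toy_params(4, eps = energy_table())
  expect_equal(free_energy("ACGT", p0), 0)
  # all eps = 1, w uniform: E = 1 for any window
  p1 <- toy_params(6, eps = stats::setNames(rep(1, 16), DINUCLEOTIDES))
  expect_equal(free_energy("ACGTAC", p1), 1)
  # hand-computed case
  ph <- stacking_params(energy_table(AC = 2, CG = 1, GT = 4),
                        c(0.1, 0.2, 0.3), window_size = 4)
  expect_equal(free_energy("ACGT", ph), 0.1 * 2 + 0.2 * 1 + 0.3 * 4)
  expect_error(free_energy("ACG", ph), class = "stackbias_bad_argument")
})

test_that("free energy matches the loop oracle on random fixtures", {
  withr::with_seed(42, {
    for (i in 1:100) {
      p <- random_params(6)
      s <- random_sequence(6)
      expect_equal(free_energy(s, p), free_energy_loop(s, p),
                   tolerance = 1e-12)
    }
  })
})

test_that("binding affinity is the logistic complement", {
  expect_equal(binding_affinity(0), 0.5)
  expect_equal(binding_affinity(1), 1 / (1 + exp(1)))
  expect_lt(binding_affinity(800), 1e-300)  # underflows smoothly, no error
  expect_equal(binding_affinity(-800), 1)
  e <- seq(-5, 5, by = 0.25)
  expect_true(all(diff(binding_affinity(e)) < 0))
  # nonnegative energies imply affinity <= 0.5
  withr::with_seed(7, {
    for (i in 1:20) {
      p <- random_params(6)
      expect_lte(binding_affinity(free_energy(random_sequence(6), p)), 0.5)
    }
  })
})

test_that("poisson rate is exp(v) * exp(alpha) * affinity", {
  expect_equal(poisson_rate(0, 0, 0.5), 0.5)
  expect_equal(poisson_rate(log(10), 0, 0.5), 5)
  withr::with_seed(1, {
    v <- rnorm(50); a <- rnorm(50); af <- runif(50, 0.01, 0.99)
    expect_equal(poisson_rate(v, a, af), exp(v) * exp(a) * af,
                 tolerance = 1e-12)
  })
  expect_error(poisson_rate(0, 0, 0), class = "stackbias_bad_argument")
})

test_that("affinity profile covers exactly the full-context positions", {
  p <- gc_bias_params(40)
  seq100 <- withr::with_seed(5, random_sequence(100))
  prof <- affinity_profile(seq100, p)
  expect_equal(nrow(prof), 61)
  expect_equal(range(prof$position), c(20, 80))
  expect_true(all(prof$affinity > 0 & prof$affinity < 1))
  # uniform energies give a constant profile
  pu <- toy_params(40)
  profu <- affinity_profile(seq100, pu)
  expect_equal(length(unique(profu$affinity)), 1L)
  # too-short sequence yields an empty profile with a warning
  expect_warning(empty <- affinity_profile("ACGT", p), "shorter")
  expect_equal(nrow(empty), 0L)
})

test_that("affinity profile equals position-wise oracle application", {
  withr::with_seed(33, {
    p <- random_params(10)
    s <- random_sequence(200)
    prof <- affinity_profile(s, p)
    manual <- vapply(prof$position, function(pos)
      binding_affinity(free_energy(extract_context(s, pos, 10), p)),
      numeric(1))
    expect_equal(prof$affinity, manual, tolerance = 1e-12)
  })
})

test_that("scaling eps by c and w by 1/c leaves affinities unchanged", {
  withr::with_seed(9, {
    p <- random_params(8)
    s <- random_sequence(120)
    for (cc in c(0.2, 3, 17)) {
      p2 <- stacking_params(p$stacking_energy * cc,
                            p$positional_weights / cc,
                            alpha = p$alpha, window_size = 8)
      expect_equal(affinity_profile(s, p2)$affinity,
                   affinity_profile(s, p)$affinity, tolerance = 1e-12)
    }
  })
})

test_that("parameter count is (N-1) + 16 + 1", {
  expect_identical(parameter_count(40), 56L)
  expect_identical(parameter_count(20), 36L)
  expect_identical(parameter_count(4), 20L)
  expect_error(parameter_count(5), class = "stackbias_bad_argument")
  expect_error(parameter_count(2), class = "stackbias_bad_argument")
})

test_that("parameter sets validate their invariants", {
  expect_error(stacking_params(rep(1, 16), rep(1, 39)),
               class = "stackbias_corrupt_parameters")  # unnamed
  bad <- uniform_stacking_energy(40); bad[1] <- -1
  expect_error(stacking_params(bad, rep(1, 39)),
               class = "stackbias_corrupt_parameters")
  expect_error(stacking_params(uniform_stacking_energy(40), rep(1, 10),
                               window_size = 40),
               class = "stackbias_corrupt_parameters")
  p <- null_params(40)
  expect_equal(sum(p$positional_weights), 1)
  expect_named(p$stacking_energy, DINUCLEOTIDES)
})

test_that("parameter JSON round-trips losslessly", {
  withr::with_seed(13, p <- random_params(12))
  path <- withr::local_tempfile(fileext = ".json")
  write_params_json(p, path)
  p2 <- read_params_json(path)
  expect_equal(p2$stacking_energy, p$stacking_energy, tolerance = 1e-15)
  expect_equal(p2$positional_weights, p$positional_weights,
               tolerance = 1e-15)
  expect_equal(p2$alpha, p$alpha, tolerance = 1e-15)
  expect_identical(p2$window_size, p$window_size)
})
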