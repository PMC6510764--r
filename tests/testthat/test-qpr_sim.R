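test_that("register initialization gives the uniform superposition", {
  st <- init_registers(1, 1)
  expect_equal(st$amplitudes, rep(complex(real = 0.5), 4))
  st2 <- init_registers(2, 2)
  expect_equal(st2$amplitudes, rep(complex(real = 0.25), 16))
  expect_equal(sum(Mod(st2$amplitudes)^2), 1, tolerance = 1e-12)
  expect_error(init_registers(0, 3), ">= 1")
  expect_error(init_registers(20, 20), "cap")
})

test_that("black box entangles the flag with the window contents", {
  all1 <- qpr_window(matrix(1L, 2, 2))
  st <- apply_black_box(init_registers(1, 1), all1)
  expect_equal(Mod(st$amplitudes[1:4]), rep(0, 4))        # flag-0 branch empty
  expect_equal(Mod(st$amplitudes[5:8]), rep(0.5, 4))

  all0 <- qpr_window(matrix(0L, 2, 2))
  st0 <- apply_black_box(init_registers(1, 1), all0)
  expect_equal(Mod(st0$amplitudes[1:4]), rep(0.5, 4))
  expect_equal(Mod(st0$amplitudes[5:8]), rep(0, 4))

  # single dot at (x=1, y=0): exactly branch z=1 carries flag 1, amp 1/2
  w <- qpr_window(matrix(c(0L, 1L, 0L, 0L), nrow = 2, byrow = TRUE))
  s1 <- apply_black_box(init_registers(1, 1), w)
  expect_equal(s1$amplitudes[4 + 2], complex(real = 0.5))
  expect_equal(sum(Mod(s1$amplitudes[5:8])^2), 1 / 4)

  expect_error(apply_black_box(init_registers(2, 2), w), "do not match")
})

test_that("flag measurement collapses with the Born rule normalization", {
  # 16-cell window with 4 dots: P(1) = 1/4, post-state amplitudes 1/sqrt(rho*S)
  cells <- matrix(0L, 4, 4); cells[cbind(c(1, 2, 3, 4), c(2, 1, 4, 3))] <- 1L
  w <- qpr_window(cells)
  st <- apply_black_box(init_registers(2, 2), w)
  withr::with_seed(5, {
    res <- measure_flag(st)
    while (res$bit != 1L) res <- measure_flag(st)
  })
  amp <- res$state$amplitudes
  expect_equal(sort(which(Mod(amp) > 1e-12)) - 1L, sort(qpralign:::window_z(w)))
  expect_equal(Mod(amp[Mod(amp) > 1e-12]), rep(1 / sqrt(0.25 * 16), 4))
  expect_equal(res$state$phase, "collapsed")

  withr::with_seed(11, {
    bits <- replicate(2000, measure_flag(st)$bit)
  })
  expect_lt(abs(mean(bits) - 0.25), 3 * sqrt(0.25 * 0.75 / 2000))

  expect_error(measure_flag(res$state), "entangled")
  all0 <- apply_black_box(init_registers(2, 2), qpr_window(matrix(0L, 4, 4)))
  expect_error(measure_flag(all0), "no reflective cells")
})

test_that("QFT matches the direct discrete Fourier oracle", {
  # uniform superposition over all S indices -> point mass at k = 0
  w_all <- qpr_window(matrix(1L, 4, 4))
  st <- apply_qft(qpralign:::collapse_to_reflective(w_all))
  p <- Mod(st$amplitudes)^2
  expect_equal(p[1], 1, tolerance = 1e-12)
  expect_equal(sum(p[-1]), 0, tolerance = 1e-12)

  # point mass at z = 0 -> uniform 1/S
  w1 <- qpr_window(matrix(c(1L, rep(0L, 15)), 4, 4, byrow = TRUE))
  p1 <- Mod(apply_qft(qpralign:::collapse_to_reflective(w1))$amplitudes)^2
  expect_equal(p1, rep(1 / 16, 16), tolerance = 1e-12)

  # S = 16, surviving z in {0, 5, 10, 15}: pointwise against the DFT oracle
  cells <- matrix(0L, 4, 4)
  cells[cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))] <- 1L   # z = 0, 5, 10, 15
  w <- qpr_window(cells)
  p16 <- Mod(apply_qft(qpralign:::collapse_to_reflective(w))$amplitudes)^2
  expect_equal(p16, dft_spectrum_oracle(c(0, 5, 10, 15), 16), tolerance = 1e-9)
})

test_that("QFT is unitary and invertible", {
  for (seed in 1:5) {
    w <- random_window(8, 8, 0.4, seed)
    st <- qpralign:::collapse_to_reflective(w)
    ft <- apply_qft(st)
    expect_equal(sum(Mod(ft$amplitudes)^2), 1, tolerance = 1e-9)
    back <- apply_qft_inverse(ft)
    expect_equal(back$amplitudes, st$amplitudes, tolerance = 1e-9)
  }
})

test_that("wave-number sampling follows the transformed distribution", {
  w1 <- qpr_window(matrix(1L, 4, 4))
  st <- apply_qft(qpralign:::collapse_to_reflective(w1))
  ks <- withr::with_seed(1, sample_k(st, 10))
  expect_equal(ks, rep(0L, 10))          # point-mass spectrum

  # uniform spectrum: chi-square goodness of fit at alpha = 0.01
  wz <- qpr_window(matrix(c(1L, rep(0L, 63)), 8, 8, byrow = TRUE))
  stu <- apply_qft(qpralign:::collapse_to_reflective(wz))
  ku <- withr::with_seed(2, sample_k(stu, 1e4))
  gof <- chisq.test(tabulate(ku + 1L, nbins = 64))
  expect_gt(gof$p.value, 0.01)

  expect_identical(withr::with_seed(3, sample_k(stu, 50)),
                   withr::with_seed(3, sample_k(stu, 50)))
  expect_error(sample_k(stu, 0), "omega")
})

test_that("analytic spectrum equals the statevector pipeline", {
  w <- qpr_window(matrix(c(0L, 1L, 0L, 0L), 2, 2))
  expect_equal(analytic_spectrum(w), rep(1 / 4, 4), tolerance = 1e-12)
  expect_equal(analytic_spectrum(qpr_window(matrix(1L, 4, 4)))[1], 1,
               tolerance = 1e-12)
  for (seed in 1:10) {
    wr <- random_window(8, 4, runif(1, 0.1, 0.9), seed * 7L)
    p <- analytic_spectrum(wr)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    p2 <- Mod(apply_qft(qpralign:::collapse_to_reflective(wr))$amplitudes)^2
    expect_equal(p, p2, tolerance = 1e-9)
  }
  expect_error(analytic_spectrum(qpr_window(matrix(0L, 2, 2))), "rho = 0")
})

test_that("transpose consistency: transposed spectrum equals index remap", {
  for (seed in 1:5) {
    w <- random_window(8, 4, 0.3, seed + 50)
    pt <- analytic_spectrum(qpralign:::transpose_window(w))
    # oracle: recompute with x/y roles exchanged, z' = y + M*x
    idx <- which(w$cells == 1L, arr.ind = TRUE)
    z2 <- (idx[, 1L] - 1L) + w$M * (idx[, 2L] - 1L)
    expect_equal(pt, dft_spectrum_oracle(z2, w$S), tolerance = 1e-9)
  }
})

test_that("routine_qpr returns both orientations with the right shape", {
  pl <- plant_line(16, 16, 10, j = 0, x0 = 4, y0 = 3, seed = 2)
  s <- routine_qpr(pl$window, 32, seed = 4)
  expect_false(s$empty)
  expect_length(s$k_orig, 32L)
  expect_length(s$k_trans, 32L)
  expect_true(all(s$k_orig >= 0 & s$k_orig < 256))
  expect_identical(routine_qpr(pl$window, 8, seed = 9),
                   routine_qpr(pl$window, 8, seed = 9))

  empty <- routine_qpr(qpr_window(matrix(0L, 8, 8)), 8, seed = 1)
  expect_true(empty$empty)
  expect_length(empty$k_orig, 0L)
})

test_that("samples from a planted full-length line land on predicted peaks", {
  pl <- plant_line(16, 16, 16, j = 0, x0 = 7, y0 = 0, seed = 3)
  s <- routine_qpr(pl$window, 64, seed = 5)
  pk <- predict_peaks(pl$line, 16, 16)
  hits <- vapply(s$k_orig, function(k)
    any(abs(k - pk$k) <= pmax(1, pk$half_width)), TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("resource estimation applies the documented counting model", {
  est <- estimate_resources(20, "superconducting", "none", aqft_degree = Inf)
  expect_equal(est$qft_gate_count, 20 * 21 / 2)       # u(u+1)/2 elementary gates
  aq <- estimate_resources(20, "superconducting", "none", aqft_degree = 2)
  expect_lte(aq$gate_counts[["phase_shift"]], est$gate_counts[["phase_shift"]])
  expect_error(estimate_resources(20, "abacus"), "arg")
  expect_error(estimate_resources(1), ">= 2")

  enc <- estimate_resources(10, "trapped-ion", "[[5,1,3]]")
  un <- estimate_resources(10, "trapped-ion", "none")
  expect_true(all(enc$gate_counts > un$gate_counts))
  # time is monotone in register size
  times <- vapply(c(6, 10, 15, 20), function(u)
    estimate_resources(u, "superconducting")$est_time_us, 0)
  expect_true(all(diff(times) > 0))
})
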