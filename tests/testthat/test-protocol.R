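test_that("protocol configuration enforces its invariants", {
  expect_error(protocol_config(L_W = 100), "power of 2")
  expect_error(protocol_config(L_W = 64, L_0 = 64), "smaller than L_W")
  expect_warning(protocol_config(L_W = 64, L_0 = 20), "L_W/4")
  expect_warning(protocol_config(L_W = 256, L_0 = 16, omega = 10000), "cap")
  cfg <- protocol_config(L_W = 256, L_0 = 16)
  expect_equal(cfg$beta_min, 16 / 256^2)
  expect_identical(cfg$omega, "auto")
})

test_that("omega selection respects both bounds", {
  expect_lte(choose_omega(1, 0.1, 0.5), 2)            # beta_min = 1: <= c2
  # halving beta_min never decreases omega
  o <- vapply(2^-(0:8), function(b) choose_omega(b, 0.1, 0.3), 0L)
  expect_true(all(diff(o) >= 0))
  # the O(1/sqrt(beta_min)) cap at beta_min = 1/64
  expect_lte(choose_omega(1 / 64, 0.1, 0.9), ceiling(2 * 8))
  expect_error(choose_omega(0, 0.1, 0.5), "beta_min")
  expect_error(choose_omega(0.5, 0.1, 0), "rho")
})

test_that("suppression clears exactly the record band and is idempotent", {
  pl <- plant_line(32, 32, 12, j = 0, x0 = 10, y0 = 6, seed = 4)
  rec <- data.frame(x0 = 10L, y0 = 6L, L_D = 12L, theta_rad = 0)
  sup <- suppress_region(pl$window, rec)
  # the line is gone: routine + inference on the suppressed window
  s <- routine_qpr(sup, 64, seed = 3)
  expect_true(s$empty || is.null(infer_line(s)))
  # dots outside the band unchanged (cell-count bookkeeping)
  half <- max(1L, ceiling(12 / 4))
  band_cols <- (10 - half):(10 + half)
  outside <- pl$window$cells[, -(band_cols + 1L)]
  expect_equal(sup$cells[, -(band_cols + 1L)], outside)
  # idempotence
  expect_equal(suppress_region(sup, rec)$cells, sup$cells)
  # record outside the window is a domain error
  bad <- data.frame(x0 = 100L, y0 = 6L, L_D = 12L, theta_rad = 0)
  expect_error(suppress_region(pl$window, bad), "outside")
})

test_that("window exhaustion records multiple lines, longest first", {
  pl <- plant_line(64, 64, 12, j = 0, x0 = 10, y0 = 4, seed = 1)
  cl <- qpralign:::line_cells(9, 0, 64, 40, 30)
  cells <- pl$window$cells
  cells[cbind(cl$y + 1, cl$x + 1)] <- 1L
  win <- qpr_window(cells, id = 2L)
  cfg <- protocol_config(L_W = 64, L_0 = 8, omega = 32, seed = 5, elasticity = 0)
  recs <- exhaust_window(win, cfg)
  expect_equal(nrow(recs), 2L)
  expect_equal(recs$L_D, c(12L, 9L))        # longest first
  expect_equal(recs$x0, c(10L, 40L))
  expect_equal(recs$y0, c(4L, 30L))
  expect_true(all(recs$density == 1))
})

test_that("lines below the L_0 cutoff are not recorded", {
  pl <- plant_line(64, 64, 5, j = 0, x0 = 12, y0 = 9, seed = 6, id = 1)
  cfg <- protocol_config(L_W = 64, L_0 = 8, omega = 32, seed = 2)
  expect_equal(nrow(exhaust_window(pl$window, cfg)), 0L)
})

test_that("exhaustion respects the per-window iteration cap", {
  win <- qpr_window(matrix(1L, 64, 64), id = 9L)
  cfg <- protocol_config(L_W = 64, L_0 = 8, omega = 16, seed = 3,
                         max_lines_per_window = 3L)
  recs <- exhaust_window(win, cfg)
  expect_lte(nrow(recs), 3L)
})

test_that("alignment of identical sequences covers the main diagonal", {
  s <- random_dna(64, 70)
  cfg <- suppressWarnings(protocol_config(L_W = 16, L_0 = 8, omega = 16, seed = 11))
  recs <- qpr_align(s, s, cfg)
  expect_gt(nrow(recs), 0)
  expect_equal(min(recs$x0), 0L)
  expect_equal(max(recs$x1), 64L)
  expect_true(all(recs$x0 == recs$y0))      # main diagonal
})

test_that("independent random sequences yield no records", {
  q <- random_dna(256, 81); r <- random_dna(256, 82)
  zero <- 0L
  for (sd in 1:5) {
    cfg <- suppressWarnings(protocol_config(L_W = 64, L_0 = 24, omega = 16, seed = sd))
    if (nrow(qpr_align(q, r, cfg)) == 0L) zero <- zero + 1L
  }
  expect_gte(zero, 5L)
})

test_that("alignment rejects empty input and is deterministic under a seed", {
  cfg <- suppressWarnings(protocol_config(L_W = 16, L_0 = 4, omega = 8, seed = 1))
  expect_error(qpr_align("", "ACGT", cfg), "non-empty")
  pair <- generate_pair(2000L, 4L, 150L, sub_rate = 0.03, seed = 12)
  cfg2 <- protocol_config(L_W = 128, L_0 = 24, word = 6, seed = 4)
  a <- qpr_align(pair$query, pair$reference, cfg2)
  b <- qpr_align(pair$query, pair$reference, cfg2)
  expect_identical(a, b)
  expect_gt(nrow(a), 0)
})

test_that("anchors are true: per-base identity meets the elasticity bound", {
  pair <- generate_pair(3000L, 6L, 150L, sub_rate = 0.05, seed = 22)
  cfg <- protocol_config(L_W = 128, L_0 = 24, word = 6, elasticity = 0.15, seed = 7)
  recs <- qpr_align(pair$query, pair$reference, cfg)
  expect_gt(nrow(recs), 0)
  qq <- strsplit(pair$query$residues, "")[[1]]
  rr <- strsplit(pair$reference$residues, "")[[1]]
  for (i in seq_len(nrow(recs))) {
    ident <- mean(qq[(recs$y0[i] + 1):recs$y1[i]] == rr[(recs$x0[i] + 1):recs$x1[i]])
    expect_gte(ident, 1 - cfg$elasticity)
    expect_equal(ident, recs$density[i], tolerance = 1e-12)
  }
  # records arrive sorted by (x0, y0)
  expect_true(!is.unsorted(recs$x0))
})

test_that("lowering the length cutoff never removes previously reported records", {
  pair <- generate_pair(2000L, 4L, 120L, sub_rate = 0.04, seed = 31)
  recs_hi <- qpr_align(pair$query, pair$reference,
                       suppressWarnings(protocol_config(L_W = 128, L_0 = 48,
                                                        word = 6, seed = 9)))
  recs_lo <- qpr_align(pair$query, pair$reference,
                       protocol_config(L_W = 128, L_0 = 24, word = 6, seed = 9))
  for (i in seq_len(nrow(recs_hi))) {
    ov <- vapply(seq_len(nrow(recs_lo)), function(k)
      min(qpralign:::interval_overlap(recs_hi$x0[i], recs_hi$x1[i],
                                      recs_lo$x0[k], recs_lo$x1[k]),
          qpralign:::interval_overlap(recs_hi$y0[i], recs_hi$y1[i],
                                      recs_lo$y0[k], recs_lo$y1[k])), 0)
    expect_gte(max(ov), 0.5)
  }
})

test_that("planted homologies round-trip with high recall at desk scale", {
  hits <- 0L; total <- 0L
  for (sd in 1:3) {
    pair <- generate_pair(4000L, 8L, 150L, sub_rate = 0.05, seed = 40 + sd)
    cfg <- protocol_config(L_W = 128, L_0 = 24, word = 6, elasticity = 0.15,
                           seed = sd)
    recs <- qpr_align(pair$query, pair$reference, cfg)
    m <- precision_recall(pair$truth, records_to_intervals(recs))
    hits <- hits + m$TP; total <- total + m$TP + m$FN
  }
  expect_gte(hits / total, 0.9)
})
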