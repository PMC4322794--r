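test_that("exchange rate matches the zero-growth and zero-change limits", {
  # constant 1e6 cells, +10 nmol over 10 h -> +1 nmol/1e6 cells/h
  course <- tibble::tibble(t_hours = c(0, 10), cell_count = 1e6,
                           metabolite_nmol = c(100, 110))
  expect_equal(exchange_rate(course), 1)
  course$metabolite_nmol <- c(100, 100)
  expect_equal(exchange_rate(course), 0)
})

test_that("exponential-growth integral agrees with numerical integration", {
  # oracle: trapezoidal integration of X(t) = X0 exp(k t) at 1e4 steps
  X0 <- 1e6
  k <- log(8) / 72
  tt <- 72
  dM <- -300
  grid <- seq(0, tt, length.out = 10001)
  cell_hours <- sum((head(X0 * exp(k * grid), -1) +
                       utils::tail(X0 * exp(k * grid), -1)) / 2) * (tt / 10000)
  oracle <- 1e6 * dM / cell_hours
  course <- tibble::tibble(t_hours = c(0, 72),
                           cell_count = c(X0, X0 * exp(k * 72)),
                           metabolite_nmol = c(1000, 1000 + dM))
  expect_equal(exchange_rate(course), oracle, tolerance = 1e-7)
})

test_that("small growth rates converge to the continuous limit", {
  X0 <- 2e6
  for (k in c(0, 1e-9, 1e-8)) {
    course <- tibble::tibble(
      t_hours = c(0, 10), cell_count = c(X0, X0 * exp(k * 10)),
      metabolite_nmol = c(0, 50))
    expect_equal(exchange_rate(course), 1e6 * 50 / (X0 * 10),
                 tolerance = 1e-6)
  }
})

test_that("exchange rate is invariant to joint rescaling of counts and reference", {
  course <- tibble::tibble(
    t_hours = c(0, 24, 48), cell_count = c(1e5, 3e5, 9e5),
    metabolite_nmol = c(500, 420, 260))
  a1 <- exchange_rate(course)
  scaled <- course
  scaled$cell_count <- scaled$cell_count * 10
  # ten-fold more cells consuming the same amount -> one tenth the rate
  expect_equal(exchange_rate(scaled), a1 / 10)
})

test_that("blank correction subtracts the cell-free course", {
  course <- tibble::tibble(
    t_hours = c(0, 10), cell_count = 1e6,
    metabolite_nmol = c(100, 90), blank_nmol = c(100, 95))
  expect_equal(exchange_rate(course), -1)
  # of the 10 nmol lost, 5 vanished without cells
  expect_equal(exchange_rate(course, blank_correct = TRUE), -0.5)
  expect_error(exchange_rate(course[, 1:3], blank_correct = TRUE),
               "blank_nmol")
})

test_that("exchange rate validates its course", {
  expect_error(exchange_rate(tibble::tibble(
    t_hours = 0, cell_count = 1e6, metabolite_nmol = 1)), "two timepoints")
  expect_error(exchange_rate(tibble::tibble(
    t_hours = c(1, 2), cell_count = 1e6, metabolite_nmol = c(1, 2))),
    "t = 0")
  expect_error(exchange_rate(tibble::tibble(
    t_hours = c(0, 10), cell_count = c(1e6, 0), metabolite_nmol = c(1, 2))),
    "> 0")
})

test_that("SDH activity applies B/(dT x V) x D", {
  expect_equal(sdh_activity(10, 30, 5, 1), 10 / (30 * 5))
  expect_equal(round(sdh_activity(10, 30, 5, 1), 4), 0.0667)
  expect_equal(sdh_activity(10, 30, 5, 2), 2 * sdh_activity(10, 30, 5, 1))
  expect_equal(sdh_activity(0, 30, 5, 4), 0)
  expect_equal(sdh_activity(c(10, 20), 30, 5), c(10, 20) / 150)
  expect_error(sdh_activity(10, 0, 5), "delta_t_min")
  expect_error(sdh_activity(10, 30, -1), "volume_ul")
})

test_that("respiratory parameters follow the stress-test arithmetic", {
  trace <- tibble::tibble(
    phase = c("basal", "oligomycin", "fccp", "rotenone"),
    ocr = c(100, 40, 159, 0))
  p <- respiratory_params(trace)
  expect_equal(p$basal, 100)
  expect_equal(p$maximal, 159)
  expect_equal(p$atp_linked, 60)
  expect_equal(p$reserve_capacity_abs, 59)
  expect_equal(p$reserve_capacity_pct, 59)
  expect_equal(p$non_mitochondrial, 0)
  expect_false(p$reserve_nonexistent)
})

test_that("nonexistent spare capacity is clamped to zero and flagged", {
  trace <- tibble::tibble(
    phase = c("basal", "oligomycin", "fccp", "rotenone"),
    ocr = c(100, 40, 90, 10))
  p <- respiratory_params(trace)
  expect_equal(p$reserve_capacity_abs, 0)
  expect_equal(p$reserve_capacity_pct, 0)
  expect_true(p$reserve_nonexistent)
  # all phases equal: every derived parameter is 0
  flat <- respiratory_params(tibble::tibble(
    phase = c("basal", "oligomycin", "fccp", "rotenone"), ocr = 50))
  expect_equal(unlist(flat[c("basal", "atp_linked", "maximal",
                             "reserve_capacity_abs",
                             "reserve_capacity_pct")]),
               c(basal = 0, atp_linked = 0, maximal = 0,
                 reserve_capacity_abs = 0, reserve_capacity_pct = 0))
})

test_that("phase means are order-invariant and synonyms are accepted", {
  withr::local_seed(8)
  trace <- tibble::tibble(
    phase = rep(c("basal", "post-oligomycin", "post-FCCP",
                  "rotenone-myxothiazol"), each = 3),
    ocr = c(98, 101, 100, 41, 39, 40, 160, 158, 159, 9, 10, 11))
  p1 <- respiratory_params(trace)
  p2 <- respiratory_params(trace[sample(nrow(trace)), ])
  expect_equal(p1, p2)
  expect_error(respiratory_params(trace[trace$phase != "post-FCCP", ]),
               "fccp")
  expect_error(respiratory_params(tibble::tibble(phase = "warp", ocr = 1)),
               "unrecognised")
})
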