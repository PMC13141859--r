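ls2_truth <- function() kinetic_params(k_on = 1.47e5, k_off = 0.0085,
                                       rmax = 100)

test_that("dilution series reproduce the published designs", {
  ser <- dilution_series(50e-3, 2, 10)
  expect_length(ser, 10)
  expect_equal(ser[10], 50e-3 / 2^9)            # ~98 uM from 50 mM
  expect_equal(ser[10] * 1e6, 97.65625)
  expect_equal(dilution_series(1e-6, 2, 1), 1e-6)
  five <- dilution_series(1e-6, 2, 5)
  expect_equal(five[5], 62.5e-9)                # 1 uM down to 62.5 nM
  expect_error(dilution_series(-1, 2, 4), "top")
})

test_that("injection series carry the published timings", {
  bin <- binary_injection_series()
  expect_equal(bin$contact_time, 120)
  expect_equal(bin$dissociation_time, 180)
  ter <- ternary_injection_series()
  expect_equal(ter$contact_time, 400)
  expect_equal(ter$dissociation_time, 600)
  expect_length(ter$concentrations, 5)
  expect_error(injection_series(c(1e-6, 2e-6), 100, 100), "decreasing")
})

test_that("simulated sensorgrams obey the 1:1 closed form", {
  p <- ls2_truth()
  flat <- simulate_sensorgram(p, 0)
  expect_true(all(flat$response == 0))

  sg <- simulate_sensorgram(p, 1e-6, contact_time = 4000,
                            dissociation_time = 10)
  kd <- p$k_off / p$k_on
  plateau <- p$rmax * 1e-6 / (1e-6 + kd)
  expect_equal(max(sg$response), plateau, tolerance = 1e-6)

  sg2 <- simulate_sensorgram(p, 2.5e-7)
  assoc <- sg2$response[sg2$phase == "association"]
  dissoc <- sg2$response[sg2$phase == "dissociation"]
  expect_true(all(diff(assoc) >= -1e-12))       # monotone association
  expect_true(all(diff(dissoc) <= 1e-12))       # monotone dissociation
  expect_true(all(assoc <= p$rmax * 2.5e-7 / (2.5e-7 + kd) + 1e-9))
  expect_error(simulate_sensorgram(p, -1e-9), "non-negative")
})

test_that("the closed form matches an independent ODE integration", {
  skip_if_not_installed("deSolve")
  p <- ls2_truth()
  conc <- 5e-7
  times <- seq(0, 1000, by = 1)
  rhs <- function(t, y, parms) {
    c_t <- if (t <= 400) conc else 0
    list(p$k_on * c_t * (p$rmax - y) - p$k_off * y)
  }
  ode <- deSolve::ode(y = c(R = 0), times = times, func = rhs, parms = NULL,
                      rtol = 1e-10, atol = 1e-10)
  sg <- simulate_sensorgram(p, conc, contact_time = 400,
                            dissociation_time = 600, dt = 1)
  expect_lt(max(abs(sg$response - ode[, "R"])), 1e-6)
})

test_that("noise is reproducible from the seed and absent at sd 0", {
  p <- ls2_truth()
  a <- simulate_sensorgram(p, 1e-7, noise_sd = 2, seed = 7)
  b <- simulate_sensorgram(p, 1e-7, noise_sd = 2, seed = 7)
  c <- simulate_sensorgram(p, 1e-7, noise_sd = 2, seed = 8)
  expect_identical(a$response, b$response)
  expect_false(identical(a$response, c$response))
  expect_error(simulate_sensorgram(p, 1e-7, noise_sd = 2), "seed")
})

test_that("derived constants reproduce the printed LS2 row and scale", {
  dc <- derive_constants(ls2_truth())
  expect_equal(dc$K_D * 1e9, 57.82, tolerance = 1e-3)   # printed as 58 nM
  expect_equal(dc$t_half, 81.55, tolerance = 1e-3)      # printed as 81 s
  unit <- derive_constants(kinetic_params(1, 1, 1))
  expect_equal(unit$K_D, 1)
  expect_equal(unit$t_half, log(2))
  doubled <- derive_constants(kinetic_params(1.47e5, 2 * 0.0085, 100))
  expect_equal(doubled$K_D, 2 * dc$K_D)
  expect_equal(doubled$t_half, dc$t_half / 2)
})

test_that("cooperativity reproduces printed alphas and classifies", {
  ls1 <- cooperativity(1320e-9, 426e-9)
  expect_equal(round(ls1$alpha, 1), 3.1)
  expect_equal(ls1$classification, "positive")
  ls2 <- cooperativity(1810e-9, 58e-9)
  expect_equal(round(ls2$alpha, 1), 31.2)
  neutral <- cooperativity(5e-7, 5e-7)
  expect_equal(neutral$alpha, 1)
  expect_equal(neutral$classification, "neutral")
  expect_equal(cooperativity(1e-7, 4e-7)$classification, "negative")
  # scale invariance
  expect_equal(cooperativity(1320, 426)$alpha, ls1$alpha)
  expect_error(cooperativity(-1, 2), "positive")
})

test_that("noise-free global fits recover the generating parameters", {
  truth <- ls2_truth()
  data <- make_sensorgram_dataset(truth, ternary_injection_series(), 0)
  fit <- fit_kinetics(data)
  expect_equal(fit$params$k_on, truth$k_on, tolerance = 1e-4)
  expect_equal(fit$params$k_off, truth$k_off, tolerance = 1e-4)
  expect_equal(fit$params$rmax, truth$rmax, tolerance = 1e-4)
  g <- glance(fit)
  expect_equal(g$K_D, 57.82e-9, tolerance = 1e-3)
  td <- tidy(fit)
  expect_equal(td$term, c("k_on", "k_off", "rmax"))
  expect_true(all(td$std.error >= 0))
})

test_that("noisy fits at 2 percent Rmax recover rates within 10 percent", {
  truth <- ls2_truth()
  data <- make_sensorgram_dataset(truth, ternary_injection_series(),
                                  noise_sd = 2, seed = 99)
  fit <- fit_kinetics(data)
  expect_lt(abs(fit$params$k_on / truth$k_on - 1), 0.1)
  expect_lt(abs(fit$params$k_off / truth$k_off - 1), 0.1)
})

test_that("poorly designed series trigger warnings, flat data errors", {
  truth <- ls2_truth()
  narrow <- make_sensorgram_dataset(
    truth, injection_series(c(1e-7, 0.5e-7), 400, 600), noise_sd = 0)
  expect_warning(fit_kinetics(narrow), "4-fold")
  flat <- tibble::tibble(time = rep(0:99, 2), response = 0,
                         concentration = rep(c(1e-7, 1e-8), each = 100),
                         cycle = rep(1:2, each = 100))
  expect_error(suppressWarnings(fit_kinetics(flat, contact_time = 50)),
               "flat")
})

test_that("sensorgram tables round-trip and malformed lines are located", {
  data <- make_sensorgram_dataset(ls2_truth(), ternary_injection_series(),
                                  noise_sd = 1, seed = 3, dt = 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sensorgrams(data, path)
  back <- read_sensorgrams(path)
  expect_equal(back$response, data$response, tolerance = 1e-9)
  expect_equal(back$cycle, data$cycle)

  lines <- readLines(path)
  lines[5] <- "oops\t1\t2\t3"
  writeLines(lines, path)
  expect_error(read_sensorgrams(path), "line 5")
})
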