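test_that("spectrum container and CSV round-trip", {
  s <- spectrum(seq(350, 750, 2), rep(0.1, 201))
  expect_equal(length(s$wavelength), 201)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(gen_spectrum(500, 1, 2, noise_sd = 0.01, seed = 1), path)
  back <- read_spectrum(path)
  expect_equal(back$wavelength, seq(350, 750, 2))

  expect_error(spectrum(c(400, 400, 402), c(1, 1, 1)), "ascending")
  expect_error(spectrum(500, 1), "at least 2")
  writeLines("wavelength_nm,absorbance\n500,0.5", path)
  expect_error(read_spectrum(path), "fewer than 2")
  writeLines("wavelength_nm,absorbance\n500,0.5\n498,0.4", path)
  expect_error(read_spectrum(path), "ascending")
})

test_that("A1 template peaks at unity on lambda_max with a beta band", {
  tpl <- template_absorbance(491, grid = seq(330, 750, 0.5))
  expect_equal(tpl$absorbance[tpl$wavelength == 491], 1, tolerance = 1e-9)
  expect_true(all(tpl$absorbance >= 0))
  expect_lte(max(tpl$absorbance), 1 + 1e-6)
  # beta band: secondary short-wavelength elevation
  blue <- tpl$absorbance[tpl$wavelength >= 340 & tpl$wavelength <= 380]
  trough <- min(tpl$absorbance[tpl$wavelength >= 400 &
                               tpl$wavelength <= 450])
  expect_gt(max(blue), trough)

  # red-shifted templates absorb more at long wavelengths
  t550 <- template_absorbance(550)
  t431 <- template_absorbance(431)
  expect_gt(t550$absorbance[t550$wavelength == 650],
            t431$absorbance[t431$wavelength == 650])

  expect_error(template_absorbance(300), "validity range")
  expect_error(template_absorbance(700), "validity range")
})

test_that("A1 half-max bandwidth matches the rod-pigment signature", {
  bw <- half_max_bandwidth_wavenumber(
    template_absorbance(491, grid = seq(350, 750, 2)))
  expect_gte(bw, 4170 - 234)
  expect_lte(bw, 4170 + 234)
})

test_that("bandwidth of a wavenumber-Gaussian matches the closed form", {
  sigma <- 1500                              # cm^-1
  nu0 <- 1e7 / 500
  grid <- seq(350, 750, 0.25)
  nu <- 1e7 / grid
  g <- spectrum(grid, exp(-(nu - nu0)^2 / (2 * sigma^2)))
  expect_equal(half_max_bandwidth_wavenumber(g),
               2 * sigma * sqrt(2 * log(2)), tolerance = 1e-3)

  # truncated red flank errors with the flank named
  tr <- spectrum(seq(350, 520, 2),
                 template_absorbance(491, seq(350, 520, 2))$absorbance)
  expect_error(half_max_bandwidth_wavenumber(tr), "red")
})

test_that("Fourier filter preserves DC, kills the stop band, denoises", {
  const <- spectrum(seq(350, 750, 2), rep(0.42, 201))
  expect_equal(fourier_filter(const, 40)$absorbance, rep(0.42, 201),
               tolerance = 1e-10)

  grid <- seq(350, 750, 2)
  hf <- spectrum(grid, sin(2 * pi * grid / 6))
  filtered <- fourier_filter(hf, 40)
  expect_lt(max(abs(filtered$absorbance)), 1e-10)

  # noise SD 0.05 on a clean template: filtering halves the RMS error
  # (median over ten fixed noise draws; end-of-record ringing keeps single
  # draws close to the factor-two mark)
  clean <- template_absorbance(500, grid)$absorbance
  rms <- function(v) sqrt(mean(v^2))
  ratio <- vapply(1:10, function(s) {
    noisy <- gen_spectrum(500, 1, 2, grid = grid, noise_sd = 0.05,
                          seed = s)
    rms(fourier_filter(noisy, 40)$absorbance - clean) /
      rms(noisy$absorbance - clean)
  }, numeric(1))
  expect_lt(stats::median(ratio), 0.5)

  expect_error(fourier_filter(const, 3), "twice the grid step")
  nonuni <- spectrum(c(400, 402, 405, 410), c(1, 2, 3, 4))
  expect_error(fourier_filter(nonuni, 40), "uniform")
})

test_that("lambda_max estimation recovers templates and rejects flats", {
  s <- gen_spectrum(514, 1, 2)
  expect_equal(estimate_lambda_max(s)$lambda_max, 514, tolerance = 0.5)

  err <- vapply(1:25, function(seed) {
    n <- gen_spectrum(491, 1, 2, noise_sd = 0.02, seed = seed)
    abs(estimate_lambda_max(n)$lambda_max - 491)
  }, numeric(1))
  expect_lte(mean(err), 3)

  flat <- spectrum(seq(350, 750, 2), rep(0, 201))
  expect_error(estimate_lambda_max(flat), "flat")
})

test_that("mixture response obeys its algebraic identities", {
  grid <- default_grid()
  tpl <- template_absorbance(500, grid)$absorbance
  one <- mixture_response(1, 3.7, 500, grid)
  expect_equal(one$absorbance, tpl, tolerance = 1e-12)

  lin <- mixture_response(c(0.7, 0.3), 1, c(431, 527), grid)
  expect_equal(lin$absorbance,
               0.7 * template_absorbance(431, grid)$absorbance +
               0.3 * template_absorbance(527, grid)$absorbance,
               tolerance = 1e-12)

  # symmetry under pigment permutation
  a <- mixture_response(c(1.398, 0.061), 5.523, c(431, 500), grid)
  b <- mixture_response(c(0.061, 1.398), 5.523, c(500, 431), grid)
  expect_equal(a$absorbance, b$absorbance, tolerance = 1e-12)

  # monotone in each coupling constant
  lo <- mixture_response(c(1.0, 0.05), 4, c(431, 500), grid)
  hi <- mixture_response(c(1.0, 0.20), 4, c(431, 500), grid)
  expect_true(all(hi$absorbance >= lo$absorbance - 1e-12))

  expect_error(mixture_response(c(1, 2), 2, 431), "same length")
  expect_error(mixture_response(numeric(0), 2, numeric(0)), "empty")
  expect_error(mixture_response(1, -2, 431), "p")
})

test_that("the co-expression hump appears above the single-pigment curve", {
  grid <- default_grid()
  mix <- mixture_response(c(1.398, 0.061), 5.523, c(431, 500), grid)
  pure <- mixture_response(1.398^(1 / 5.523), 1, 431, grid)
  sel <- grid >= 460 & grid <= 540
  expect_true(all(mix$absorbance[sel] > pure$absorbance[sel]))
  expect_true(all(mix$absorbance >= pure$absorbance - 1e-9))
})

test_that("gen_spectrum is the analytic response plus calibrated noise", {
  clean <- gen_spectrum(c(431, 500), c(1.398, 0.061), 5.523)
  analytic <- mixture_response(c(1.398, 0.061), 5.523, c(431, 500))
  expect_equal(clean$absorbance, analytic$absorbance, tolerance = 1e-12)

  noisy <- gen_spectrum(c(431, 500), c(1.398, 0.061), 5.523,
                        noise_sd = 0.01, seed = 42)
  resid <- noisy$absorbance - analytic$absorbance
  expect_equal(stats::sd(resid), 0.01, tolerance = 0.25)
  expect_identical(
    noisy$absorbance,
    gen_spectrum(c(431, 500), c(1.398, 0.061), 5.523, noise_sd = 0.01,
                 seed = 42)$absorbance)

  expect_error(gen_spectrum(numeric(0), numeric(0), 2), "empty")
})

test_that("noiseless mixture refit recovers the generating parameters", {
  obs <- gen_spectrum(c(431, 500), c(1.398, 0.061), 5.523)
  fits <- fit_mixture(obs, list(c(431, 500)))
  best <- fits[[1]]
  expect_lte(abs(best$k[1] - 1.398) / 1.398, 0.01)
  expect_lte(abs(best$k[2] - 0.061) / 0.061, 0.01)
  expect_lte(abs(best$p - 5.523) / 5.523, 0.01)
  expect_lte(best$ss, 1e-8)
  # reported SS equals independent recomputation from the parameters
  recomp <- sum((mixture_response(best$k, best$p, best$lambda_max,
                                  obs$wavelength)$absorbance -
                 obs$absorbance)^2)
  expect_equal(best$ss, recomp, tolerance = 1e-10)
})

test_that("model selection ranks the generating pigment pair first", {
  obs <- gen_spectrum(c(431, 500), c(1.398, 0.061), 5.523)
  sets <- list(431, c(431, 457), c(431, 500), c(431, 514), c(431, 527))
  fits <- fit_mixture(obs, sets)
  expect_equal(fits[[1]]$lambda_max, c(431, 500))
  ss <- vapply(fits, function(f) f$ss, numeric(1))
  expect_true(!is.unsorted(ss))
})

test_that("single-pigment fit degenerates gracefully", {
  obs <- gen_spectrum(431, 1, 2)
  f <- fit_mixture(obs, list(431))[[1]]
  # only k^(1/p) is identified; the response itself must match
  expect_lt(f$ss, 1e-10)
  expect_equal(f$k[1]^(1 / f$p), 1, tolerance = 0.01)
  expect_true(is.finite(f$p))
})

test_that("mixture_fit methods are mutually consistent", {
  obs <- gen_spectrum(c(431, 500), c(1.398, 0.061), 5.523,
                      noise_sd = 0.005, seed = 9)
  f <- fit_mixture(obs, list(c(431, 500)))[[1]]
  expect_named(coef(f), c("k_431", "k_500", "p"))
  expect_equal(residuals(f), obs$absorbance - fitted(f))
  expect_equal(sum(residuals(f)^2), f$ss, tolerance = 1e-10)
  pr <- predict(f, grid = seq(400, 600, 5))
  expect_s3_class(pr, "spectrum")
  expect_equal(length(pr$wavelength), 41)
  expect_error(fit_mixture(obs, list()), "candidate")
})
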