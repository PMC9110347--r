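# Visual-pigment absorbance spectra: container and I/O, A1 nomogram
# templates, Fourier low-pass filtering, lambda_max and half-maximum
# bandwidth estimation, and the pigment-mixture response model
#
#   R(lambda) = [ sum_i k_i * A_i(lambda)^p ]^(1/p)
#
# fitted to observed spectra by Nelder-Mead (Simplex) least squares. A_i is
# the absorbance template of pigment i (normalized to 1 at its lambda_max),
# the k_i are non-negative coupling constants, and p > 0 is an exponent
# that keeps the fitted absorbance function differentiable at the origin.

#' Default microspectrophotometry wavelength grid (350-750 nm, 2 nm steps)
#' @return Numeric vector of wavelengths in nm.
#' @export
default_grid <- function() seq(350, 750, by = 2)

#' Absorbance spectrum container
#'
#' @param wavelength Ascending numeric vector, nm.
#' @param absorbance Numeric vector, same length.
#' @param meta Optional named list (cell type, number of scans, ...).
#' @return Object of class `spectrum`.
#' @export
spectrum <- function(wavelength, absorbance, meta = list()) {
  wavelength <- as.numeric(wavelength)
  absorbance <- as.numeric(absorbance)
  if (length(wavelength) != length(absorbance))
    stop("`wavelength` and `absorbance` must have the same length")
  if (length(wavelength) < 2L)
    stop("a spectrum needs at least 2 samples")
  if (any(diff(wavelength) <= 0))
    stop("wavelengths must be strictly ascending (no duplicates)")
  structure(list(wavelength = wavelength, absorbance = absorbance,
                 meta = meta),
            class = "spectrum")
}

is_uniform_grid <- function(w, tol = 1e-6) {
  d <- diff(w)
  max(d) - min(d) <= tol * mean(d)
}

#' @export
print.spectrum <- function(x, ...) {
  cat("Absorbance spectrum: ", length(x$wavelength), " samples, ",
      min(x$wavelength), "-", max(x$wavelength), " nm",
      if (is_uniform_grid(x$wavelength))
        paste0(" (uniform ", diff(x$wavelength[1:2]), " nm grid)") else
        " (non-uniform grid)", "\n", sep = "")
  invisible(x)
}

#' @export
plot.spectrum <- function(x, type = "l", ...) {
  graphics::plot(x$wavelength, x$absorbance, type = type,
                 xlab = "wavelength (nm)", ylab = "absorbance", ...)
  invisible(x)
}

#' Read a spectrum from CSV (`wavelength_nm,absorbance`)
#'
#' Non-uniform grids are accepted (with a message) but are rejected later
#' by [fourier_filter()].
#'
#' @param path Path to the CSV file.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  need <- c("wavelength_nm", "absorbance")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  if (nrow(df) < 2L) stop("spectrum in ", path, " has fewer than 2 rows")
  if (any(diff(df$wavelength_nm) <= 0))
    stop("wavelengths in ", path,
         " must be strictly ascending without duplicates")
  s <- spectrum(df$wavelength_nm, df$absorbance,
                meta = list(source = path))
  if (!is_uniform_grid(s$wavelength))
    message("note: non-uniform wavelength grid in ", path)
  s
}

#' Write a spectrum to CSV
#' @param spec A [spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  df <- data.frame(wavelength_nm = spec$wavelength,
                   absorbance = spec$absorbance)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' A1 visual-pigment absorbance template
#'
#' Standard vitamin-A1 (retinal) nomogram parameterized solely by
#' lambda_max: the Govardovskii-type alpha band plus the Gaussian beta
#' band, renormalized to exactly 1 at lambda_max. The beta band matters
#' because short-wavelength absorbance is often missing or noisy in
#' microspectrophotometry records.
#'
#' @param lambda_max Peak wavelength in nm; must lie in the A1 validity
#'   range 330-620 nm.
#' @param grid Wavelength grid in nm (default [default_grid()]).
#' @return Object of class `pigment_template` (also a `spectrum`), with
#'   element `lambda_max`.
#' @examples
#' tpl <- template_absorbance(491)
#' tpl$absorbance[tpl$wavelength == 491]
#' @export
template_absorbance <- function(lambda_max, grid = default_grid()) {
  if (!is.finite(lambda_max) || lambda_max < 330 || lambda_max > 620)
    stop("`lambda_max` = ", lambda_max,
         " nm outside the A1 template validity range [330, 620] nm")
  v <- a1_template_raw(lambda_max, grid)
  peak <- a1_template_raw(lambda_max, lambda_max)
  structure(list(wavelength = grid, absorbance = v / peak,
                 lambda_max = lambda_max, chromophore = "A1",
                 meta = list()),
            class = c("pigment_template", "spectrum"))
}

# alpha + beta bands, un-normalized (alpha alone is ~1 at lambda_max)
a1_template_raw <- function(lambda_max, lambda) {
  x <- lambda_max / lambda
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lambda_max
  bb <- -40.5 + 0.195 * lambda_max
  beta <- 0.26 * exp(-((lambda - lmb) / bb)^2)
  alpha + beta
}

#' Evaluate the pigment-mixture response function
#'
#' R(lambda) = [sum_i k_i A_i(lambda)^p]^(1/p), the overall absorbance of
#' a photoreceptor co-expressing several pigments with coupling constants
#' k_i. With a single pigment and k = 1 the response equals the template;
#' with p = 1 it is a plain weighted sum.
#'
#' @param k Non-negative coupling constants, one per pigment.
#' @param p Positive exponent.
#' @param lambda_max Peak wavelengths (nm) of the component pigments.
#' @param grid Wavelength grid (nm).
#' @param template_fun Template generator, by default
#'   [template_absorbance()]; any function of `(lambda_max, grid)`
#'   returning an object with an `absorbance` element may be plugged in.
#' @return A [spectrum()] of the response.
#' @examples
#' r <- mixture_response(c(1.398, 0.061), 5.523, c(431, 500))
#' @export
mixture_response <- function(k, p, lambda_max, grid = default_grid(),
                             template_fun = template_absorbance) {
  if (length(k) != length(lambda_max))
    stop("`k` and `lambda_max` must have the same length")
  if (!length(k)) stop("empty pigment list")
  if (any(k < 0)) stop("coupling constants must be >= 0")
  if (!is.finite(p) || p <= 0) stop("`p` must be > 0")
  acc <- 0
  for (i in seq_along(k)) {
    A <- template_fun(lambda_max[i], grid)$absorbance
    acc <- acc + k[i] * A^p
  }
  spectrum(grid, acc^(1 / p),
           meta = list(k = k, p = p, lambda_max = lambda_max))
}

#' Generate a noisy mixture spectrum
#'
#' Forward-evaluates [mixture_response()] and adds i.i.d. Gaussian noise;
#' with `noise_sd = 0` the output equals the analytic response exactly.
#'
#' @inheritParams mixture_response
#' @param noise_sd Additive noise SD in absorbance units (>= 0).
#' @param seed Integer seed.
#' @return A [spectrum()].
#' @export
gen_spectrum <- function(lambda_max, k, p, grid = default_grid(),
                         noise_sd = 0, seed = 0,
                         template_fun = template_absorbance) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  r <- mixture_response(k, p, lambda_max, grid, template_fun)
  if (noise_sd > 0) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
    r$absorbance <- r$absorbance + stats::rnorm(length(grid), 0, noise_sd)
  }
  r$meta$noise_sd <- noise_sd
  r$meta$seed <- seed
  r
}

#' Fourier low-pass filter of a spectrum
#'
#' Removes frequency components with period shorter than `cutoff_period`
#' (in nm along the wavelength axis); the DC component is kept, so the
#' mean absorbance is preserved. Used to derive smooth fits from noisy
#' microspectrophotometer records.
#'
#' @param spec A [spectrum()] on a uniform grid.
#' @param cutoff_period Shortest period retained, nm; must exceed twice
#'   the grid step.
#' @return A filtered [spectrum()] on the same grid.
#' @export
fourier_filter <- function(spec, cutoff_period = 40) {
  stopifnot(inherits(spec, "spectrum"))
  if (!is_uniform_grid(spec$wavelength))
    stop("Fourier filtering requires a uniform wavelength grid")
  step <- diff(spec$wavelength[1:2])
  if (cutoff_period <= 2 * step)
    stop("`cutoff_period` must exceed twice the grid step (",
         2 * step, " nm)")
  y <- spec$absorbance
  n <- length(y)
  co <- stats::fft(y)
  freq <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n * step)
  co[abs(freq) > 1 / cutoff_period] <- 0
  spectrum(spec$wavelength, Re(stats::fft(co, inverse = TRUE)) / n,
           meta = c(spec$meta, list(fourier_cutoff_nm = cutoff_period)))
}

#' Estimate lambda_max of a single-pigment spectrum
#'
#' Fits a single A1 template, with its scale obtained by linear least
#' squares, over a coarse 1 nm grid of candidate lambda_max values within
#' `search_range`, then refines the best candidate by golden-section
#' optimization.
#'
#' @param spec A [spectrum()] covering the search range.
#' @param search_range Length-2 numeric, nm (default the full A1 validity
#'   range intersected with the spectrum support).
#' @param template_fun Template generator (see [mixture_response()]).
#' @return List with `lambda_max` (nm), `scale`, and `ss` (residual sum
#'   of squares).
#' @examples
#' s <- gen_spectrum(514, 1, 2)
#' estimate_lambda_max(s)$lambda_max
#' @export
estimate_lambda_max <- function(spec, search_range = NULL,
                                template_fun = template_absorbance) {
  stopifnot(inherits(spec, "spectrum"))
  if (stats::sd(spec$absorbance) == 0)
    stop("flat spectrum: lambda_max undefined")
  if (is.null(search_range))
    search_range <- c(max(330, min(spec$wavelength)),
                      min(620, max(spec$wavelength)))
  if (search_range[1] < min(spec$wavelength) ||
      search_range[2] > max(spec$wavelength))
    stop("spectrum does not cover the search range")
  ss_at <- function(lm) {
    tv <- template_fun(lm, spec$wavelength)$absorbance
    sc <- sum(tv * spec$absorbance) / sum(tv * tv)
    sum((spec$absorbance - sc * tv)^2)
  }
  cand <- seq(search_range[1], search_range[2], by = 1)
  ss <- vapply(cand, ss_at, numeric(1))
  best <- cand[which.min(ss)]
  lo <- max(search_range[1], best - 1.5)
  hi <- min(search_range[2], best + 1.5)
  opt <- stats::optimize(ss_at, c(lo, hi), tol = 1e-4)
  lm <- opt$minimum
  tv <- template_fun(lm, spec$wavelength)$absorbance
  list(lambda_max = lm,
       scale = sum(tv * spec$absorbance) / sum(tv * tv),
       ss = opt$objective)
}

#' Half-maximum bandwidth on the wavenumber axis
#'
#' Full width of the alpha band at half of the peak absorbance, measured
#' in wavenumber (cm^-1): the two crossings of half-maximum nearest the
#' peak are located by linear interpolation and converted via
#' nu = 1e7 / lambda(nm). For an A1 pigment this is close to 4170 cm^-1,
#' a signature used to identify the chromophore.
#'
#' @param spec A [spectrum()] or [template_absorbance()] result with a
#'   unique absorbance maximum bracketed by both half-maximum crossings.
#' @return Bandwidth nu_blue - nu_red in cm^-1 (positive).
#' @examples
#' half_max_bandwidth_wavenumber(template_absorbance(491))
#' @export
half_max_bandwidth_wavenumber <- function(spec) {
  stopifnot(inherits(spec, "spectrum"))
  y <- spec$absorbance
  w <- spec$wavelength
  ipk <- which.max(y)
  half <- y[ipk] / 2
  cross_toward <- function(side) {
    ii <- if (side == "blue") rev(seq_len(ipk)) else ipk:length(y)
    below <- which(y[ii] < half)
    if (!length(below))
      stop("half-maximum not bracketed on the ", side,
           " flank of the spectrum")
    j2 <- ii[below[1]]                       # first sample below half
    j1 <- if (side == "blue") j2 + 1L else j2 - 1L
    w[j1] + (w[j2] - w[j1]) * (y[j1] - half) / (y[j1] - y[j2])
  }
  lam_blue <- cross_toward("blue")
  lam_red <- cross_toward("red")
  1e7 / lam_blue - 1e7 / lam_red
}

#' Fit pigment-mixture models to a spectrum (Simplex least squares)
#'
#' For each candidate set of pigment peak wavelengths, minimizes
#' SS(k, p) = sum over the grid of (R(lambda) - A_obs(lambda))^2 by
#' Nelder-Mead, with positivity of the k_i and p enforced through a log
#' parameterization. Each candidate set is fit from multiple starts
#' (p0 in {1, 2, 4}; k0 from matching the observed absorbance at each
#' pigment's peak) and polished from the best start; fits are returned
#' ranked by SS, mirroring the model-selection table in which the pigment
#' combination with the least sum of squares is preferred.
#'
#' @param spec Observed [spectrum()].
#' @param candidate_sets List of numeric vectors of lambda_max values
#'   (nm); a single vector is treated as one candidate set.
#' @param normalize If `TRUE`, the observed spectrum is scaled to unit
#'   peak before fitting; the default fits the absorbance as given.
#' @param template_fun Template generator (see [mixture_response()]).
#' @param p_starts Starting exponents for the multi-start.
#' @param maxit,reltol Nelder-Mead control parameters.
#' @return Object of class `mixture_fit_list`: a list of `mixture_fit`
#'   objects sorted ascending by `ss`, best first. Each `mixture_fit` has
#'   elements `lambda_max`, `k`, `p`, `ss`, `converged`, `fitted`
#'   (a [spectrum()]), and `observed`.
#' @examples
#' obs <- gen_spectrum(c(431, 500), c(1.398, 0.061), 5.523)
#' fits <- fit_mixture(obs, list(431, c(431, 500)))
#' coef(fits[[1]])
#' @export
fit_mixture <- function(spec, candidate_sets, normalize = FALSE,
                        template_fun = template_absorbance,
                        p_starts = c(1, 2, 4), maxit = 5000,
                        reltol = 1e-12) {
  stopifnot(inherits(spec, "spectrum"))
  if (!is.list(candidate_sets)) candidate_sets <- list(candidate_sets)
  if (!length(candidate_sets)) stop("no candidate pigment sets given")
  if (any(!vapply(candidate_sets, length, 1L)))
    stop("every candidate set must contain at least one pigment")
  obs <- spec$absorbance
  if (normalize) obs <- obs / max(obs)
  grid <- spec$wavelength
  fits <- lapply(candidate_sets, function(lmax) {
    fit_one_set(obs, grid, lmax, template_fun, p_starts, maxit, reltol)
  })
  fits <- fits[order(vapply(fits, function(f) f$ss, numeric(1)))]
  for (i in seq_along(fits)) {
    fits[[i]]$observed <- spectrum(grid, obs)
    class(fits[[i]]) <- "mixture_fit"
  }
  structure(fits, class = "mixture_fit_list")
}

fit_one_set <- function(obs, grid, lmax, template_fun, p_starts, maxit,
                        reltol) {
  templates <- lapply(lmax, function(lm)
    template_fun(lm, grid)$absorbance)
  response <- function(k, p) {
    acc <- 0
    for (i in seq_along(k)) acc <- acc + k[i] * templates[[i]]^p
    acc^(1 / p)
  }
  ssfun <- function(theta) {
    k <- exp(theta[seq_along(lmax)])
    p <- exp(theta[length(lmax) + 1L])
    if (!is.finite(p) || p > 50) return(1e10)
    r <- response(k, p)
    if (any(!is.finite(r))) return(1e10)
    sum((r - obs)^2)
  }
  # k0 from peak matching: if pigment i dominated at its own peak, the
  # observed absorbance there would be ~ k_i^(1/p)
  peak_obs <- vapply(lmax, function(lm)
    max(obs[which.min(abs(grid - lm))], 0.05), numeric(1))
  best <- NULL
  for (p0 in p_starts) {
    theta0 <- c(log(peak_obs^p0), log(p0))
    o <- stats::optim(theta0, ssfun, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
    if (is.null(best) || o$value < best$value) best <- o
  }
  # polish from the incumbent optimum
  o <- stats::optim(best$par, ssfun, method = "Nelder-Mead",
                    control = list(maxit = maxit, reltol = reltol))
  if (o$value <= best$value) best <- o
  k <- exp(best$par[seq_along(lmax)])
  p <- exp(best$par[length(lmax) + 1L])
  list(lambda_max = lmax, k = unname(k), p = unname(p), ss = best$value,
       converged = best$convergence == 0,
       fitted = spectrum(grid, response(k, p)))
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Pigment mixture fit: lambda_max = {",
      paste(x$lambda_max, collapse = ", "), "} nm\n", sep = "")
  cat("  k = ", paste(sprintf("%.4g", x$k), collapse = ", "),
      ";  p = ", sprintf("%.4g", x$p),
      ";  SS = ", sprintf("%.4g", x$ss),
      if (!x$converged) "  (NOT converged)", "\n", sep = "")
  invisible(x)
}

#' @export
print.mixture_fit_list <- function(x, ...) {
  cat("Ranked pigment-mixture fits (best first):\n")
  for (i in seq_along(x)) {
    cat(sprintf("%2d. {%s} nm: SS = %.4g\n", i,
                paste(x[[i]]$lambda_max, collapse = ", "), x[[i]]$ss))
  }
  invisible(x)
}

#' @export
summary.mixture_fit <- function(object, ...) {
  res <- object$observed$absorbance - object$fitted$absorbance
  cat("Pigment mixture model R = [sum_i k_i A_i^p]^(1/p)\n")
  print(object)
  cat(sprintf("  residuals: RMS %.4g, range [%.4g, %.4g] over %d samples\n",
              sqrt(mean(res^2)), min(res), max(res), length(res)))
  invisible(object)
}

#' @export
coef.mixture_fit <- function(object, ...) {
  stats::setNames(c(object$k, object$p),
                  c(paste0("k_", object$lambda_max), "p"))
}

#' @export
fitted.mixture_fit <- function(object, ...) object$fitted$absorbance

#' @export
residuals.mixture_fit <- function(object, ...)
  object$observed$absorbance - object$fitted$absorbance

#' @export
predict.mixture_fit <- function(object, grid = NULL,
                                template_fun = template_absorbance, ...) {
  if (is.null(grid)) return(object$fitted)
  mixture_response(object$k, object$p, object$lambda_max, grid,
                   template_fun)
}

#' @export
plot.mixture_fit <- function(x, ...) {
  graphics::plot(x$observed$wavelength, x$observed$absorbance, pch = 16,
                 cex = 0.5, xlab = "wavelength (nm)",
                 ylab = "absorbance", ...)
  graphics::lines(x$fitted$wavelength, x$fitted$absorbance,
                  col = "firebrick", lwd = 2)
  invisible(x)
}
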