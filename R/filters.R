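#' Least-squares linear-phase FIR bandpass design
#'
#' Designs an odd-length, even-symmetric (type I) FIR filter minimising the
#' integrated squared error between its amplitude response and an ideal
#' bandpass over passband and stopbands, with don't-care transition regions.
#' Solving the normal equations of this least-squares problem in the cosine
#' basis gives the coefficients directly (no iteration).
#'
#' @param numtaps odd filter length.
#' @param lo,hi passband edges, Hz.
#' @param fs sampling rate, Hz.
#' @param trans_lo,trans_hi transition widths, Hz; defaults follow the band
#'   edges (`min(lo/2, 2)` below, `min(hi/4, 2)` above).
#' @return numeric vector of `numtaps` coefficients (symmetric).
#' @keywords internal
design_fir_bandpass <- function(numtaps, lo, hi, fs,
                                trans_lo = min(lo / 2, 2),
                                trans_hi = min(hi / 4, 2)) {
  if (numtaps %% 2 == 0) numtaps <- numtaps - 1
  if (numtaps < 9)
    bna_stop("bna_filter_too_short", "FIR filter needs at least 9 taps")
  nyq <- fs / 2
  if (hi + trans_hi >= nyq)
    bna_stop("bna_filter_band", "upper band edge too close to Nyquist")
  M <- (numtaps - 1) / 2
  # bands as (lo, hi, desired) in normalised frequency (cycles/sample)
  bands <- list(c(lo / fs, hi / fs, 1),
                c((hi + trans_hi) / fs, 0.5, 0))
  if (lo - trans_lo > 0)
    bands <- c(list(c(0, (lo - trans_lo) / fs, 0)), bands)
  # I(m) = integral of cos(2 pi f m) over a band
  band_int <- function(b, m) {
    out <- numeric(length(m))
    z <- m == 0
    out[z] <- b[2] - b[1]
    mm <- m[!z]
    out[!z] <- (sin(2 * pi * b[2] * mm) - sin(2 * pi * b[1] * mm)) / (2 * pi * mm)
    out
  }
  k <- 0:M
  G <- matrix(0, M + 1, M + 1)
  r <- numeric(M + 1)
  for (b in bands) {
    for (i in k) {
      G[i + 1, ] <- G[i + 1, ] + 0.5 * (band_int(b, k - i) + band_int(b, k + i))
    }
    r <- r + b[3] * band_int(b, k)
  }
  a <- tryCatch(solve(G, r),
                error = function(e) solve(G + diag(1e-10, M + 1), r))
  h <- numeric(numtaps)
  h[M + 1] <- a[1]
  if (M > 0) {
    h[M + 1 + 1:M] <- a[-1] / 2
    h[M + 1 - 1:M] <- a[-1] / 2
  }
  h
}

# Evaluate the amplitude response of a symmetric FIR at frequencies f (Hz).
fir_response <- function(h, f, fs) {
  n <- length(h)
  M <- (n - 1) / 2
  sapply(f, function(fi) {
    w <- 2 * pi * fi / fs
    sum(h * cos(w * ((0:(n - 1)) - M)))
  })
}

# Zero-phase filtering: forward pass then time-reversed pass (net squared
# magnitude response, zero phase), with symmetric reflection padding of one
# filter length at each end.  x is a channels x time matrix.
filtfilt_fir <- function(x, h) {
  x <- rbind(x)
  n <- ncol(x)
  L <- length(h)
  if (L >= n)
    bna_stop("bna_filter_too_long",
             sprintf("filter length %d >= signal length %d", L, n))
  pad <- L
  idx_pre <- pmin(pad + 1, n):2
  idx_post <- (n - 1):max(1, n - pad)
  # forward + reverse = single convolution with conv(h, rev(h)); h symmetric
  g <- stats::convolve(h, rev(h), type = "open")  # length 2L - 1
  delay <- L - 1
  t(apply(x, 1, function(row) {
    xp <- c(row[idx_pre], row, row[idx_post])
    y <- stats::convolve(xp, rev(g), type = "open")
    y[(delay + length(idx_pre) + 1):(delay + length(idx_pre) + n)]
  }))
}

#' Decompose an ERP into conventional frequency bands
#'
#' Applies a least-squares linear-phase FIR bandpass, forward then reversed
#' (zero net phase), for each requested band: delta (0.5-4 Hz),
#' theta (3-8 Hz), alpha (7-13 Hz), beta (12-30 Hz).  Band edges overlap by
#' design, as is conventional for ERP decomposition.
#'
#' @param rec a [erp_record()].
#' @param bands character vector of band names (subset of
#'   `c("delta", "theta", "alpha", "beta")`).
#' @param filter_length optional FIR length; default
#'   `3 * fs / lower_edge` samples (three cycles of the slowest passband
#'   component), capped at `signal length - 1` and forced odd.
#' @return Named list, one channels x time matrix per band.
#' @export
bandpass_decompose <- function(rec, bands = names(BNA_BANDS),
                               filter_length = NULL) {
  stopifnot(inherits(rec, "bna_erp"))
  fs <- rec$sampling_rate_hz
  n <- ncol(rec$data)
  out <- list()
  for (band in bands) {
    check_band(band)
    edges <- BNA_BANDS[[band]]
    if (fs <= 2 * edges[2])
      bna_stop("bna_filter_band",
               sprintf("sampling rate %g Hz too low for band %s", fs, band))
    L <- filter_length
    if (is.null(L)) L <- round(3 * fs / edges[1])
    if (L >= n) L <- n - 1
    if (L %% 2 == 0) L <- L - 1
    if (!is.null(filter_length) && filter_length >= n)
      bna_stop("bna_filter_too_long",
               sprintf("filter length %d >= signal length %d", filter_length, n))
    h <- design_fir_bandpass(L, edges[1], edges[2], fs)
    out[[band]] <- filtfilt_fir(rec$data, h)
    rownames(out[[band]]) <- rownames(rec$data)
  }
  out
}
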