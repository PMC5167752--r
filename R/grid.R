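#' Scalp grid geometry
#'
#' The high-resolution scalp grid: `n_lr` pixels along the left-right axis,
#' `n_ap` along the anterior-posterior axis, with a circular head mask in
#' grid-fraction coordinates.  The default 33 x 37 grid gives roughly four
#' times the spatial resolution of a 10-20 electrode placement.
#'
#' @param n_lr,n_ap pixel counts along the two spatial axes.
#' @return An object of class `bna_geometry` with pixel-centre coordinates
#'   (`u`, `v` in `[0, 1]`) and a logical head `mask`.
#' @export
grid_geometry <- function(n_lr = 33, n_ap = 37) {
  stopifnot(n_lr >= 4, n_ap >= 4)
  u <- seq(0, 1, length.out = n_lr)
  v <- seq(0, 1, length.out = n_ap)
  mask <- outer(u, v, function(a, b) (a - 0.5)^2 + (b - 0.5)^2 <= 0.25 + 1e-12)
  structure(list(n_lr = n_lr, n_ap = n_ap, u = u, v = v, mask = mask),
            class = "bna_geometry")
}

#' @export
print.bna_geometry <- function(x, ...) {
  cat(sprintf("<bna_geometry> %d x %d grid, %d masked pixels\n",
              x$n_lr, x$n_ap, sum(x$mask)))
  invisible(x)
}

# Thin-plate spline interpolation matrix mapping values at scattered 2-D
# sites to values at query points.  Exact interpolation (no smoothing);
# reproduces affine functions, hence constants, exactly.
tps_matrix <- function(sites, query) {
  n <- nrow(sites)
  if (n < 4)
    bna_stop("bna_too_few_electrodes",
             "thin-plate interpolation needs at least 4 electrodes")
  U <- function(r2) ifelse(r2 == 0, 0, 0.5 * r2 * log(r2))  # r^2 log r
  d2 <- function(a, b) {
    outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  }
  K <- U(d2(sites, sites))
  P <- cbind(1, sites)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  Ainv <- tryCatch(solve(A),
                   error = function(e)
                     bna_stop("bna_degenerate_montage",
                              "electrode positions are collinear; spline underdetermined"))
  B <- cbind(U(d2(query, sites)), 1, query)  # m x (n + 3)
  B %*% Ainv[, seq_len(n), drop = FALSE]     # m x n
}

#' Interpolate band-limited channel data onto the scalp grid
#'
#' For each band and each time sample, fits a thin-plate spline surface
#' through the projected electrode values and evaluates it at every masked
#' pixel, yielding one 3-D amplitude volume (left-right x
#' anterior-posterior x time) per band.  Pixels outside the head mask are
#' set to `NA`.
#'
#' @param band_mats named list of channels x time matrices (one per band),
#'   as returned by [bandpass_decompose()].
#' @param m a projected [montage()] (`pos2d` filled).
#' @param geometry a [grid_geometry()].
#' @param times_ms time axis of the matrices.
#' @return Named list of `bna_volume` objects.
#' @export
interpolate_grid <- function(band_mats, m, geometry = grid_geometry(),
                             times_ms) {
  stopifnot(inherits(m, "bna_montage"), inherits(geometry, "bna_geometry"))
  if (is.null(m$pos2d))
    bna_stop("bna_montage_unprojected", "montage must be projected first")
  masked <- which(geometry$mask)
  px <- cbind(geometry$u[(masked - 1) %% geometry$n_lr + 1],
              geometry$v[(masked - 1) %/% geometry$n_lr + 1])
  W <- tps_matrix(m$pos2d, px)
  lapply_named(band_mats, function(band, mat) {
    if (nrow(mat) != nrow(m$pos2d))
      bna_stop("bna_shape_mismatch",
               "channel count does not match montage electrode count")
    n_t <- ncol(mat)
    vol <- array(NA_real_, dim = c(geometry$n_lr, geometry$n_ap, n_t))
    vals <- W %*% mat                      # masked pixels x time
    idx <- rep(masked, n_t) +
      rep((seq_len(n_t) - 1) * geometry$n_lr * geometry$n_ap, each = length(masked))
    vol[idx] <- vals
    band_volume(band, vol, times_ms, geometry)
  })
}

lapply_named <- function(x, f) {
  out <- lapply(names(x), function(nm) f(nm, x[[nm]]))
  names(out) <- names(x)
  out
}

#' Band volume container
#'
#' @param band band name.
#' @param data 3-D array (left-right x anterior-posterior x time), `NA`
#'   outside the head mask.
#' @param times_ms time axis.
#' @param geometry a [grid_geometry()].
#' @export
band_volume <- function(band, data, times_ms, geometry) {
  stopifnot(length(dim(data)) == 3,
            dim(data)[1] == geometry$n_lr, dim(data)[2] == geometry$n_ap,
            dim(data)[3] == length(times_ms))
  structure(list(band = band, data = data, times_ms = as.numeric(times_ms),
                 geometry = geometry),
            class = "bna_volume")
}

#' @export
print.bna_volume <- function(x, ...) {
  cat(sprintf("<bna_volume> band %s, %d x %d x %d\n", x$band,
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3]))
  invisible(x)
}
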