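#' Electrode montages
#'
#' A montage holds electrode labels, their 3-D head positions and (after
#' [project_montage()]) 2-D grid-fraction positions used for scalp-map
#' interpolation.
#'
#' @param labels character vector of unique electrode names.
#' @param pos3d numeric matrix, one row per electrode, columns x (left-right),
#'   y (posterior-anterior), z (inferior-superior), arbitrary head units.
#' @param pos2d optional numeric matrix of projected (u, v) positions in
#'   grid-fraction coordinates on `[0, 1]^2`.
#' @return An object of class `bna_montage`.
#' @export
montage <- function(labels, pos3d, pos2d = NULL) {
  labels <- as.character(labels)
  pos3d <- as.matrix(pos3d)
  if (anyDuplicated(labels))
    bna_stop("bna_duplicate_label",
             sprintf("duplicate electrode label(s): %s",
                     paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  if (length(labels) < 3)
    bna_stop("bna_too_few_electrodes", "a montage needs at least 3 electrodes")
  if (nrow(pos3d) != length(labels) || ncol(pos3d) != 3)
    bna_stop("bna_bad_positions", "pos3d must be an n x 3 matrix matching labels")
  if (!all(is.finite(pos3d)))
    bna_stop("bna_bad_positions", "pos3d contains non-finite coordinates")
  dimnames(pos3d) <- list(labels, c("x", "y", "z"))
  m <- structure(list(labels = labels, pos3d = pos3d, pos2d = NULL),
                 class = "bna_montage")
  if (!is.null(pos2d)) {
    pos2d <- as.matrix(pos2d)
    stopifnot(nrow(pos2d) == length(labels), ncol(pos2d) == 2)
    dimnames(pos2d) <- list(labels, c("u", "v"))
    m$pos2d <- pos2d
  }
  m
}

#' @export
print.bna_montage <- function(x, ...) {
  cat(sprintf("<bna_montage> %d electrodes (%s ...), pos2d %s\n",
              length(x$labels), paste(head(x$labels, 4), collapse = ", "),
              if (is.null(x$pos2d)) "unset" else "set"))
  invisible(x)
}

#' Read an electrode montage from an sfp-style text file
#'
#' Each line is `label x y z`, whitespace separated, one electrode per line.
#' File order is preserved; projected 2-D positions are left unset.
#'
#' @param path path to the montage file.
#' @return A [montage()] object with `pos2d` unset.
#' @export
read_montage <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 3)
    bna_stop("bna_too_few_electrodes",
             sprintf("montage file '%s' has fewer than 3 electrodes", path))
  parts <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(parts) != 4))
    bna_stop("bna_parse_error",
             sprintf("montage file '%s': every line must be 'label x y z'", path))
  labels <- vapply(parts, `[[`, "", 1L)
  coords <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))), ncol = 3, byrow = TRUE))
  if (anyNA(coords))
    bna_stop("bna_parse_error",
             sprintf("montage file '%s': non-numeric coordinate", path))
  montage(labels, coords)
}

#' Write a montage to an sfp-style text file
#'
#' @param m a [montage()] object.
#' @param path output path.
#' @export
write_montage <- function(m, path) {
  stopifnot(inherits(m, "bna_montage"))
  writeLines(sprintf("%s\t%.6f\t%.6f\t%.6f",
                     m$labels, m$pos3d[, 1], m$pos3d[, 2], m$pos3d[, 3]),
             path)
  invisible(path)
}

#' Project 3-D electrode positions onto the 2-D scalp grid
#'
#' Uses an azimuthal-equidistant projection about the vertex (the +z axis
#' after centring the positions on their centroid): an electrode at arc
#' angle \eqn{\gamma} from the vertex maps to radius \eqn{\gamma} along its
#' azimuth.  The projection is rescaled isotropically so all electrodes fall
#' inside `[0, 1]^2` with the vertex at (0.5, 0.5); left-right and
#' anterior-posterior orientation is preserved.
#'
#' @param m a [montage()] object; positions should lie on or near a
#'   head-centred sphere (radial sd/mean < 0.2 after centring).
#' @param margin fraction of the half-grid kept free around the outermost
#'   electrode (default 0.1, i.e. electrodes span radius 0.45).
#' @return The montage with `pos2d` filled.
#' @export
project_montage <- function(m, margin = 0.1) {
  stopifnot(inherits(m, "bna_montage"))
  p <- sweep(m$pos3d, 2, colMeans(m$pos3d))
  r <- sqrt(rowSums(p^2))
  if (any(r < .Machine$double.eps * 100))
    bna_stop("bna_degenerate_montage", "electrode at the centroid; cannot project")
  if (stats::sd(r) / mean(r) > 0.2)
    bna_stop("bna_degenerate_montage",
             "positions are not approximately spherical about their centroid")
  # arc angle from vertex (+z), azimuthal direction from (x, y)
  gamma <- acos(pmin(1, pmax(-1, p[, 3] / r)))
  rho_xy <- sqrt(p[, 1]^2 + p[, 2]^2)
  ux <- ifelse(rho_xy > 0, p[, 1] / rho_xy, 0)
  uy <- ifelse(rho_xy > 0, p[, 2] / rho_xy, 0)
  px <- gamma * ux
  py <- gamma * uy
  rmax <- max(sqrt(px^2 + py^2))
  if (rmax <= 0)
    bna_stop("bna_degenerate_montage", "all electrodes at the vertex")
  s <- (0.5 - margin / 2) / rmax
  # u: left-right, v: anterior(-y 0) -> posterior(+1); flip so that +y
  # (anterior) maps to small v, matching scalp-map convention (nose up).
  pos2d <- cbind(u = 0.5 + s * px, v = 0.5 - s * py)
  rownames(pos2d) <- m$labels
  m$pos2d <- pos2d
  m
}

#' Synthetic spherical-cap montage
#'
#' Builds a deterministic, roughly 10-20-like electrode layout on a unit
#' sphere: a vertex electrode plus concentric rings down to the equator.
#' This is a synthetic stand-in for a recorded digitised montage, intended
#' for simulation and testing.
#'
#' @param n_per_ring integer vector: electrode count per ring, first entry
#'   must be 1 (the vertex).  Default gives 32 electrodes.
#' @return A projected [montage()] (with `pos2d` filled).
#' @export
demo_montage <- function(n_per_ring = c(1, 6, 12, 13)) {
  stopifnot(n_per_ring[1] == 1)
  polar <- seq(0, pi / 2, length.out = length(n_per_ring))
  pos <- NULL
  for (i in seq_along(n_per_ring)) {
    n <- n_per_ring[i]
    if (n == 1) {
      pos <- rbind(pos, c(0, 0, 1))
    } else {
      az <- 2 * pi * (seq_len(n) - 1) / n + pi / 2  # start at anterior midline
      pos <- rbind(pos, cbind(sin(polar[i]) * cos(az),
                              sin(polar[i]) * sin(az),
                              rep(cos(polar[i]), n)))
    }
  }
  labels <- sprintf("E%02d", seq_len(nrow(pos)))
  project_montage(montage(labels, pos))
}
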