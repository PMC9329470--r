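#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed (restores the caller's RNG state)
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  withr::with_seed(as.integer(seed), code)
}

#' Nearest-neighbour resize of a 2-D matrix
#' @noRd
resize_nn <- function(img, nr, nc) {
  stopifnot(nr >= 1, nc >= 1)
  ri <- floor((seq_len(nr) - 0.5) * nrow(img) / nr) + 1L
  ci <- floor((seq_len(nc) - 0.5) * ncol(img) / nc) + 1L
  img[pmin(ri, nrow(img)), pmin(ci, ncol(img)), drop = FALSE]
}

#' Stable small content hash (polynomial rolling hash of the serialization)
#' @noRd
object_hash <- function(x) {
  raw <- as.double(serialize(x, NULL, version = 2))
  m <- 2147483647  # 2^31 - 1; doubles stay exact throughout
  h <- 17
  for (chunk in split(raw, ceiling(seq_along(raw) / 2048))) {
    h <- (h * 31 + sum(chunk * (seq_along(chunk) %% 97 + 1))) %% m
  }
  sprintf("%08x", h)
}

#' Ramanujan approximation to the perimeter of an ellipse with semi-axes a, b
#' @noRd
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' 3x3 weighted box smoothing (anti-aliasing) of a binary mask
#' @noRd
.smooth_mask <- function(m, passes = 2) {
  m <- m * 1
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(passes)) {
    p <- rbind(0, cbind(0, m, 0), 0)
    m <- (p[2:(nr + 1), 2:(nc + 1)] * 4 +
            p[1:nr, 2:(nc + 1)] + p[3:(nr + 2), 2:(nc + 1)] +
            p[2:(nr + 1), 1:nc] + p[2:(nr + 1), 3:(nc + 2)] +
            p[1:nr, 1:nc] + p[1:nr, 3:(nc + 2)] +
            p[3:(nr + 2), 1:nc] + p[3:(nr + 2), 3:(nc + 2)]) / 12
  }
  m
}

#' Perimeter of the longest closed contour of a binary slice, in mm
#'
#' The mask is anti-aliased with two 3x3 box-smoothing passes (sub-pixel
#' boundary recovery; a raw binary mask inflates marching-squares
#' perimeters by ~6% through staircasing), then iso-level 0.5 contours are
#' extracted with marching squares (\code{grDevices::contourLines}) on the
#' physical coordinate grid; returns the length of the longest polygon.
#' @noRd
contour_perimeter <- function(mask, spacing_yx) {
  storage.mode(mask) <- "double"
  mask <- .smooth_mask(mask)
  ny <- nrow(mask); nx <- ncol(mask)
  # pad so contours close around border-touching bodies
  m <- matrix(0, ny + 2, nx + 2)
  m[2:(ny + 1), 2:(nx + 1)] <- mask
  yy <- (seq_len(ny + 2) - 1.5) * spacing_yx[1]
  xx <- (seq_len(nx + 2) - 1.5) * spacing_yx[2]
  cl <- grDevices::contourLines(yy, xx, m, levels = 0.5)
  if (!length(cl)) return(0)
  per <- vapply(cl, function(cc) {
    dx <- diff(c(cc$x, cc$x[1])); dy <- diff(c(cc$y, cc$y[1]))
    sum(sqrt(dx^2 + dy^2))
  }, numeric(1))
  max(per)
}

#' Check that a matrix/array is binary (all values 0 or 1)
#' @noRd
is_binary <- function(x) {
  all(x == 0 | x == 1)
}

#' Package pipeline version string used in provenance records
#' @noRd
silfat_version <- function() {
  paste0("silfat-", as.character(utils::packageVersion("silfat")))
}
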