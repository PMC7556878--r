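# Discrete Radon transform and filtered back-projection.
#
# These primitives back both vessel cross-section segmentation (TiRS) and
# linescan velocimetry, so they are implemented here rather than delegated:
# no installed R package provides a 2-D Radon/inverse-Radon pair.

#' Discrete Radon transform
#'
#' Projects a 2-D image onto a set of axes. For angle theta (degrees), each
#' pixel at centered coordinates (x = col - cx, y = row - cy) contributes its
#' intensity to the bin at t = x cos(theta) + y sin(theta), split linearly
#' between the two adjacent unit-width bins (bilinear splatting). This is the
#' standard discrete approximation used in tomography.
#'
#' @param im numeric matrix (rows = y, columns = x).
#' @param angles_deg projection angles in degrees.
#' @return list with `sinogram` (bins x angles matrix), `t` (bin centers in
#'   pixels, 0 at the image center) and `angles_deg`.
#' @export
radon_transform <- function(im, angles_deg) {
  stopifnot(is.matrix(im), length(angles_deg) >= 1)
  nr <- nrow(im); nc <- ncol(im)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  x <- rep(seq_len(nc), each = nr) - cx
  y <- rep(seq_len(nr), times = nc) - cy
  v <- as.numeric(im)
  half <- ceiling(sqrt((nr / 2)^2 + (nc / 2)^2)) + 1L
  tc <- seq.int(-half, half)                  # bin centers
  nt <- length(tc)
  sino <- matrix(0, nt, length(angles_deg))
  for (k in seq_along(angles_deg)) {
    th <- angles_deg[k] * pi / 180
    t <- x * cos(th) + y * sin(th)
    idx <- t + half + 1                       # fractional bin index
    i0 <- floor(idx)
    fr <- idx - i0
    agg <- rowsum(c(v * (1 - fr), v * fr), c(i0, i0 + 1L))
    p <- numeric(nt)
    ii <- as.integer(rownames(agg))
    ok <- ii >= 1L & ii <= nt
    p[ii[ok]] <- agg[ok, 1]
    sino[, k] <- p
  }
  list(sinogram = sino, t = tc, angles_deg = angles_deg)
}

#' Filtered back-projection (inverse Radon transform)
#'
#' Reconstructs an image from a sinogram using the Ram-Lak (ramp) filter
#' applied in the frequency domain, followed by back-projection with linear
#' interpolation. The output scale is arbitrary up to a constant, which is
#' irrelevant for threshold-at-fraction-of-maximum segmentation.
#'
#' @param sino bins x angles sinogram matrix.
#' @param t bin centers (pixels, 0 at image center).
#' @param angles_deg projection angles, degrees.
#' @param dim output image size `c(nrow, ncol)`.
#' @param filter `"hann"` (Hann-apodized ramp, default -- suppresses the
#'   noise amplification of the pure ramp) or `"ramp"` (Ram-Lak).
#' @return reconstructed matrix of size `dim`.
#' @export
iradon_fbp <- function(sino, t, angles_deg, dim,
                       filter = c("hann", "ramp")) {
  filter <- match.arg(filter)
  nt <- nrow(sino)
  nfft <- 2 * nextn(nt, 2)
  f <- c(seq(0, nfft / 2), seq(nfft / 2 - 1, 1)) / nfft  # |freq|
  ramp <- f
  if (filter == "hann") ramp <- f * (0.5 + 0.5 * cos(pi * f / max(f)))
  filt <- apply(sino, 2, function(p) {
    P <- fft(c(p, rep(0, nfft - nt)))
    Re(fft(P * ramp, inverse = TRUE))[seq_len(nt)] / nfft
  })
  nr <- dim[1]; nc <- dim[2]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  x <- rep(seq_len(nc), each = nr) - cx
  y <- rep(seq_len(nr), times = nc) - cy
  acc <- numeric(nr * nc)
  t0 <- t[1]
  for (k in seq_along(angles_deg)) {
    th <- angles_deg[k] * pi / 180
    tt <- x * cos(th) + y * sin(th)
    idx <- tt - t0 + 1
    i0 <- pmin(pmax(floor(idx), 1L), nt - 1L)
    fr <- pmin(pmax(idx - i0, 0), 1)
    acc <- acc + filt[i0, k] * (1 - fr) + filt[i0 + 1L, k] * fr
  }
  matrix(acc * pi / (2 * length(angles_deg)), nr, nc)
}
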