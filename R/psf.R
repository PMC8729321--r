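#' Point-spread-function model
#'
#' Describes the scanner resolution as an isotropic (or per-axis) Gaussian
#' kernel parameterized by its full width at half maximum. The Gaussian sigma
#' is `fwhm / (2 * sqrt(2 * log(2)))`; the discrete kernel is truncated at
#' `trunc` multiples of sigma and renormalized to unit sum.
#'
#' @param fwhm Full width at half maximum in mm; scalar (isotropic) or
#'   length-3 vector, one value per axis. Default 8 mm, a typical harmonized
#'   amyloid-PET resolution.
#' @param trunc Kernel truncation radius in multiples of sigma (default 4).
#' @return An object of class `psf_model`.
#' @export
psf_model <- function(fwhm = 8, trunc = 4) {
  if (any(fwhm <= 0)) stop("PSF fwhm must be positive")
  if (!(length(fwhm) %in% c(1L, 3L))) stop("fwhm must have length 1 or 3")
  if (trunc <= 0) stop("trunc must be positive")
  structure(list(fwhm = fwhm, trunc = trunc,
                 sigma = fwhm / (2 * sqrt(2 * log(2)))),
            class = "psf_model")
}

#' @export
print.psf_model <- function(x, ...) {
  cat("Gaussian PSF: FWHM", paste(format(x$fwhm), collapse = " x "),
      "mm (sigma", paste(format(round(x$sigma, 3)), collapse = " x "),
      "mm), truncated at", x$trunc, "sigma\n")
  invisible(x)
}

## Discrete 1-D Gaussian kernel in voxel units, unit sum.
gauss_kernel_1d <- function(fwhm_mm, voxel_mm, trunc = 4) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  r <- max(1L, as.integer(ceiling(trunc * sigma)))
  k <- stats::dnorm(seq.int(-r, r), sd = sigma)
  k / sum(k)
}

## Banded convolution matrix for a zero-padded 1-D convolution of length n.
conv_band_matrix <- function(n, kern) {
  r <- (length(kern) - 1L) %/% 2L
  B <- matrix(0, n, n)
  for (off in -r:r) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1L & j <= n
    B[cbind(i[ok], j[ok])] <- kern[off + r + 1L]
  }
  B
}

## Convolve along the first axis of a 3-D array via the band matrix.
conv_axis1 <- function(a, kern) {
  d <- dim(a)
  B <- conv_band_matrix(d[1L], kern)
  array(B %*% matrix(a, d[1L]), dim = d)
}

#' Separable Gaussian smoothing of a 3-D volume
#'
#' Applies the PSF as a separable, zero-padded Gaussian convolution along each
#' axis. This is a linear operator; constants are preserved in the deep
#' interior (further than the truncation radius from any edge), and the
#' kernel is normalized so that total activity of an interior point source is
#' preserved.
#'
#' @param volume Numeric 3-D array, finite everywhere.
#' @param psf A [psf_model], or a numeric FWHM in mm.
#' @param voxel_size Voxel edge length in mm (isotropic).
#' @return Smoothed array of the same dimensions.
#' @export
smooth_psf <- function(volume, psf, voxel_size) {
  if (!is.array(volume) || length(dim(volume)) != 3L)
    stop("volume must be a 3-D array")
  if (!all(is.finite(volume))) stop("volume must be finite everywhere")
  if (!inherits(psf, "psf_model")) psf <- psf_model(psf)
  fwhm <- rep(psf$fwhm, length.out = 3L)
  out <- volume
  for (ax in 1:3) {
    kern <- gauss_kernel_1d(fwhm[ax], voxel_size, psf$trunc)
    ## rotate axes so the target axis is first
    out <- aperm(conv_axis1(aperm(out, c(ax, setdiff(1:3, ax))), kern),
                 order(c(ax, setdiff(1:3, ax))))
  }
  out
}

#' Binary erosion of a mask by a metric ball
#'
#' A voxel survives only if every voxel within `radius_mm` (Euclidean, voxel
#' centers) lies inside the mask. Used to isolate deep white matter from
#' GM-adjacent voxels before estimating the WM activity.
#'
#' @param mask Logical (or 0/1) 3-D array.
#' @param radius_mm Erosion radius in mm.
#' @param voxel_size Voxel edge length in mm.
#' @return Logical array of the same dimensions.
#' @export
erode_mask <- function(mask, radius_mm, voxel_size) {
  m <- array(as.logical(mask), dim = dim(mask))
  if (radius_mm <= 0) return(m)
  r <- floor(radius_mm / voxel_size)
  ## a ball of radius r voxels cannot fit if the mask's bounding box is
  ## narrower than its diameter along any axis
  if (!any(m)) return(m)
  bb <- apply(which(m, arr.ind = TRUE), 2, range)
  if (any(bb[2, ] - bb[1, ] + 1 < 2 * r + 1))
    return(array(FALSE, dim = dim(m)))
  offs <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  offs <- offs[(offs$dx^2 + offs$dy^2 + offs$dz^2) * voxel_size^2 <=
                 radius_mm^2 + 1e-9, , drop = FALSE]
  out <- m
  for (i in seq_len(nrow(offs))) {
    out <- out & shift_array(m, c(offs$dx[i], offs$dy[i], offs$dz[i]))
  }
  out
}

## Integer shift of a 3-D array, filling with `fill` (shift of +1 along an
## axis moves content toward higher indices).
shift_array <- function(a, by, fill = FALSE) {
  d <- dim(a)
  idx <- lapply(1:3, function(ax) {
    i <- seq_len(d[ax]) - by[ax]
    ifelse(i >= 1L & i <= d[ax], i, NA_integer_)
  })
  out <- a[cbind(rep(idx[[1]], times = d[2] * d[3]),
                 rep(rep(idx[[2]], each = d[1]), times = d[3]),
                 rep(idx[[3]], each = d[1] * d[2]))]
  out[is.na(out)] <- fill
  array(out, dim = d)
}
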