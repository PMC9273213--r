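## Projection and background correction: every measurement downstream uses a
## single background-corrected 2D image per channel.

#' Average-intensity z-projection
#'
#' Per-pixel arithmetic mean across focal planes. A single plane (matrix or
#' one-plane array) is returned unchanged.
#'
#' @param stack A `height x width` matrix, a `height x width x n_z` array, or
#'   a list of equal-shape matrices.
#' @return A matrix.
#' @export
average_projection <- function(stack) {
  if (is.matrix(stack)) return(stack)
  if (is.list(stack)) {
    if (length(stack) == 0) abort("empty stack", class = "mitoloc_input_error")
    dims <- lapply(stack, dim)
    same <- vapply(dims, identical, TRUE, dims[[1]])
    if (!all(same))
      abort(sprintf("plane shape mismatch: %s vs %s",
                    paste(dims[[1]], collapse = "x"),
                    paste(dims[[which(!same)[1]]], collapse = "x")),
            class = "mitoloc_input_error")
    stack <- array(unlist(stack), dim = c(dims[[1]], length(stack)))
  }
  d <- dim(stack)
  if (is.null(d) || length(d) != 3)
    abort("stack must be a matrix or a 3-d array", class = "mitoloc_input_error")
  if (d[3] < 1) abort("empty stack", class = "mitoloc_input_error")
  out <- rowMeans(stack, dims = 2)
  matrix(out, d[1], d[2])
}

#' Background correction
#'
#' Subtracts an estimate of the smooth background and clips at zero. Two
#' estimators:
#' \describe{
#'   \item{`"opening"`}{grayscale morphological opening with a disc larger
#'     than any cell (rolling-ball style). For speed the opening runs on a
#'     block-downsampled copy (factor `downsample`) with a proportionally
#'     smaller disc, and the background is resized back; the approximation is
#'     well below the noise floor for smooth backgrounds.}
#'   \item{`"polynomial"`}{least-squares fit of a low-order 2D polynomial
#'     surface to the below-median pixels (so cells, which are bright and
#'     sparse, do not pull the fit).}
#' }
#'
#' @param image Nonnegative numeric matrix.
#' @param method `"opening"` or `"polynomial"`.
#' @param radius_px Disc radius for the opening method (must fit the image).
#' @param poly_order Polynomial order (<= 3) for the polynomial method.
#' @param downsample Downsampling factor for the opening method.
#' @return Corrected image, same shape, all values >= 0.
#' @export
#' @examples
#' img <- outer(1:64, 1:64, function(r, c) 10 + 0.1 * c)
#' max(abs(correct_background(img, "polynomial", poly_order = 1)))
correct_background <- function(image, method = c("opening", "polynomial"),
                               radius_px = 50, poly_order = 2,
                               downsample = 4) {
  method <- match.arg(method)
  if (!is.matrix(image)) abort("image must be a matrix",
                               class = "mitoloc_input_error")
  if (any(image < 0)) abort("image must be nonnegative",
                            class = "mitoloc_input_error")
  bg <- switch(method,
    opening = {
      if (2 * radius_px + 1 > min(dim(image)))
        abort("structuring element larger than image",
              class = "mitoloc_input_error")
      s <- max(1L, as.integer(downsample))
      if (s > 1L && all(dim(image) >= 16 * s)) {
        small <- EBImage::resize(image, w = nrow(image) %/% s,
                                 h = ncol(image) %/% s)
        r <- max(1L, round(radius_px / s))
        op <- EBImage::opening(small, EBImage::makeBrush(2L * r + 1L, "disc"))
        b <- EBImage::resize(op, w = nrow(image), h = ncol(image))
        as.matrix(b)
      } else {
        as.matrix(EBImage::opening(image,
          EBImage::makeBrush(2L * as.integer(radius_px) + 1L, "disc")))
      }
    },
    polynomial = {
      if (poly_order > 3) abort("polynomial order must be <= 3",
                                class = "mitoloc_input_error")
      fit_background_poly(image, poly_order)
    })
  pmax(image - bg, 0)
}

## Low-order polynomial surface fit to below-median pixels (subsampled for
## speed on large fields).
fit_background_poly <- function(image, order) {
  h <- nrow(image); w <- ncol(image)
  ys <- (row(image) - 1) / max(1, h - 1)
  xs <- (col(image) - 1) / max(1, w - 1)
  med <- stats::median(image)
  sel <- which(image <= med)
  if (length(sel) < 16) sel <- seq_along(image)
  if (length(sel) > 20000) sel <- sel[seq(1, length(sel), length.out = 20000)]
  basis <- function(x, y) {
    cols <- list(rep(1, length(x)))
    for (d in seq_len(order))
      for (i in 0:d) cols[[length(cols) + 1L]] <- x^(d - i) * y^i
    do.call(cbind, cols)
  }
  X <- basis(xs[sel], ys[sel])
  beta <- qr.coef(qr(X), image[sel])
  beta[is.na(beta)] <- 0
  Xfull <- basis(as.vector(xs), as.vector(ys))
  matrix(Xfull %*% beta, h, w)
}

#' Project and background-correct every channel of a field
#'
#' @param field A `field_stack`.
#' @param method,radius_px,poly_order Passed to [correct_background()].
#' @return The field with each channel replaced by its corrected 2D image.
#' @export
preprocess_field <- function(field, method = "opening", radius_px = 50,
                             poly_order = 2) {
  field$channels <- lapply(field$channels, function(ch)
    correct_background(average_projection(ch), method = method,
                       radius_px = radius_px, poly_order = poly_order))
  field
}
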