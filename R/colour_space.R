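#' @title Colour-space conversions: CIE xyY, XYZ, Lab and LCh
#'
#' @description
#' The analysis currency of this package is CIE LCh, the cylindrical form of
#' CIE 1976 L*a*b*.  Colour records enter the pipeline either as measured
#' CIE xyY (chromaticity + luminance, the preferred route) or as device RGB
#' values pushed through a parameterised display model.  All conversions are
#' vectorised over their numeric arguments and return data frames.
#'
#' The reference white is always an explicit argument: it is the tristimulus
#' of the white background against which colour patches are presented, and
#' no hidden default is applied inside the conversion functions themselves.
#'
#' @name colour_space
NULL

# CIE 1976 threshold (6/29)^3 for the cube-root/linear branch
.lab_delta3 <- (6 / 29)^3

.lab_f <- function(t) {
  ifelse(t > .lab_delta3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
}

.lab_finv <- function(t) {
  ifelse(t > 6 / 29, t^3, 3 * (6 / 29)^2 * (t - 4 / 29))
}

#' Convert CIE xyY to XYZ tristimulus values
#'
#' @param x,y Chromaticity coordinates, each in `[0, 1]` with `x + y <= 1`.
#' @param Y Luminance (cd/m^2 or any fixed scale), `>= 0`.
#'
#' @details `X = x Y / y` and `Z = (1 - x - y) Y / y`.  A colour with zero
#' luminance maps to `(0, 0, 0)` regardless of chromaticity; `y = 0` with
#' positive luminance has no defined chromaticity and is an error.
#'
#' @return A data frame with columns `X`, `Y`, `Z`.
#' @examples
#' xyY_to_XYZ(1 / 3, 1 / 3, 100) # equal-energy white: X = Y = Z
#' @export
xyY_to_XYZ <- function(x, y, Y) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(Y))
  n <- max(length(x), length(y), length(Y))
  x <- rep_len(x, n); y <- rep_len(y, n); Y <- rep_len(Y, n)
  if (any(!is.finite(x) | !is.finite(y) | !is.finite(Y))) {
    stop("non-finite xyY input")
  }
  if (any(x < 0 | y < 0 | x + y > 1 + 1e-12 | Y < 0)) {
    stop("invalid chromaticity: need x >= 0, y >= 0, x + y <= 1, Y >= 0")
  }
  bad <- y == 0 & Y > 0
  if (any(bad)) {
    stop("undefined chromaticity: y = 0 with positive luminance")
  }
  zero <- Y == 0
  X <- Z <- numeric(n)
  X[!zero] <- x[!zero] * Y[!zero] / y[!zero]
  Z[!zero] <- (1 - x[!zero] - y[!zero]) * Y[!zero] / y[!zero]
  Yout <- Y
  Yout[zero] <- 0
  data.frame(X = X, Y = Yout, Z = Z)
}

#' Convert XYZ tristimulus values to CIE 1976 L*a*b*
#'
#' @param X,Y,Z Tristimulus values, `>= 0`, on the same scale as `white`.
#' @param white Reference white tristimulus, numeric length 3 `(Xn, Yn, Zn)`
#'   with `Yn > 0`.  In this pipeline the white is the picker's white
#'   background, measured per display.
#'
#' @details Standard CIE 1976 transform with the cube-root/linear branch at
#' ratio `(6/29)^3`.  The white itself maps exactly to `(L = 100, a = 0,
#' b = 0)` and black to `(0, 0, 0)`.
#'
#' @return A data frame with columns `L`, `a`, `b`.
#' @export
XYZ_to_Lab <- function(X, Y, Z, white) {
  stopifnot(is.numeric(white), length(white) == 3)
  if (any(!is.finite(white)) || white[2] <= 0) {
    stop("reference white must be finite with Y > 0")
  }
  n <- max(length(X), length(Y), length(Z))
  X <- rep_len(X, n); Y <- rep_len(Y, n); Z <- rep_len(Z, n)
  if (any(!is.finite(X) | !is.finite(Y) | !is.finite(Z))) {
    stop("non-finite XYZ input")
  }
  if (any(X < 0 | Y < 0 | Z < 0)) stop("XYZ components must be >= 0")
  fx <- .lab_f(X / white[1])
  fy <- .lab_f(Y / white[2])
  fz <- .lab_f(Z / white[3])
  data.frame(
    L = 116 * fy - 16,
    a = 500 * (fx - fy),
    b = 200 * (fy - fz)
  )
}

#' Convert CIE Lab to XYZ under a reference white
#'
#' Inverse of [XYZ_to_Lab()]; used when rendering analysis colours back to
#' device RGB.
#'
#' @inheritParams XYZ_to_Lab
#' @param L,a,b CIE Lab coordinates.
#' @return A data frame with columns `X`, `Y`, `Z`.
#' @export
Lab_to_XYZ <- function(L, a, b, white) {
  stopifnot(is.numeric(white), length(white) == 3)
  if (white[2] <= 0) stop("reference white must have Y > 0")
  n <- max(length(L), length(a), length(b))
  L <- rep_len(L, n); a <- rep_len(a, n); b <- rep_len(b, n)
  fy <- (L + 16) / 116
  fx <- fy + a / 500
  fz <- fy - b / 200
  data.frame(
    X = white[1] * .lab_finv(fx),
    Y = white[2] * .lab_finv(fy),
    Z = white[3] * .lab_finv(fz)
  )
}

#' Convert CIE Lab to cylindrical LCh
#'
#' @param L,a,b CIE Lab coordinates.
#'
#' @details `C = sqrt(a^2 + b^2)`; `h = atan2(b, a)` in degrees, mapped to
#' the half-open interval `[0, 360)`.  Achromatic colours (`a = b = 0`) get
#' `h = 0` by convention; downstream hue categorisation never consults the
#' hue angle at or below the achromatic chroma cut-off, so the convention is
#' inert.
#'
#' @return A data frame with columns `L`, `C`, `h`.
#' @examples
#' Lab_to_LCh(50, 3, 4) # C = 5, h = atan2(4, 3) ~ 53.13 degrees
#' @export
Lab_to_LCh <- function(L, a, b) {
  n <- max(length(L), length(a), length(b))
  L <- rep_len(L, n); a <- rep_len(a, n); b <- rep_len(b, n)
  C <- sqrt(a^2 + b^2)
  h <- (atan2(b, a) * 180 / pi) %% 360
  h[C == 0] <- 0
  data.frame(L = L, C = C, h = h)
}

#' Convert cylindrical LCh back to CIE Lab
#'
#' @param L,C,h Lightness, chroma and hue angle (degrees).
#' @return A data frame with columns `L`, `a`, `b`.
#' @export
LCh_to_Lab <- function(L, C, h) {
  n <- max(length(L), length(C), length(h))
  L <- rep_len(L, n); C <- rep_len(C, n); h <- rep_len(h, n)
  data.frame(
    L = L,
    a = C * cos(h * pi / 180),
    b = C * sin(h * pi / 180)
  )
}

#' Display model: device RGB to XYZ
#'
#' A display model captures the additive RGB-to-XYZ mapping of a monitor:
#' the chromaticities of its three primaries, its white point, and the
#' electro-optical transfer function.  In the original experimental setting
#' every final colour was physically measured with a chroma meter; when such
#' measurements are unavailable, the model provides a deterministic,
#' configurable approximation (and the pipeline flags colours converted
#' through it).
#'
#' @param red,green,blue Chromaticities `c(x, y)` of the primaries.
#' @param white White point, either a chromaticity `c(x, y)` or a
#'   tristimulus `c(X, Y, Z)` on the `Y = 100` scale.
#' @param gamma Transfer function: the string `"srgb"` for the piecewise
#'   sRGB curve, or a single numeric exponent (e.g. 2.2 for a pure-power
#'   CRT-style curve).
#'
#' @return An object of class `display_model` with elements `M` (3 x 3
#'   RGB-to-XYZ matrix on the `Y = 100` scale), `white` (tristimulus,
#'   `Y = 100`), and `gamma`.
#' @examples
#' m <- default_display_model()
#' rgb_to_XYZ(255, 255, 255, m) # exactly the model white point
#' @export
display_model <- function(red = c(0.64, 0.33), green = c(0.30, 0.60),
                          blue = c(0.15, 0.06), white = c(0.3127, 0.3290),
                          gamma = "srgb") {
  stopifnot(length(red) == 2, length(green) == 2, length(blue) == 2)
  if (!(identical(gamma, "srgb") ||
        (is.numeric(gamma) && length(gamma) == 1 && gamma > 0))) {
    stop("gamma must be \"srgb\" or a single positive number")
  }
  xy_to_col <- function(p) c(p[1] / p[2], 1, (1 - p[1] - p[2]) / p[2])
  P <- cbind(xy_to_col(red), xy_to_col(green), xy_to_col(blue))
  W <- if (length(white) == 2) {
    xy_to_col(white)
  } else if (length(white) == 3) {
    white / white[2]
  } else {
    stop("white must be a chromaticity (length 2) or tristimulus (length 3)")
  }
  if (W[2] <= 0) stop("white point must have positive luminance")
  M <- P %*% diag(drop(solve(P, W)))
  structure(
    list(M = M * 100, white = W * 100, gamma = gamma,
         primaries = list(red = red, green = green, blue = blue)),
    class = "display_model"
  )
}

#' @rdname display_model
#' @details `default_display_model()` is an sRGB monitor: IEC 61966-2-1
#'   primaries, D65 white point, piecewise sRGB transfer function.
#' @export
default_display_model <- function() display_model()

.linearise_channel <- function(v, gamma) {
  if (identical(gamma, "srgb")) {
    ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  } else {
    v^gamma
  }
}

.encode_channel <- function(v, gamma) {
  v <- pmin(pmax(v, 0), 1)
  if (identical(gamma, "srgb")) {
    ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055)
  } else {
    v^(1 / gamma)
  }
}

#' Convert device RGB to XYZ through a display model
#'
#' @param r,g,b Channel values in `0..255`.
#' @param model A [display_model()].
#' @return A data frame with columns `X`, `Y`, `Z` on the `Y = 100` scale;
#'   `(255, 255, 255)` maps exactly to the model's white point.
#' @export
rgb_to_XYZ <- function(r, g, b, model = default_display_model()) {
  stopifnot(inherits(model, "display_model"))
  n <- max(length(r), length(g), length(b))
  r <- rep_len(r, n); g <- rep_len(g, n); b <- rep_len(b, n)
  rgb <- cbind(r, g, b)
  if (any(!is.finite(rgb)) || any(rgb < 0) || any(rgb > 255)) {
    stop("RGB channels must lie in [0, 255]")
  }
  lin <- .linearise_channel(rgb / 255, model$gamma)
  out <- lin %*% t(model$M)
  data.frame(X = out[, 1], Y = out[, 2], Z = out[, 3])
}

#' Render XYZ to device RGB through a display model
#'
#' Out-of-gamut linear channel values are clipped to `[0, 1]`; the result is
#' rounded to integer `0..255` channels.  Rendering helper only -- analysis
#' never routes through this function.
#'
#' @inheritParams rgb_to_XYZ
#' @param X,Y,Z Tristimulus values on the `Y = 100` scale.
#' @return A data frame with integer columns `r`, `g`, `b`.
#' @export
XYZ_to_rgb <- function(X, Y, Z, model = default_display_model()) {
  stopifnot(inherits(model, "display_model"))
  n <- max(length(X), length(Y), length(Z))
  xyz <- cbind(rep_len(X, n), rep_len(Y, n), rep_len(Z, n))
  lin <- xyz %*% t(solve(model$M))
  enc <- .encode_channel(lin, model$gamma)
  data.frame(
    r = as.integer(round(enc[, 1] * 255)),
    g = as.integer(round(enc[, 2] * 255)),
    b = as.integer(round(enc[, 3] * 255))
  )
}

#' Convert a colour record to CIE LCh
#'
#' Composition of the conversion chain used for every analysed colour:
#' measured xyY (preferred, when available) or device RGB through the
#' display model, then XYZ -> Lab under the reference white, then Lab ->
#' LCh.
#'
#' @param xyY Optional measured colour: numeric `c(x, y, Y)` or a 3-column
#'   matrix/data frame.
#' @param rgb Optional device colour: numeric `c(r, g, b)` in `0..255` or a
#'   3-column matrix/data frame.
#' @param white Reference white tristimulus `(Xn, Yn, Zn)`.  Defaults to the
#'   display model's white point (the white patch background).
#' @param model A [display_model()], used only for the RGB route.
#' @return A data frame with columns `L`, `C`, `h` and a `source` column
#'   (`"xyY"` or `"rgb"`) recording which route was taken.
#' @export
convert_choice <- function(xyY = NULL, rgb = NULL,
                           model = default_display_model(),
                           white = model$white) {
  as_mat <- function(v) {
    if (is.null(v)) return(NULL)
    if (is.data.frame(v)) v <- as.matrix(v)
    if (is.null(dim(v))) v <- matrix(v, ncol = 3, byrow = FALSE, nrow = 1)
    stopifnot(ncol(v) == 3)
    v
  }
  xyY <- as_mat(xyY); rgb <- as_mat(rgb)
  if (is.null(xyY) && is.null(rgb)) {
    stop("supply a colour as xyY or rgb")
  }
  if (!is.null(xyY)) {
    xyz <- xyY_to_XYZ(xyY[, 1], xyY[, 2], xyY[, 3])
    src <- "xyY"
  } else {
    xyz <- rgb_to_XYZ(rgb[, 1], rgb[, 2], rgb[, 3], model)
    src <- "rgb"
  }
  lab <- XYZ_to_Lab(xyz$X, xyz$Y, xyz$Z, white)
  out <- Lab_to_LCh(lab$L, lab$a, lab$b)
  out$source <- src
  out
}
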