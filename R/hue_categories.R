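#' Nine-category perceptual hue scheme
#'
#' The default scheme bins the hue circle into eight chromatic categories
#' plus an achromatic category for low-chroma colours.  Each chromatic
#' category is a half-open arc `[lo, hi)` of hue angles with a focal hue
#' representative; the red arc wraps through 0 degrees.  Colours whose
#' chroma is at or below the cut-off (default 5) are achromatic regardless
#' of hue and lightness.
#'
#' Boundary convention: arcs are lower-inclusive, so a hue exactly on a
#' printed shared boundary (e.g. 40 degrees between red and orange) belongs
#' to the category whose arc starts there (orange).
#'
#' @param chroma_cutoff Achromatic chroma cut-off; chroma `<=` cut-off is
#'   achromatic.
#' @return An object of class `hue_scheme`: a data frame of chromatic
#'   categories (`label`, `focal`, `lo`, `hi`) with attributes
#'   `chroma_cutoff` and `achromatic_label`.
#' @examples
#' s <- default_hue_scheme()
#' categorize_lch(L = 50, C = 50, h = 25, scheme = s) # "Red"
#' @export
default_hue_scheme <- function(chroma_cutoff = 5) {
  hue_scheme(
    data.frame(
      label = c("Red", "Orange", "Yellow", "Yellow-Green", "Green",
                "Green-Blue", "Blue", "Purple"),
      focal = c(25, 57, 87, 116, 144, 194, 244, 306),
      lo = c(346, 40, 72, 105, 130, 166, 220, 275),
      hi = c(40, 72, 105, 130, 166, 220, 275, 346),
      stringsAsFactors = FALSE
    ),
    chroma_cutoff = chroma_cutoff
  )
}

#' Construct a hue scheme from a category table
#'
#' @param categories Data frame with columns `label`, `focal`, `lo`, `hi`
#'   (degrees).  An arc with `lo > hi` wraps through 360 -> 0.
#' @param chroma_cutoff Achromatic chroma cut-off (`>= 0`).
#' @param achromatic_label Label used for at-or-below-cut-off colours.
#' @export
hue_scheme <- function(categories, chroma_cutoff = 5,
                       achromatic_label = "Achromatic") {
  stopifnot(is.data.frame(categories),
            all(c("label", "focal", "lo", "hi") %in% names(categories)))
  if (!is.numeric(chroma_cutoff) || length(chroma_cutoff) != 1 ||
      chroma_cutoff < 0) {
    stop("chroma_cutoff must be a single number >= 0")
  }
  categories$label <- as.character(categories$label)
  structure(categories,
            chroma_cutoff = chroma_cutoff,
            achromatic_label = achromatic_label,
            class = c("hue_scheme", "data.frame"))
}

#' Category labels of a hue scheme, achromatic last
#' @param scheme A `hue_scheme`.
#' @export
scheme_labels <- function(scheme) {
  stopifnot(inherits(scheme, "hue_scheme"))
  c(scheme$label, attr(scheme, "achromatic_label"))
}

.in_arc <- function(h, lo, hi) {
  if (lo < hi) h >= lo & h < hi else h >= lo | h < hi
}

#' Categorise CIE LCh colours into hue categories
#'
#' @param L,C,h Lightness, chroma and hue angle (degrees, `[0, 360)`;
#'   angles outside are reduced modulo 360).
#' @param scheme A [hue_scheme()].
#' @return A factor with levels `scheme_labels(scheme)`.  Chroma at or below
#'   the cut-off maps to the achromatic category independently of `h` and
#'   `L`; any other colour maps to the unique chromatic arc containing its
#'   hue.
#' @export
categorize_lch <- function(L, C, h, scheme = default_hue_scheme()) {
  stopifnot(inherits(scheme, "hue_scheme"))
  n <- max(length(L), length(C), length(h))
  C <- rep_len(C, n); h <- rep_len(h, n) %% 360
  if (any(!is.finite(C) | !is.finite(h)) || any(C < 0)) {
    stop("invalid LCh input")
  }
  cutoff <- attr(scheme, "chroma_cutoff")
  labels <- scheme_labels(scheme)
  out <- rep(NA_character_, n)
  out[C <= cutoff] <- attr(scheme, "achromatic_label")
  chrom <- which(C > cutoff)
  for (i in seq_len(nrow(scheme))) {
    hit <- chrom[.in_arc(h[chrom], scheme$lo[i], scheme$hi[i])]
    out[hit] <- scheme$label[i]
  }
  if (anyNA(out)) {
    stop("hue scheme does not cover hue angle(s): ",
         paste(unique(round(h[is.na(out)], 2)), collapse = ", "))
  }
  factor(out, levels = labels)
}

#' Focal hue of a chromatic category
#'
#' @param label Category label.
#' @param scheme A [hue_scheme()].
#' @return Focal hue angle in degrees.  The achromatic category has no
#'   focal hue and raises an error.
#' @export
focal_hue <- function(label, scheme = default_hue_scheme()) {
  stopifnot(inherits(scheme, "hue_scheme"))
  if (any(label == attr(scheme, "achromatic_label"))) {
    stop("the achromatic category has no focal hue")
  }
  idx <- match(label, scheme$label)
  if (anyNA(idx)) {
    stop("unknown categor", if (sum(is.na(idx)) > 1) "ies: " else "y: ",
         paste(label[is.na(idx)], collapse = ", "))
  }
  scheme$focal[idx]
}

#' Validate a hue scheme
#'
#' Checks that the chromatic arcs partition the hue circle exactly once
#' (no gaps, no overlaps, total coverage 360 degrees), that each focal hue
#' lies inside its own arc, and that the chroma cut-off is non-negative.
#'
#' @param scheme A [hue_scheme()].
#' @return A character vector of violations; empty when the scheme is valid.
#' @export
validate_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "hue_scheme"))
  bad <- character(0)
  if (attr(scheme, "chroma_cutoff") < 0) {
    bad <- c(bad, "chroma cut-off is negative")
  }
  lo <- scheme$lo %% 360
  hi <- scheme$hi %% 360
  # an upper bound that reduces to 0 means "up to the top of the circle"
  hi[hi == 0 & scheme$hi != 0] <- 360
  # unwrap each arc into non-wrapping segments on [0, 360)
  segs <- list()
  for (i in seq_len(nrow(scheme))) {
    if (lo[i] == hi[i]) {
      bad <- c(bad, sprintf("category %s has an empty or full arc",
                            scheme$label[i]))
      next
    }
    if (lo[i] < hi[i]) {
      segs[[length(segs) + 1]] <- c(lo[i], hi[i], i)
    } else {
      segs[[length(segs) + 1]] <- c(lo[i], 360, i)
      segs[[length(segs) + 1]] <- c(0, hi[i], i)
    }
  }
  if (length(segs)) {
    tol <- 1e-9
    m <- do.call(rbind, segs)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (m[1, 1] > tol) {
      bad <- c(bad, sprintf("gap between 0 and %g degrees", m[1, 1]))
    }
    for (j in seq_len(nrow(m) - 1)) {
      if (m[j, 2] > m[j + 1, 1] + tol) {
        bad <- c(bad, sprintf("overlap between %s and %s near %g degrees",
                              scheme$label[m[j, 3]], scheme$label[m[j + 1, 3]],
                              m[j + 1, 1]))
      }
      if (m[j, 2] < m[j + 1, 1] - tol) {
        bad <- c(bad, sprintf("gap between %g and %g degrees",
                              m[j, 2], m[j + 1, 1]))
      }
    }
    if (m[nrow(m), 2] < 360 - tol) {
      bad <- c(bad, sprintf("gap between %g and 360 degrees", m[nrow(m), 2]))
    }
  }
  inside <- mapply(.in_arc, scheme$focal %% 360, lo, hi)
  if (any(!inside)) {
    bad <- c(bad, sprintf("focal hue of %s lies outside its arc",
                          scheme$label[!inside]))
  }
  bad
}

#' Write a hue scheme to JSON
#' @param scheme A [hue_scheme()].
#' @param path Output file path.
#' @export
hue_scheme_to_json <- function(scheme, path) {
  stopifnot(inherits(scheme, "hue_scheme"))
  jsonlite::write_json(
    list(
      chroma_cutoff = attr(scheme, "chroma_cutoff"),
      achromatic_label = attr(scheme, "achromatic_label"),
      categories = as.data.frame(scheme)
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a hue scheme from JSON
#' @param path JSON file written by [hue_scheme_to_json()].
#' @export
hue_scheme_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  hue_scheme(x$categories, chroma_cutoff = x$chroma_cutoff,
             achromatic_label = x$achromatic_label)
}
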