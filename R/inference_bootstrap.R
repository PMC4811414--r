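#' Multiplicity-corrected pairwise significance level
#'
#' With `k` categories there are `k (k - 1) / 2` unordered pairwise
#' proportion comparisons; the family alpha is divided by `k (k - 1)` to
#' control the familywise error of the whole set.
#'
#' @param alpha Family significance level, in `(0, 1)`.
#' @param k Number of categories, `>= 2`.
#' @return The corrected level `alpha / (k (k - 1))`.
#' @examples
#' corrected_alpha(0.05, 9) # 0.05 / 72
#' @export
corrected_alpha <- function(alpha = 0.05, k = 9) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  if (!is.numeric(k) || k < 2) stop("k must be >= 2")
  alpha / (k * (k - 1))
}

#' Bootstrap pairwise comparison of category proportions
#'
#' Draws `B` multinomial resamples of size `n` from the observed category
#' frequency distribution and, for every unordered pair of categories,
#' forms a confidence interval for the difference in choice proportions
#' `p_i - p_j` at the multiplicity-corrected level.  A pair differs
#' significantly when its interval excludes zero.
#'
#' Two interval constructions are available.  `"normal"` (the default) uses
#' the bootstrap mean and standard deviation with normal quantiles at the
#' corrected level per tail; reconstruction against the published letter
#' patterns of the motivating study favours this variant (see the methods
#' vignette).  `"percentile"` takes the empirical quantiles of the
#' bootstrap distribution at the corrected level per tail.
#'
#' @param counts Named non-negative integer vector of category counts; the
#'   names are the category labels in display order.
#' @param B Number of bootstrap resamples.
#' @param alpha Family significance level.
#' @param seed Optional integer seed; results are bit-reproducible given
#'   the seed.
#' @param method Interval construction, `"normal"` or `"percentile"`.
#' @return An object of class `pairwise_boot`: a data frame with one row
#'   per unordered pair (`cat_i`, `cat_j`, observed `diff = p_i - p_j`,
#'   `lower`, `upper`, `significant`), with attributes `n`, `B`, `alpha`,
#'   `alpha_corrected`, `method`, `seed` and `labels`.
#' @export
bootstrap_pairwise <- function(counts, B = 100000L, alpha = 0.05,
                               seed = NULL,
                               method = c("normal", "percentile")) {
  method <- match.arg(method)
  if (is.null(names(counts))) {
    names(counts) <- paste0("cat", seq_along(counts))
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0) stop("empty frequency table: n = 0")
  if (B < 1) stop("B must be >= 1")
  k <- length(counts)
  ac <- corrected_alpha(alpha, k)
  if (!is.null(seed)) set.seed(seed)
  props <- stats::rmultinom(B, n, counts / n) / n
  pairs <- utils::combn(k, 2)
  rows <- vector("list", ncol(pairs))
  for (m in seq_len(ncol(pairs))) {
    i <- pairs[1, m]; j <- pairs[2, m]
    d <- props[i, ] - props[j, ]
    if (method == "normal") {
      z <- stats::qnorm(1 - ac)
      ci <- mean(d) + c(-1, 1) * z * stats::sd(d)
    } else {
      ci <- unname(stats::quantile(d, c(ac, 1 - ac)))
    }
    rows[[m]] <- data.frame(
      i = i, j = j,
      cat_i = names(counts)[i], cat_j = names(counts)[j],
      diff = (counts[[i]] - counts[[j]]) / n,
      lower = ci[1], upper = ci[2],
      significant = ci[1] > 0 || ci[2] < 0,
      stringsAsFactors = FALSE
    )
  }
  structure(do.call(rbind, rows),
            n = n, B = B, alpha = alpha, alpha_corrected = ac,
            method = method, seed = seed, labels = names(counts),
            class = c("pairwise_boot", "data.frame"))
}

#' Significance matrix of a pairwise comparison set
#'
#' @param x A `pairwise_boot` object.
#' @return Symmetric logical matrix; `TRUE` marks a significant pair.
#' @export
significance_matrix <- function(x) {
  stopifnot(inherits(x, "pairwise_boot"))
  labels <- attr(x, "labels")
  k <- length(labels)
  m <- matrix(FALSE, k, k, dimnames = list(labels, labels))
  for (r in seq_len(nrow(x))) {
    m[x$i[r], x$j[r]] <- m[x$j[r], x$i[r]] <- x$significant[r]
  }
  m
}

#' Compact letter display of pairwise comparisons
#'
#' Encodes a full set of pairwise significance results with letters such
#' that two categories share at least one letter exactly when their
#' comparison is non-significant.  Uses the insert-and-absorb algorithm:
#' starting from a single letter covering all categories, each significant
#' pair splits every letter set containing both members into two reduced
#' copies, and sets contained in other sets are absorbed.  Letters are
#' assigned in category display order, so the letter *partition* is stable
#' even though specific glyphs are arbitrary.
#'
#' @param x A `pairwise_boot` object, or a symmetric logical significance
#'   matrix with dimnames (`TRUE` = significant pair).
#' @return An object of class `letter_display`: a named character vector
#'   mapping each category to its sorted letter string, with attribute
#'   `sets` (the list of letter membership sets).
#' @export
letter_display <- function(x) {
  if (inherits(x, "pairwise_boot")) {
    sig <- significance_matrix(x)
  } else if (is.matrix(x) && is.logical(x)) {
    if (!isTRUE(all.equal(x, t(x))) || any(diag(x))) {
      stop("inconsistent significance matrix: must be symmetric with a ",
           "FALSE diagonal")
    }
    if (is.null(dimnames(x))) {
      dimnames(x) <- list(paste0("cat", seq_len(nrow(x))),
                          paste0("cat", seq_len(nrow(x))))
    }
    sig <- x
  } else {
    stop("x must be a pairwise_boot object or a logical matrix")
  }
  labels <- rownames(sig)
  k <- length(labels)
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (!sig[i, j]) next
      hit <- vapply(sets, function(s) i %in% s && j %in% s, logical(1))
      if (!any(hit)) next
      new_sets <- sets[!hit]
      for (s in sets[hit]) {
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      }
      # absorb sets contained in another set
      keep <- rep(TRUE, length(new_sets))
      for (u in seq_along(new_sets)) {
        for (v in seq_along(new_sets)) {
          if (u != v && keep[u] &&
              all(new_sets[[u]] %in% new_sets[[v]]) &&
              (length(new_sets[[u]]) < length(new_sets[[v]]) ||
               (length(new_sets[[u]]) == length(new_sets[[v]]) && u > v))) {
            keep[u] <- FALSE
          }
        }
      }
      sets <- new_sets[keep]
    }
  }
  # order letter sets by their first member in display order
  sets <- sets[order(vapply(sets, min, numeric(1)),
                     vapply(sets, function(s) paste(s, collapse = ","),
                            character(1)))]
  glyphs <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- vapply(seq_len(k), function(i) {
    paste(glyphs[which(vapply(sets, function(s) i %in% s, logical(1)))],
          collapse = "")
  }, character(1))
  names(out) <- labels
  structure(out, sets = sets, class = "letter_display")
}

#' Do two categories share a letter?
#'
#' @param ld A `letter_display`.
#' @param a,b Category labels.
#' @return `TRUE` when the two categories share at least one letter, i.e.
#'   their pairwise comparison was not significant.
#' @export
shares_letter <- function(ld, a, b) {
  stopifnot(inherits(ld, "letter_display"))
  la <- strsplit(unname(ld[[a]]), "")[[1]]
  lb <- strsplit(unname(ld[[b]]), "")[[1]]
  length(intersect(la, lb)) > 0
}

#' Familywise error rate of the pairwise bootstrap under a null
#'
#' Simulation utility for calibration: generates datasets from a true
#' category distribution, runs [bootstrap_pairwise()] on each, and records
#' how often at least one truly null pair is declared significant.
#'
#' @param prob True category probabilities (a point null: every pairwise
#'   difference with equal probabilities is zero).
#' @param n Sample size per simulated dataset.
#' @param reps Number of simulated datasets.
#' @param B Bootstrap resamples per dataset.
#' @param alpha Family significance level.
#' @param seed Integer seed.
#' @param method Interval construction, passed to [bootstrap_pairwise()].
#' @return A list: `fwer` (estimated familywise error rate), `mc_se`
#'   (binomial Monte-Carlo standard error), `reps`.
#' @export
simulate_fwer <- function(prob, n = 85, reps = 500, B = 10000,
                          alpha = 0.05, seed = 1, method = "normal") {
  stopifnot(abs(sum(prob) - 1) < 1e-9)
  set.seed(seed)
  k <- length(prob)
  if (is.null(names(prob))) names(prob) <- paste0("cat", seq_len(k))
  hits <- logical(reps)
  for (r in seq_len(reps)) {
    counts <- stats::rmultinom(1, n, prob)[, 1]
    names(counts) <- names(prob)
    bp <- bootstrap_pairwise(counts, B = B, alpha = alpha, method = method)
    hits[r] <- any(bp$significant)
  }
  fwer <- mean(hits)
  list(fwer = fwer, mc_se = sqrt(fwer * (1 - fwer) / reps), reps = reps)
}
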