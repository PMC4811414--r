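#' Default configuration of the synthetic participant generator
#'
#' Encodes the statistical structure the analysis pipeline assumes, so
#' every stage can be exercised on data with known ground truth.  The
#' hue-category weights of each preference-by-context condition default to
#' the observed frequency distributions of the motivating study
#' ([table2_counts()] normalised by 85).  Lightness and chroma are
#' condition-specific truncated normals encoding the qualitative pattern:
#' most-preferred wall colours light, most-preferred t-shirt colours dark
#' and unchromatic, most-preferred general colours chromatic.  Association
#' types are imbalanced (most-preferred rich in object associations,
#' least-preferred rich in "none"), valence is positive for most- and
#' negative for least-preferred associations, and the selection process is
#' longer (more clicks, more time) for most-preferred choices.
#'
#' @param n Number of participants.
#' @return An object of class `generator_config` (a list).
#' @export
default_generator_config <- function(n = 85) {
  counts <- table2_counts()
  weights <- t(t(counts) / colSums(counts))
  conds <- colnames(counts)
  lightness <- data.frame(
    condition = conds,
    mean = c(60, 60, 75, 50, 45, 60),
    sd = rep(15, 6)
  )
  chroma <- data.frame(
    condition = conds,
    mean = c(65, 60, 40, 45, 40, 60),
    sd = rep(18, 6)
  )
  association <- data.frame(
    preference = c("most", "least"),
    object = c(0.50, 0.25),
    concept = c(0.30, 0.30),
    none = c(0.20, 0.45)
  )
  valence <- data.frame(
    preference = c("most", "least"),
    mean = c(20, -20),
    sd = c(12, 12),
    lo = c(0, -45),
    hi = c(45, 0)
  )
  clicks_lambda <- c(most = 24, least = 16)
  structure(
    list(n = n, weights = weights, lightness = lightness, chroma = chroma,
         association = association, valence = valence,
         clicks_lambda = clicks_lambda,
         latency_meanlog = log(1.0), latency_sdlog = 0.4,
         scheme = default_hue_scheme()),
    class = "generator_config"
  )
}

.check_generator_config <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n < 1) stop("n must be >= 1")
  if (any(abs(colSums(config$weights) - 1) > 1e-9)) {
    stop("hue-category weights must sum to 1 in every condition")
  }
  if (any(config$weights < 0)) stop("hue-category weights must be >= 0")
  if (any(config$lightness$sd <= 0) || any(config$chroma$sd <= 0)) {
    stop("lightness and chroma SDs must be > 0")
  }
  probs <- as.matrix(config$association[, c("object", "concept", "none")])
  if (any(probs < 0) || any(abs(rowSums(probs) - 1) > 1e-9)) {
    stop("association-type probabilities must form a simplex")
  }
  if (any(config$valence$lo < -45) || any(config$valence$hi > 45)) {
    stop("valence support must lie within [-45, 45]")
  }
  invisible(config)
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

.runif_arc <- function(n, lo, hi) {
  width <- (hi - lo) %% 360
  if (width == 0) width <- 360
  (lo + stats::runif(n, 0, width)) %% 360
}

.condition_key <- function(preference, context) paste(preference, context,
                                                      sep = ".")

#' Generate a synthetic participant choice dataset
#'
#' For each participant and each preference-by-context condition: draws a
#' hue category from the condition's weights; draws a hue angle uniformly
#' within the category's arc (maximum-entropy stand-in for the unreported
#' within-category spread); draws lightness and chroma from the
#' condition's truncated normals (the achromatic category forces chroma at
#' or below the cut-off); draws an association type, a valence rating
#' (missing when the type is "none"), a click count and a selection time.
#' Deterministic given the seed.
#'
#' @param config A [default_generator_config()]-style configuration.
#' @param seed Integer seed.
#' @return A tibble with one row per participant x preference x context:
#'   `participant`, `preference`, `context`, `L`, `C`, `h`, `hue_category`,
#'   `r`, `g`, `b` (rendered through the default display model),
#'   `time_s`, `clicks`, `association_type`, `association_text`,
#'   `valence`.  Attributes `seed` and `config` record provenance.
#' @export
generate_dataset <- function(config = default_generator_config(),
                             seed = 1) {
  .check_generator_config(config)
  set.seed(seed)
  scheme <- config$scheme
  cutoff <- attr(scheme, "chroma_cutoff")
  labels <- scheme_labels(scheme)
  prefs <- c("most", "least")
  contexts <- c("general", "walls", "tshirt")
  rows <- list()
  for (pref in prefs) {
    for (ctx in contexts) {
      cond <- .condition_key(pref, ctx)
      w <- config$weights[, cond]
      li <- config$lightness[config$lightness$condition == cond, ]
      ch <- config$chroma[config$chroma$condition == cond, ]
      m <- config$n
      cat_idx <- sample.int(length(labels), m, replace = TRUE, prob = w)
      cat_lab <- labels[cat_idx]
      h <- numeric(m)
      C <- numeric(m)
      for (i in seq_len(m)) {
        if (cat_lab[i] == attr(scheme, "achromatic_label")) {
          h[i] <- stats::runif(1, 0, 360)
          C[i] <- stats::runif(1, 0, cutoff)
        } else {
          row <- scheme[scheme$label == cat_lab[i], ]
          h[i] <- .runif_arc(1, row$lo, row$hi)
          C[i] <- .rtruncnorm(1, ch$mean, ch$sd, cutoff + 1e-6, 141)
        }
      }
      L <- .rtruncnorm(m, li$mean, li$sd, 0, 100)
      ap <- config$association[config$association$preference == pref, ]
      atype <- sample(c("object", "concept", "none"), m, replace = TRUE,
                      prob = c(ap$object, ap$concept, ap$none))
      vp <- config$valence[config$valence$preference == pref, ]
      valence <- .rtruncnorm(m, vp$mean, vp$sd, vp$lo, vp$hi)
      valence[atype == "none"] <- NA_real_
      clicks <- 1L + stats::rpois(m, config$clicks_lambda[[pref]])
      time_s <- clicks * stats::rlnorm(m, config$latency_meanlog,
                                       config$latency_sdlog)
      rows[[cond]] <- tibble::tibble(
        participant = sprintf("p%03d", seq_len(m)),
        preference = pref, context = ctx,
        L = L, C = C, h = h,
        hue_category = cat_lab,
        time_s = time_s, clicks = clicks,
        association_type = atype,
        association_text = ifelse(atype == "none", "",
                                  paste0(atype, "-", seq_len(m))),
        valence = valence
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  model <- default_display_model()
  lab <- LCh_to_Lab(out$L, out$C, out$h)
  xyz <- Lab_to_XYZ(lab$L, lab$a, lab$b, model$white)
  rgb <- XYZ_to_rgb(xyz$X, xyz$Y, xyz$Z, model)
  out$r <- rgb$r; out$g <- rgb$g; out$b <- rgb$b
  out$preference <- factor(out$preference, levels = prefs)
  out$context <- factor(out$context, levels = contexts)
  attr(out, "seed") <- seed
  attr(out, "generator_config") <- config
  out
}

#' Generate a dataset end-to-end through the picker engine
#'
#' Mechanistic variant of [generate_dataset()]: for every record a target
#' colour is drawn as in the direct generator, then a noisy greedy agent
#' navigates the picker towards it.  The recorded colour is the agent's
#' finalised choice and the click count comes from the actual trajectory,
#' so process measures arise from the selection mechanism rather than from
#' parametric distributions.
#'
#' @inheritParams generate_dataset
#' @param picker_cfg A [picker_config()].
#' @param noise Agent decision noise (Lab units on candidate distances).
#' @return A tibble with the same columns as [generate_dataset()].
#' @export
generate_via_picker <- function(config = default_generator_config(),
                                picker_cfg = picker_config(), seed = 1,
                                noise = 0) {
  base <- generate_dataset(config, seed = seed)
  gam <- picker_cfg$gamut
  lab <- LCh_to_Lab(base$L, base$C, base$h)
  n <- nrow(base)
  clicks <- integer(n)
  Lf <- Cf <- hf <- numeric(n)
  for (i in seq_len(n)) {
    target <- .clip_gamut(c(lab$L[i], lab$a[i], lab$b[i]), gam)
    res <- run_agent(target, picker_cfg, noise = noise)
    clicks[i] <- res$choice$clicks
    Lf[i] <- res$choice$lch[["L"]]
    Cf[i] <- res$choice$lch[["C"]]
    hf[i] <- res$choice$lch[["h"]]
  }
  base$L <- Lf; base$C <- Cf; base$h <- hf
  base$clicks <- clicks
  base$hue_category <- as.character(
    categorize_lch(base$L, base$C, base$h, config$scheme))
  base$time_s <- base$clicks *
    stats::rlnorm(n, config$latency_meanlog, config$latency_sdlog)
  model <- default_display_model()
  labf <- LCh_to_Lab(base$L, base$C, base$h)
  xyz <- Lab_to_XYZ(labf$L, labf$a, labf$b, model$white)
  rgbv <- XYZ_to_rgb(xyz$X, xyz$Y, xyz$Z, model)
  base$r <- rgbv$r; base$g <- rgbv$g; base$b <- rgbv$b
  base
}
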