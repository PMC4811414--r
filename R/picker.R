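#' Configuration for the headless colour picker
#'
#' The picker is a sequential colour-production tool.  A starting screen
#' shows nine palette patches (eight hue families plus grey).  After the
#' first click the tool enters a refinement loop: the chosen colour sits in
#' the centre, surrounded by up to eight variation patches -- four corners
#' moving along the Lab red-green (`a`) and yellow-blue (`b`) axes, upper
#' and lower patches moving lightness, and left/right patches moving chroma
#' radially.  Selecting any patch makes it the new centre and shrinks all
#' step sizes geometrically.  When every variation falls below the minimum
#' renderable difference the outer patches disappear and the centre is
#' proposed as the final choice; clicking the proposed centre reopens the
#' loop with the last renderable step sizes.
#'
#' @param palette Data frame with columns `label`, `L`, `a`, `b`: the nine
#'   starting patches.  Default: the focal hues of the default hue scheme
#'   at `L = 60`, `C = 60`, plus a mid grey.
#' @param initial_steps Named numeric vector `c(L=, C=, a=, b=)` of initial
#'   step sizes (Lab units), all `> 0`.
#' @param shrink Multiplicative step-shrink factor per refinement click, in
#'   `(0, 1)`.
#' @param threshold Minimum renderable difference (Lab units, `> 0`):
#'   patches closer to the centre than this are not shown.
#' @param gamut List with ranges `L`, `a`, `b`; centre colours are clipped
#'   to this box.
#' @return An object of class `picker_config`.
#' @export
picker_config <- function(palette = default_palette(),
                          initial_steps = c(L = 25, C = 25, a = 25, b = 25),
                          shrink = 0.5, threshold = 2,
                          gamut = list(L = c(0, 100), a = c(-128, 128),
                                       b = c(-128, 128))) {
  stopifnot(is.data.frame(palette),
            all(c("label", "L", "a", "b") %in% names(palette)))
  if (nrow(palette) != 9) {
    stop("the starting palette must contain exactly 9 patches")
  }
  if (!all(c("L", "C", "a", "b") %in% names(initial_steps)) ||
      any(initial_steps <= 0)) {
    stop("initial_steps must be positive and named L, C, a, b")
  }
  if (shrink <= 0 || shrink >= 1) stop("shrink must lie in (0, 1)")
  if (threshold <= 0) stop("threshold must be > 0")
  structure(
    list(palette = palette,
         initial_steps = initial_steps[c("L", "C", "a", "b")],
         shrink = shrink, threshold = threshold, gamut = gamut),
    class = "picker_config"
  )
}

#' @rdname picker_config
#' @param scheme Hue scheme supplying the focal hues of the eight chromatic
#'   palette patches.
#' @export
default_palette <- function(scheme = default_hue_scheme()) {
  lab <- LCh_to_Lab(60, 60, scheme$focal)
  rbind(
    data.frame(label = scheme$label, L = lab$L, a = lab$a, b = lab$b,
               stringsAsFactors = FALSE),
    data.frame(label = "Grey", L = 60, a = 0, b = 0)
  )
}

.clip_gamut <- function(lab, gamut) {
  c(min(max(lab[1], gamut$L[1]), gamut$L[2]),
    min(max(lab[2], gamut$a[1]), gamut$a[2]),
    min(max(lab[3], gamut$b[1]), gamut$b[2]))
}

#' Start a picker session
#'
#' @param config A [picker_config()].
#' @return A `picker_state`: phase `"palette"`, zero clicks, the nine
#'   palette patches exposed.  Sessions are deterministic: the same
#'   configuration always yields the same state.
#' @export
start_session <- function(config = picker_config()) {
  stopifnot(inherits(config, "picker_config"))
  structure(
    list(config = config, phase = "palette", centre = NULL,
         steps = config$initial_steps, reopen_steps = NULL, clicks = 0L,
         history = list()),
    class = "picker_state"
  )
}

.refine_patches <- function(centre, steps, config) {
  moves <- list(
    `L+` = c(steps[["L"]], 0, 0),
    `L-` = c(-steps[["L"]], 0, 0),
    `a+` = c(0, steps[["a"]], 0),
    `a-` = c(0, -steps[["a"]], 0),
    `b+` = c(0, 0, steps[["b"]]),
    `b-` = c(0, 0, -steps[["b"]])
  )
  # chroma moves act radially on (a, b); at zero chroma "more chroma"
  # departs along +a by convention
  C <- sqrt(centre[2]^2 + centre[3]^2)
  u <- if (C > 0) c(centre[2], centre[3]) / C else c(1, 0)
  moves$`C+` <- c(0, steps[["C"]] * u)
  moves$`C-` <- c(0, -steps[["C"]] * u)
  out <- lapply(moves, function(d) .clip_gamut(centre + d, config$gamut))
  keep <- vapply(out, function(p) {
    sqrt(sum((p - centre)^2)) >= config$threshold
  }, logical(1))
  out <- out[keep]
  if (length(out)) {
    df <- do.call(rbind, out)
    data.frame(patch = names(out), L = df[, 1], a = df[, 2], b = df[, 3],
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(patch = character(0), L = numeric(0), a = numeric(0),
               b = numeric(0))
  }
}

#' List the patches available in the current frame
#'
#' @param state A `picker_state`.
#' @return A data frame with columns `patch`, `L`, `a`, `b`.  In the palette
#'   phase these are the nine starting patches; in the refine phase the
#'   renderable outer variations plus the centre; in the proposed-final
#'   phase only the centre (clicking it reopens refinement).  Errors in the
#'   final phase.
#' @export
available_patches <- function(state) {
  stopifnot(inherits(state, "picker_state"))
  switch(state$phase,
    palette = {
      p <- state$config$palette
      data.frame(patch = p$label, L = p$L, a = p$a, b = p$b,
                 stringsAsFactors = FALSE)
    },
    refine = {
      outer <- .refine_patches(state$centre, state$steps, state$config)
      rbind(outer,
            data.frame(patch = "centre", L = state$centre[1],
                       a = state$centre[2], b = state$centre[3]))
    },
    `proposed-final` = data.frame(
      patch = "centre", L = state$centre[1], a = state$centre[2],
      b = state$centre[3], stringsAsFactors = FALSE),
    final = stop("session is final: no patches available")
  )
}

.log_click <- function(state, patch, centre) {
  state$history[[length(state$history) + 1]] <- data.frame(
    click = state$clicks, phase = state$phase, patch = patch,
    L = centre[1], a = centre[2], b = centre[3],
    step_L = state$steps[["L"]], step_C = state$steps[["C"]],
    step_a = state$steps[["a"]], step_b = state$steps[["b"]],
    stringsAsFactors = FALSE
  )
  state
}

#' Click a patch
#'
#' Advances the state machine: a palette click enters refinement centred on
#' the chosen hue family; a refine click makes the chosen patch the new
#' centre (the centre patch itself may be clicked to keep the colour) and
#' shrinks every step size by the shrink factor; when all variations drop
#' below the renderable threshold the session moves to the proposed-final
#' phase; clicking the centre there reopens refinement with the last
#' renderable (pre-termination) step sizes.
#'
#' @param state A `picker_state`.
#' @param patch Patch identifier: a palette label, one of `"L+"`, `"L-"`,
#'   `"C+"`, `"C-"`, `"a+"`, `"a-"`, `"b+"`, `"b-"`, or `"centre"`.
#' @return The new `picker_state`.
#' @export
click <- function(state, patch) {
  stopifnot(inherits(state, "picker_state"))
  if (state$phase == "final") stop("session is final: no further clicks")
  avail <- available_patches(state)
  i <- match(patch, avail$patch)
  if (is.na(i)) {
    stop(sprintf("patch \"%s\" is not available in phase %s", patch,
                 state$phase))
  }
  target <- c(avail$L[i], avail$a[i], avail$b[i])
  state$clicks <- state$clicks + 1L
  state <- .log_click(state, patch, target)
  if (state$phase == "palette") {
    state$centre <- target
    state$phase <- "refine"
    # palette screen has no step semantics; shrinking starts with refine
  } else if (state$phase == "refine") {
    state$centre <- target
    pre <- state$steps
    state$steps <- state$steps * state$config$shrink
    if (nrow(.refine_patches(state$centre, state$steps, state$config)) == 0) {
      state$reopen_steps <- pre
      state$phase <- "proposed-final"
    }
  } else { # proposed-final: reopen with last pre-termination steps
    state$steps <- state$reopen_steps
    state$phase <- "refine"
  }
  # a freshly entered refine phase may already be unrenderable
  if (state$phase == "refine" &&
      nrow(.refine_patches(state$centre, state$steps, state$config)) == 0) {
    state$reopen_steps <- state$steps
    state$phase <- "proposed-final"
  }
  state
}

#' Finalise a session and extract the colour choice
#'
#' @param state A `picker_state` in the proposed-final (or final) phase.
#' @return A list of class `picker_choice`: `lab` (centre colour), `lch`,
#'   `clicks` (total clicks), and `trajectory` (one row per click: phase,
#'   patch chosen, centre Lab, step sizes).  Repeated finalisation of a
#'   final state returns the identical choice.
#' @export
finalize <- function(state) {
  stopifnot(inherits(state, "picker_state"))
  if (!state$phase %in% c("proposed-final", "final")) {
    stop("cannot finalise mid-refinement: phase is ", state$phase)
  }
  lch <- Lab_to_LCh(state$centre[1], state$centre[2], state$centre[3])
  structure(
    list(lab = c(L = state$centre[1], a = state$centre[2],
                 b = state$centre[3]),
         lch = c(L = lch$L, C = lch$C, h = lch$h),
         clicks = state$clicks,
         trajectory = trajectory(state)),
    class = "picker_choice"
  )
}

#' Trajectory log of a session
#'
#' @param state A `picker_state`.
#' @return Data frame with one row per click: click index, phase at click
#'   time, patch chosen, resulting centre Lab, and step sizes at click time.
#' @export
trajectory <- function(state) {
  stopifnot(inherits(state, "picker_state"))
  if (!length(state$history)) {
    return(data.frame(click = integer(0), phase = character(0),
                      patch = character(0), L = numeric(0), a = numeric(0),
                      b = numeric(0), step_L = numeric(0), step_C = numeric(0),
                      step_a = numeric(0), step_b = numeric(0)))
  }
  do.call(rbind, state$history)
}

#' Run a simulated agent through the picker
#'
#' A greedy agent aiming for a target colour: at every frame it clicks the
#' available patch closest to the target in Euclidean Lab distance
#' (optionally perturbed by Gaussian noise on the distances).  At a
#' proposed-final screen the agent reopens refinement only if some
#' renderable move would strictly reduce its distance; otherwise it
#' finalises.  With zero noise the distance to target never increases along
#' the trajectory, and the final colour lies within
#' `sqrt(3) * threshold / (2 * shrink)` of any in-gamut target.
#'
#' @param target Target colour, numeric `c(L, a, b)`, inside the gamut.
#' @param config A [picker_config()].
#' @param noise Standard deviation of Gaussian perturbation added to each
#'   candidate distance (`>= 0`).
#' @param seed Optional integer seed; the run is deterministic given the
#'   seed.
#' @param max_clicks Click cap; exceeding it raises a non-convergence error
#'   carrying the trajectory in its `trajectory` field.
#' @return A list: `choice` (a `picker_choice`), `state`, and `distance`
#'   (final Lab distance to target).
#' @export
run_agent <- function(target, config = picker_config(), noise = 0,
                      seed = NULL, max_clicks = 1000L) {
  stopifnot(length(target) == 3, is.numeric(target))
  if (noise < 0) stop("noise must be >= 0")
  g <- config$gamut
  if (target[1] < g$L[1] || target[1] > g$L[2] ||
      target[2] < g$a[1] || target[2] > g$a[2] ||
      target[3] < g$b[1] || target[3] > g$b[2]) {
    stop("target lies outside the display gamut")
  }
  if (!is.null(seed)) set.seed(seed)
  dist_to <- function(p) sqrt(sum((p - target)^2))
  state <- start_session(config)
  check_cap <- function(state) {
    if (state$clicks >= max_clicks) {
      cond <- structure(
        class = c("picker_nonconvergence", "error", "condition"),
        list(message = sprintf("agent did not converge within %d clicks",
                               max_clicks),
             call = sys.call(), trajectory = trajectory(state))
      )
      stop(cond)
    }
  }
  repeat {
    if (state$phase == "proposed-final") {
      # reopen only if a renderable move would strictly improve
      probe <- .refine_patches(state$centre, state$reopen_steps,
                               state$config)
      d0 <- dist_to(state$centre)
      improves <- FALSE
      if (nrow(probe)) {
        dd <- apply(probe[, c("L", "a", "b")], 1, dist_to)
        improves <- any(dd < d0 - 1e-9)
      }
      if (!improves) break
      check_cap(state)
      state <- click(state, "centre")
    } else {
      avail <- available_patches(state)
      d <- apply(avail[, c("L", "a", "b")], 1, dist_to)
      if (noise > 0) d <- d + stats::rnorm(length(d), 0, noise)
      check_cap(state)
      state <- click(state, avail$patch[which.min(d)])
    }
  }
  choice <- finalize(state)
  list(choice = choice, state = state, distance = dist_to(state$centre))
}
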