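test_that("sessions start on a nine-patch palette, deterministically", {
  cfg <- picker_config()
  s <- start_session(cfg)
  expect_equal(s$phase, "palette")
  expect_equal(s$clicks, 0L)
  patches <- available_patches(s)
  expect_equal(nrow(patches), 9)
  expect_setequal(patches$patch,
                  c(default_hue_scheme()$label, "Grey"))
  expect_identical(start_session(cfg), start_session(cfg))
  bad_palette <- default_palette()[1:8, ]
  expect_error(picker_config(palette = bad_palette), "exactly 9")
  expect_error(picker_config(shrink = 1), "shrink")
  expect_error(picker_config(threshold = 0), "threshold")
})

test_that("refine patches move along the stated axes and clip to gamut", {
  cfg <- picker_config()
  s <- click(start_session(cfg), "Grey") # centre (60, 0, 0)
  p <- available_patches(s)
  up <- p[p$patch == "L+", ]
  expect_equal(up$L, 60 + 25)
  expect_equal(c(up$a, up$b), c(0, 0))
  dn <- p[p$patch == "L-", ]
  expect_equal(dn$L, 60 - 25)
  corner <- p[p$patch == "b+", ]
  expect_equal(corner$b, 25)
  expect_equal(corner$L, 60)
  # at zero chroma the chroma+ move departs along +a by convention
  cp <- p[p$patch == "C+", ]
  expect_equal(c(cp$a, cp$b), c(25, 0))
  # near the top of the lightness range the upper patch clips to L = 100
  s2 <- s
  s2$centre <- c(95, 0, 0)
  p2 <- available_patches(s2)
  expect_equal(p2[p2$patch == "L+", "L"], 100)
})

test_that("steps shrink geometrically and sessions terminate at the bound", {
  cfg <- picker_config()
  s <- click(start_session(cfg), "Blue")
  expect_equal(unname(s$steps), rep(25, 4)) # palette click has no step semantics
  k <- 0
  while (s$phase == "refine") {
    s <- click(s, "centre")
    k <- k + 1
    if (s$phase == "refine") {
      expect_equal(unname(s$steps), rep(25 * 0.5^k, 4))
    }
  }
  bound <- ceiling(log(cfg$threshold / max(cfg$initial_steps)) /
                     log(cfg$shrink))
  expect_equal(k, bound)
  expect_equal(s$phase, "proposed-final")
  expect_equal(nrow(available_patches(s)), 1)
  # reopening restores the last renderable step sizes
  s3 <- click(s, "centre")
  expect_equal(s3$phase, "refine")
  expect_equal(unname(s3$steps), rep(25 * 0.5^(bound - 1), 4))
})

test_that("finalize requires a proposed-final phase and is idempotent", {
  cfg <- picker_config()
  s <- click(start_session(cfg), "Red")
  expect_error(finalize(s), "mid-refinement")
  while (s$phase == "refine") s <- click(s, "centre")
  ch1 <- finalize(s)
  ch2 <- finalize(s)
  expect_identical(ch1, ch2)
  expect_s3_class(ch1, "picker_choice")
  expect_equal(ch1$clicks, s$clicks)
  expect_equal(nrow(ch1$trajectory), s$clicks)
  expect_error(click(s, "L+"), "not available")
})

test_that("greedy zero-noise agents converge within the analytic bound", {
  cfg <- picker_config()
  # a palette colour as target: reached essentially exactly
  pal <- default_palette()
  res <- run_agent(c(pal$L[3], pal$a[3], pal$b[3]), cfg)
  expect_lt(res$distance, cfg$threshold)
  bound <- sqrt(3) * cfg$threshold / (2 * cfg$shrink)
  per_visit_bound <- ceiling(log(cfg$threshold / max(cfg$initial_steps)) /
                               log(cfg$shrink))
  set.seed(31)
  for (i in 1:30) {
    target <- c(runif(1, 0, 100), runif(1, -128, 128), runif(1, -128, 128))
    r <- run_agent(target, cfg)
    expect_lte(r$distance, bound)
    # distance to target is non-increasing along the trajectory
    tr <- r$choice$trajectory
    d <- sqrt((tr$L - target[1])^2 + (tr$a - target[2])^2 +
                (tr$b - target[3])^2)
    expect_true(all(diff(d) <= 1e-9))
    # centre colours never leave the gamut box
    expect_true(all(tr$L >= 0 & tr$L <= 100))
    expect_true(all(abs(tr$a) <= 128 & abs(tr$b) <= 128))
    # refine clicks per visit never exceed the termination bound
    visit_len <- rle(tr$phase)$lengths[rle(tr$phase)$values == "refine"]
    expect_true(all(visit_len <= per_visit_bound + 1))
  }
})

test_that("agents are deterministic given a seed and reject bad targets", {
  cfg <- picker_config()
  r1 <- run_agent(c(40, 30, -20), cfg, noise = 3, seed = 7)
  r2 <- run_agent(c(40, 30, -20), cfg, noise = 3, seed = 7)
  expect_identical(r1$choice$clicks, r2$choice$clicks)
  expect_identical(r1$choice$lab, r2$choice$lab)
  expect_error(run_agent(c(150, 0, 0), cfg), "outside the display gamut")
  expect_error(run_agent(c(50, 0, 0), cfg, noise = -1), "noise")
})

test_that("a non-convergent agent fails with its trajectory attached", {
  cfg <- picker_config()
  err <- tryCatch(
    run_agent(c(20, 100, 100), cfg, noise = 50, seed = 1, max_clicks = 5L),
    picker_nonconvergence = function(e) e
  )
  expect_s3_class(err, "picker_nonconvergence")
  expect_true(is.data.frame(err$trajectory))
})
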