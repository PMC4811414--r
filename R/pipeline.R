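#' Embedded hue-frequency fixture (published Table 2 counts)
#'
#' Observed counts of 85 participants' hue-category choices for each
#' preference (most/least) by context (general/walls/t-shirt) condition,
#' as printed in the motivating study's bootstrap comparison table.  Used
#' as the package's built-in worked example and as the default
#' hue-category weights of the synthetic generator.
#'
#' @return A 9 x 6 integer matrix; rows are the hue categories in display
#'   order, columns the conditions (`most.general`, `least.general`,
#'   `most.walls`, `least.walls`, `most.tshirt`, `least.tshirt`).  Every
#'   column sums to 85.
#' @export
table2_counts <- function() {
  m <- matrix(
    c(26,  8, 21, 20, 27,  6,   # Red
       5, 12,  9,  9,  2, 18,   # Orange
       5, 34, 11, 13,  4, 26,   # Yellow
       2,  6,  4,  4,  3,  6,   # Yellow-Green
       9,  3,  5,  9,  6,  7,   # Green
      23,  3, 12,  4, 11,  2,   # Green-Blue
       8,  0,  2,  2, 10,  1,   # Blue
       6, 11,  7,  6,  6, 16,   # Purple
       1,  8, 14, 18, 16,  3),  # Achromatic
    nrow = 9, byrow = TRUE,
    dimnames = list(
      c("Red", "Orange", "Yellow", "Yellow-Green", "Green", "Green-Blue",
        "Blue", "Purple", "Achromatic"),
      c("most.general", "least.general", "most.walls", "least.walls",
        "most.tshirt", "least.tshirt")
    )
  )
  storage.mode(m) <- "integer"
  m
}

#' Percentage of participants, rounded half-up to one decimal
#'
#' @param count Number of participants making the selection, `0 <= count
#'   <= n`.
#' @param n Total number of participants, `> 0`.
#' @return `100 * count / n` rounded half-up to one decimal place (the
#'   rounding used in published frequency tables, where e.g. 26 of 85 is
#'   printed as 30.6).
#' @export
percent <- function(count, n) {
  if (any(n <= 0)) stop("n must be > 0")
  if (any(count < 0) || any(count > n)) stop("need 0 <= count <= n")
  floor(1000 * count / n + 0.5) / 10
}

#' Read a participant choice table from CSV
#'
#' The canonical choice table has one row per participant x preference x
#' context with columns `participant`, `preference` (most/least),
#' `context` (general/walls/tshirt), a colour as device RGB (`r`, `g`,
#' `b`), measured CIE xyY (`x`, `y`, `Y`) and/or ready CIE LCh (`L`, `C`,
#' `h`), and optionally `time_s`, `clicks`, `association_type`
#' (object/concept/none), `association_text`, `valence` (in `[-45, 45]`,
#' empty when the association type is "none").
#'
#' @param path CSV file path.
#' @return A validated tibble.  Violations (missing columns, unknown
#'   factor levels, duplicate participant-condition rows, out-of-range
#'   valence, click counts below 1) raise errors naming the offending rows
#'   or participants.
#' @export
read_choices <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant", "preference", "context")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  has_rgb <- all(c("r", "g", "b") %in% names(df))
  has_xyY <- all(c("x", "y", "Y") %in% names(df))
  has_lch <- all(c("L", "C", "h") %in% names(df))
  if (!has_rgb && !has_xyY && !has_lch) {
    stop("no colour columns found: need (r, g, b), (x, y, Y) or (L, C, h)")
  }
  problems <- character(0)
  bad_pref <- !df$preference %in% c("most", "least")
  if (any(bad_pref)) {
    problems <- c(problems, paste0("row ", which(bad_pref),
                                   ": unknown preference \"",
                                   df$preference[bad_pref], "\""))
  }
  bad_ctx <- !df$context %in% c("general", "walls", "tshirt")
  if (any(bad_ctx)) {
    problems <- c(problems, paste0("row ", which(bad_ctx),
                                   ": unknown context \"",
                                   df$context[bad_ctx], "\""))
  }
  key <- paste(df$participant, df$preference, df$context)
  dup <- duplicated(key)
  if (any(dup)) {
    problems <- c(problems,
                  paste0("duplicate condition row for participant ",
                         df$participant[dup], " (", df$preference[dup], ", ",
                         df$context[dup], ")"))
  }
  if ("valence" %in% names(df)) {
    bad_val <- !is.na(df$valence) & (df$valence < -45 | df$valence > 45)
    if (any(bad_val)) {
      problems <- c(problems, paste0("row ", which(bad_val),
                                     ": valence ", df$valence[bad_val],
                                     " outside [-45, 45]"))
    }
  }
  if ("clicks" %in% names(df)) {
    bad_cl <- !is.na(df$clicks) & df$clicks < 1
    if (any(bad_cl)) {
      problems <- c(problems, paste0("row ", which(bad_cl),
                                     ": click count below 1"))
    }
  }
  if (length(problems)) {
    stop("invalid choice table:\n  ", paste(problems, collapse = "\n  "))
  }
  df$preference <- factor(df$preference, levels = c("most", "least"))
  df$context <- factor(df$context, levels = c("general", "walls", "tshirt"))
  tibble::as_tibble(df)
}

#' Write a participant choice table to CSV
#' @param dataset Choice tibble (e.g. from [generate_dataset()]).
#' @param path Output CSV path.
#' @export
write_choices <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Attach CIE LCh coordinates to a choice table
#'
#' Uses measured xyY columns when present (preferred), otherwise device
#' RGB through the display model; keeps ready-made LCh columns untouched.
#' Adds a `colour_source` column flagging rows converted through the
#' display-model approximation.
#'
#' @param dataset Choice tibble.
#' @param model A [display_model()].
#' @param white Reference white tristimulus; defaults to the model white.
#' @export
convert_choices <- function(dataset, model = default_display_model(),
                            white = model$white) {
  has_xyY <- all(c("x", "y", "Y") %in% names(dataset))
  has_rgb <- all(c("r", "g", "b") %in% names(dataset))
  has_lch <- all(c("L", "C", "h") %in% names(dataset))
  if (has_lch && !"colour_source" %in% names(dataset)) {
    dataset$colour_source <- "LCh"
    return(dataset)
  }
  if (has_lch) return(dataset)
  if (has_xyY) {
    lch <- convert_choice(xyY = as.matrix(dataset[, c("x", "y", "Y")]),
                          model = model, white = white)
    dataset$colour_source <- "measured-xyY"
  } else if (has_rgb) {
    lch <- convert_choice(rgb = as.matrix(dataset[, c("r", "g", "b")]),
                          model = model, white = white)
    dataset$colour_source <- "rgb-display-model"
  } else {
    stop("no colour columns to convert")
  }
  dataset$L <- lch$L; dataset$C <- lch$C; dataset$h <- lch$h
  dataset
}

#' Hue-category frequency table of one condition
#'
#' @param dataset Choice tibble with LCh columns (see [convert_choices()]).
#' @param preference `"most"` or `"least"`.
#' @param context `"general"`, `"walls"` or `"tshirt"`.
#' @param scheme A [hue_scheme()].
#' @return Named integer vector of counts over the scheme's categories,
#'   with attributes `n` and `condition`.  Counts sum to the number of
#'   participants in the condition.
#' @export
frequency_table <- function(dataset, preference, context,
                            scheme = default_hue_scheme()) {
  sub <- dataset[dataset$preference == preference &
                   dataset$context == context, ]
  if (nrow(sub) == 0) {
    stop(sprintf("no observations for condition (%s, %s)", preference,
                 context))
  }
  cats <- categorize_lch(sub$L, sub$C, sub$h, scheme)
  counts <- table(cats)
  out <- as.integer(counts)
  names(out) <- names(counts)
  attr(out, "n") <- nrow(sub)
  attr(out, "condition") <- .condition_key(preference, context)
  out
}

#' Frequency tables for all six conditions
#'
#' @inheritParams frequency_table
#' @return A 9 x 6 matrix of counts, columns in the fixture's condition
#'   order.
#' @export
condition_frequencies <- function(dataset, scheme = default_hue_scheme()) {
  conds <- expand.grid(preference = c("most", "least"),
                       context = c("general", "walls", "tshirt"),
                       stringsAsFactors = FALSE)
  cols <- lapply(seq_len(nrow(conds)), function(i) {
    frequency_table(dataset, conds$preference[i], conds$context[i], scheme)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- mapply(.condition_key, conds$preference, conds$context)
  m[, c("most.general", "least.general", "most.walls", "least.walls",
        "most.tshirt", "least.tshirt")]
}

#' Valence summaries per preference and association type
#'
#' @param dataset Choice tibble.
#' @return Tibble grouped by preference and association type (object /
#'   concept): record count, median, mean, quartiles, 1.5 IQR outlier
#'   fences, and counts of positive / negative ratings.
#' @export
summarize_valence <- function(dataset) {
  val <- dataset[!is.na(dataset$valence), ]
  if (nrow(val) == 0) stop("no valenced records in the dataset")
  val |>
    dplyr::group_by(.data$preference, .data$association_type) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$valence),
      mean = mean(.data$valence),
      q1 = unname(stats::quantile(.data$valence, 0.25)),
      q3 = unname(stats::quantile(.data$valence, 0.75)),
      fence_lo = .data$q1 - 1.5 * (.data$q3 - .data$q1),
      fence_hi = .data$q3 + 1.5 * (.data$q3 - .data$q1),
      n_positive = sum(.data$valence > 0),
      n_negative = sum(.data$valence < 0),
      .groups = "drop"
    )
}

#' Association-type distribution tests
#'
#' Cross-tabulates each participant-context pair's association type for
#' the most-preferred against the least-preferred choice and tests
#' marginal homogeneity (Stuart-Maxwell), overall and per context.  Also
#' compares, per preference type, each participant's number of object-
#' versus concept-based associations with a Wilcoxon signed-rank test.
#'
#' @param dataset Choice tibble with `association_type`.
#' @return A list: `paired_tables` (overall and per-context 3 x 3 paired
#'   tables, most in rows, least in columns), `stuart_maxwell` (tests per
#'   table), `wilcoxon` (object vs concept counts, one test per
#'   preference type).
#' @export
association_distribution <- function(dataset) {
  types <- c("object", "concept", "none")
  wide <- dataset |>
    dplyr::select("participant", "preference", "context",
                  "association_type") |>
    .assoc_pairs()
  tab_for <- function(d) {
    table(factor(d$most, levels = types), factor(d$least, levels = types))
  }
  tables <- c(
    list(overall = tab_for(wide)),
    lapply(split(wide, wide$context), tab_for)
  )
  sm <- lapply(tables, stuart_maxwell)
  obj_con <- dataset |>
    dplyr::group_by(.data$participant, .data$preference) |>
    dplyr::summarise(
      object = sum(.data$association_type == "object"),
      concept = sum(.data$association_type == "concept"),
      .groups = "drop"
    )
  wres <- lapply(split(obj_con, obj_con$preference), function(d) {
    # every participant tied on object vs concept counts: no test possible
    tryCatch(wilcoxon_signed_rank(d$object, d$concept),
             error = function(e) NULL)
  })
  list(paired_tables = tables, stuart_maxwell = sm, wilcoxon = wres)
}

# most/least association types side by side per participant x context
.assoc_pairs <- function(d) {
  most <- d[d$preference == "most", c("participant", "context",
                                      "association_type")]
  least <- d[d$preference == "least", c("participant", "context",
                                        "association_type")]
  names(most)[3] <- "most"
  names(least)[3] <- "least"
  merge(most, least, by = c("participant", "context"))
}

#' Within-subject cell matrix of a measure
#'
#' @param dataset Choice tibble.
#' @param measure Column name (`"L"`, `"C"`, `"clicks"`, `"time_s"`, ...).
#' @return Matrix, participants in rows, the six preference-by-context
#'   cells in columns (`most.general, most.walls, most.tshirt,
#'   least.general, ...`), suitable for [rm_anova_2x3()].  Errors when any
#'   participant lacks a cell.
#' @export
cell_matrix <- function(dataset, measure) {
  stopifnot(measure %in% names(dataset))
  prefs <- c("most", "least")
  ctxs <- c("general", "walls", "tshirt")
  parts <- sort(unique(dataset$participant))
  m <- matrix(NA_real_, length(parts), 6,
              dimnames = list(parts, paste(rep(prefs, each = 3),
                                           rep(ctxs, 2), sep = ".")))
  for (i in seq_len(nrow(dataset))) {
    col <- paste(dataset$preference[i], dataset$context[i], sep = ".")
    m[dataset$participant[i], col] <- dataset[[measure]][i]
  }
  if (any(is.na(m))) {
    bad <- rownames(m)[rowSums(is.na(m)) > 0]
    stop("incomplete within-subject data for participant(s): ",
         paste(bad, collapse = ", "))
  }
  m
}

#' Run the full analysis pipeline on a choice dataset
#'
#' Converts colours when needed, builds the six hue-frequency tables with
#' percentages and compact letter displays from the pairwise bootstrap,
#' runs the within-subject ANOVAs on lightness, chroma, click counts and
#' selection time, tests the association-type distributions, and
#' summarises valence ratings.  The report is deterministic given the
#' seed.
#'
#' @param dataset Choice tibble.
#' @param scheme A [hue_scheme()].
#' @param B Bootstrap resamples per condition.
#' @param alpha Family significance level for the pairwise comparisons.
#' @param seed Integer seed for the bootstrap.
#' @param model Display model used if colours need converting from RGB.
#' @return A list of class `analysis_report`.
#' @export
run_full_analysis <- function(dataset, scheme = default_hue_scheme(),
                              B = 100000L, alpha = 0.05, seed = 1,
                              model = default_display_model()) {
  dataset <- convert_choices(dataset, model = model)
  freq <- condition_frequencies(dataset, scheme)
  conds <- colnames(freq)
  boot <- list()
  hue_tables <- list()
  for (i in seq_along(conds)) {
    counts <- freq[, i]
    bp <- bootstrap_pairwise(counts, B = B, alpha = alpha,
                             seed = seed + i - 1)
    ld <- letter_display(bp)
    boot[[conds[i]]] <- bp
    hue_tables[[conds[i]]] <- data.frame(
      category = rownames(freq),
      count = unname(counts),
      percent = percent(unname(counts), sum(counts)),
      letters = unname(unclass(ld)[rownames(freq)]),
      stringsAsFactors = FALSE
    )
  }
  anovas <- list()
  posthoc <- list()
  for (measure in intersect(c("L", "C", "clicks", "time_s"),
                            names(dataset))) {
    cm <- cell_matrix(dataset, measure)
    anovas[[measure]] <- rm_anova_2x3(cm)
    posthoc[[measure]] <- list(
      preference = bonferroni_posthoc(cm, "A",
                                      level_names = c("most", "least")),
      context = bonferroni_posthoc(cm, "B",
                                   level_names = c("general", "walls",
                                                   "tshirt")),
      cells = bonferroni_posthoc(cm, "cells")
    )
  }
  assoc <- if ("association_type" %in% names(dataset)) {
    association_distribution(dataset)
  }
  valence <- if ("valence" %in% names(dataset) &&
                 any(!is.na(dataset$valence))) {
    summarize_valence(dataset)
  }
  structure(
    list(
      hue_tables = hue_tables,
      frequencies = freq,
      bootstrap = boot,
      anova = anovas,
      posthoc = posthoc,
      associations = assoc,
      valence = valence,
      provenance = list(
        seed = seed, B = B, alpha = alpha,
        alpha_corrected = corrected_alpha(alpha, nrow(freq)),
        chroma_cutoff = attr(scheme, "chroma_cutoff"),
        n = sum(freq[, 1]),
        package_version = as.character(utils::packageVersion("colourpref"))
      )
    ),
    class = "analysis_report"
  )
}

#' Render hue-frequency tables in the published layout
#'
#' One row per hue category; per condition a `count (percent)` column and
#' the compact letter display, mirroring the published bootstrap
#' comparison table.
#'
#' @param report An `analysis_report`, or a counts matrix like
#'   [table2_counts()] (letters are then computed with the given
#'   bootstrap settings).
#' @param ... Passed to [run_full_analysis()]-style bootstrap arguments
#'   (`B`, `alpha`, `seed`) when `report` is a counts matrix.
#' @return Character vector of formatted lines.
#' @export
render_table2 <- function(report, ...) {
  if (!inherits(report, "analysis_report")) {
    freq <- report
    args <- list(...)
    B <- args$B %||% 100000L
    alpha <- args$alpha %||% 0.05
    seed <- args$seed %||% 1
    tabs <- list()
    for (i in seq_len(ncol(freq))) {
      counts <- freq[, i]
      ld <- letter_display(bootstrap_pairwise(counts, B = B, alpha = alpha,
                                              seed = seed + i - 1))
      tabs[[colnames(freq)[i]]] <- data.frame(
        category = rownames(freq), count = unname(counts),
        percent = percent(unname(counts), sum(counts)),
        letters = unname(unclass(ld)[rownames(freq)]),
        stringsAsFactors = FALSE
      )
    }
  } else {
    tabs <- report$hue_tables
  }
  conds <- names(tabs)
  cats <- tabs[[1]]$category
  header <- sprintf("%-14s %s", "Hue",
                    paste(sprintf("%-18s", conds), collapse = " "))
  lines <- header
  for (r in seq_along(cats)) {
    cells <- vapply(conds, function(cn) {
      t1 <- tabs[[cn]]
      sprintf("%3d (%4.1f) %-5s", t1$count[r], t1$percent[r], t1$letters[r])
    }, character(1))
    lines <- c(lines, sprintf("%-14s %s", cats[r],
                              paste(sprintf("%-18s", cells),
                                    collapse = " ")))
  }
  totals <- vapply(conds, function(cn) {
    sprintf("%3d (100.0)      ", sum(tabs[[cn]]$count))
  }, character(1))
  c(lines, sprintf("%-14s %s", "Total",
                   paste(sprintf("%-18s", totals), collapse = " ")))
}

#' Write an analysis report to JSON
#'
#' @param report An `analysis_report`.
#' @param path Output path.
#' @return The path, invisibly.  Reports are deterministic given identical
#'   inputs and seed, so the JSON is byte-identical across reruns.
#' @export
report_to_json <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  strip <- function(x) {
    if (inherits(x, "pairwise_boot")) {
      as.data.frame(x)
    } else if (inherits(x, c("stuart_maxwell", "wilcoxon_sr"))) {
      unclass(x)
    } else if (inherits(x, "rm_anova")) {
      as.data.frame(x)
    } else if (is.list(x) && !is.data.frame(x)) {
      lapply(x, strip)
    } else if (is.table(x)) {
      as.data.frame(unclass(x))
    } else {
      x
    }
  }
  jsonlite::write_json(strip(unclass(report)), path, auto_unbox = TRUE,
                       digits = 12, na = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
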