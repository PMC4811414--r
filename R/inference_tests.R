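#' Stuart-Maxwell test of marginal homogeneity
#'
#' Tests whether the marginal distributions of a paired categorical
#' response (a square contingency table of first-occasion rows versus
#' second-occasion columns) are equal, generalising McNemar's test beyond
#' 2 x 2.  With `d` the vector of row-minus-column marginal differences
#' (one category dropped) and `S` its covariance under marginal
#' homogeneity, the statistic is `chi^2 = d' S^{-1} d` on `k - 1` degrees
#' of freedom.
#'
#' Categories with empty row *and* column margins are dropped before
#' computation.  If `S` is singular a Moore-Penrose generalised inverse is
#' used and the rank of `S` is reported as the effective df.
#'
#' @param tab Square numeric matrix of paired counts; `tab[i, j]` counts
#'   subjects in category `i` on the first occasion and `j` on the second.
#' @return A list of class `stuart_maxwell`: `statistic` (chi-square),
#'   `df`, `p.value`, `n` (number of pairs).
#' @examples
#' m <- matrix(c(10, 5, 0, 0, 10, 5, 5, 0, 10), 3, byrow = TRUE)
#' stuart_maxwell(m)
#' @export
stuart_maxwell <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab) || nrow(tab) < 2) {
    stop("tab must be a square matrix with k >= 2 categories")
  }
  if (any(tab < 0)) stop("counts must be non-negative")
  keep <- rowSums(tab) + colSums(tab) > 0
  tab <- tab[keep, keep, drop = FALSE]
  k <- nrow(tab)
  if (k < 2) {
    # a single occupied category is trivially marginally homogeneous
    return(structure(list(statistic = 0, df = 0L, p.value = 1,
                          n = sum(tab)),
                     class = "stuart_maxwell"))
  }
  n <- sum(tab)
  d_full <- rowSums(tab) - colSums(tab)
  d <- d_full[-k]
  S <- matrix(0, k - 1, k - 1)
  for (i in seq_len(k - 1)) {
    S[i, i] <- sum(tab[i, ]) + sum(tab[, i]) - 2 * tab[i, i]
    for (j in seq_len(k - 1)) {
      if (i != j) S[i, j] <- -(tab[i, j] + tab[j, i])
    }
  }
  if (all(abs(d_full) < 1e-12)) {
    stat <- 0
    df <- k - 1
  } else {
    qrS <- qr(S)
    if (qrS$rank == k - 1) {
      stat <- drop(t(d) %*% solve(S, d))
      df <- k - 1
    } else {
      stat <- drop(t(d) %*% MASS::ginv(S) %*% d)
      df <- qrS$rank
    }
  }
  structure(
    list(statistic = stat, df = df,
         p.value = stats::pchisq(stat, df, lower.tail = FALSE), n = n),
    class = "stuart_maxwell"
  )
}

#' Wilcoxon signed-rank test with normal approximation
#'
#' Paired signed-rank test reporting the `V` statistic (sum of ranks of
#' positive differences, zeros dropped, ties mid-ranked), a standardised
#' `Z` with tie correction, and a two-sided p-value.  For small samples
#' without ties the exact signed-rank distribution is used for the
#' p-value; otherwise the normal approximation.
#'
#' @param x Numeric vector: paired differences, or first member of the
#'   pairs when `y` is given.
#' @param y Optional second member of the pairs.
#' @param exact Use the exact distribution for the p-value?  Default: yes
#'   when there are no ties among the nonzero `|d|` and at most 50 of
#'   them.
#' @return A list of class `wilcoxon_sr`: `statistic` (V), `Z`, `p.value`,
#'   `n` (nonzero differences), `exact`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero (or missing)")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- table(r)
  has_ties <- any(ties > 1)
  mu <- n * (n + 1) / 4
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  Z <- if (sigma2 > 0) (V - mu) / sqrt(sigma2) else 0
  if (is.null(exact)) exact <- !has_ties && n <= 50
  if (exact && has_ties) {
    warning("exact p-value not available with tied ranks; using normal ",
            "approximation")
    exact <- FALSE
  }
  p <- if (exact) {
    if (V > mu) {
      min(1, 2 * stats::psignrank(V - 1, n, lower.tail = FALSE))
    } else {
      min(1, 2 * stats::psignrank(V, n))
    }
  } else {
    min(1, 2 * stats::pnorm(-abs(Z)))
  }
  structure(list(statistic = V, Z = Z, p.value = p, n = n, exact = exact),
            class = "wilcoxon_sr")
}

# orthonormal within-subject effect contrasts for a p x q cell layout,
# cells ordered with factor B varying fastest
.effect_contrasts <- function(p, q) {
  orth <- function(m) { # rows of m span the space; return orthonormal rows
    b <- qr.Q(qr(t(m)))
    t(b)
  }
  cA <- orth(stats::contr.helmert(p) |> t())
  cB <- orth(stats::contr.helmert(q) |> t())
  oneA <- matrix(1 / sqrt(p), 1, p)
  oneB <- matrix(1 / sqrt(q), 1, q)
  list(
    A = kronecker(cA, oneB),
    B = kronecker(oneA, cB),
    AB = kronecker(cA, cB)
  )
}

#' Two-way fully within-subject (repeated measures) ANOVA
#'
#' Classical univariate decomposition for a 2 x 3 (or generally `p x q`)
#' design in which every subject contributes one value per cell.  Each
#' effect is tested against its own effect-by-subject error term.
#' Greenhouse-Geisser epsilon is estimated from the covariance of the
#' orthonormalised effect contrast scores and applied to the degrees of
#' freedom of every effect with more than one numerator df; effect sizes
#' are partial eta squared, `SS_effect / (SS_effect + SS_error)`.
#'
#' @param values Numeric matrix or data frame, subjects in rows and the
#'   `p * q` cells in columns, with factor B varying fastest (e.g. columns
#'   `most.general, most.walls, most.tshirt, least.general, ...`).  No
#'   missing cells are allowed.
#' @param p,q Numbers of levels of the first (slow) and second (fast)
#'   within-subject factor.
#' @param effect_names Names used for the two main effects in the output.
#' @return An object of class `rm_anova`: a data frame with one row per
#'   effect (`effect`, `df1`, `df2`, `F`, `epsilon`, `p` with the
#'   Greenhouse-Geisser correction applied where `df1 > 1`,
#'   `p_uncorrected`, `pes`), plus attribute `ss` with the full
#'   sum-of-squares table.
#' @export
rm_anova_2x3 <- function(values, p = 2, q = 3,
                         effect_names = c("preference", "context")) {
  Y <- as.matrix(values)
  if (any(is.na(Y))) stop("missing cells are not allowed")
  if (ncol(Y) != p * q) {
    stop(sprintf("expected %d columns (p * q cells), got %d", p * q,
                 ncol(Y)))
  }
  n <- nrow(Y)
  if (n < 2) stop("at least 2 subjects are required")
  A_idx <- rep(seq_len(p), each = q)
  B_idx <- rep(seq_len(q), times = p)
  gm <- mean(Y)
  subj_m <- rowMeans(Y)
  A_m <- vapply(seq_len(p), function(j) mean(Y[, A_idx == j]), numeric(1))
  B_m <- vapply(seq_len(q), function(k) mean(Y[, B_idx == k]), numeric(1))
  cell_m <- colMeans(Y)
  AS_m <- vapply(seq_len(p), function(j) {
    rowMeans(Y[, A_idx == j, drop = FALSE])
  }, numeric(n))
  BS_m <- vapply(seq_len(q), function(k) {
    rowMeans(Y[, B_idx == k, drop = FALSE])
  }, numeric(n))
  ss_total <- sum((Y - gm)^2)
  ss_subj <- p * q * sum((subj_m - gm)^2)
  ss_A <- n * q * sum((A_m - gm)^2)
  ss_B <- n * p * sum((B_m - gm)^2)
  ss_AB <- n * sum((cell_m - gm)^2) - ss_A - ss_B
  ss_AS <- q * sum((AS_m - gm)^2) - ss_A - ss_subj
  ss_BS <- p * sum((BS_m - gm)^2) - ss_B - ss_subj
  ss_ABS <- ss_total - ss_subj - ss_A - ss_B - ss_AB - ss_AS - ss_BS
  eff <- .effect_contrasts(p, q)
  gg_eps <- function(Cm) {
    Tm <- Y %*% t(Cm)
    S <- stats::cov(Tm)
    r <- nrow(Cm)
    if (r == 1) return(1)
    tr <- sum(diag(S))
    if (tr <= 0) return(1)
    (tr^2) / (r * sum(S^2))
  }
  row_for <- function(name, ss_eff, ss_err, df1, df2, eps) {
    if (ss_eff <= 1e-12 * max(ss_total, 1)) {
      f <- 0; p_un <- 1; p_gg <- 1; pes <- 0
    } else {
      f <- (ss_eff / df1) / (ss_err / df2)
      p_un <- stats::pf(f, df1, df2, lower.tail = FALSE)
      p_gg <- if (df1 > 1) {
        stats::pf(f, df1 * eps, df2 * eps, lower.tail = FALSE)
      } else {
        p_un
      }
      pes <- ss_eff / (ss_eff + ss_err)
    }
    data.frame(effect = name, df1 = df1, df2 = df2, F = f,
               epsilon = eps, p = p_gg, p_uncorrected = p_un, pes = pes,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    row_for(effect_names[1], ss_A, ss_AS, p - 1, (p - 1) * (n - 1),
            gg_eps(eff$A)),
    row_for(effect_names[2], ss_B, ss_BS, q - 1, (q - 1) * (n - 1),
            gg_eps(eff$B)),
    row_for(paste(effect_names, collapse = ":"), ss_AB, ss_ABS,
            (p - 1) * (q - 1), (p - 1) * (q - 1) * (n - 1),
            gg_eps(eff$AB))
  )
  structure(out,
            ss = c(total = ss_total, subjects = ss_subj, A = ss_A,
                   B = ss_B, AB = ss_AB, AS = ss_AS, BS = ss_BS,
                   ABS = ss_ABS),
            n = n,
            class = c("rm_anova", "data.frame"))
}

#' Bonferroni-adjusted post-hoc paired comparisons
#'
#' Paired t-tests between condition means following a within-subject
#' ANOVA; each raw p-value is multiplied by the number of comparisons in
#' the family and capped at 1.
#'
#' @param values Cell matrix as in [rm_anova_2x3()].
#' @param effect `"A"`/`"B"` for pairwise levels of a main effect
#'   (subject scores averaged over the other factor), or `"cells"` for all
#'   pairwise comparisons among the `p * q` cells.
#' @inheritParams rm_anova_2x3
#' @param level_names Optional level names for the chosen effect.
#' @return Data frame: `comparison`, mean difference `estimate`, `t`,
#'   `df`, `p_raw`, `p_adj`.
#' @export
bonferroni_posthoc <- function(values, effect = c("A", "B", "cells"),
                               p = 2, q = 3, level_names = NULL) {
  effect <- match.arg(effect)
  Y <- as.matrix(values)
  if (any(is.na(Y))) stop("missing cells are not allowed")
  A_idx <- rep(seq_len(p), each = q)
  B_idx <- rep(seq_len(q), times = p)
  scores <- switch(effect,
    A = vapply(seq_len(p), function(j) {
      rowMeans(Y[, A_idx == j, drop = FALSE])
    }, numeric(nrow(Y))),
    B = vapply(seq_len(q), function(k) {
      rowMeans(Y[, B_idx == k, drop = FALSE])
    }, numeric(nrow(Y))),
    cells = Y
  )
  nm <- if (!is.null(level_names)) {
    level_names
  } else if (effect == "cells" && !is.null(colnames(Y))) {
    colnames(Y)
  } else {
    paste0(if (effect == "cells") "cell" else effect, seq_len(ncol(scores)))
  }
  pairs <- utils::combn(ncol(scores), 2)
  m <- ncol(pairs)
  rows <- vector("list", m)
  for (idx in seq_len(m)) {
    i <- pairs[1, idx]; j <- pairs[2, idx]
    d <- scores[, i] - scores[, j]
    est <- mean(d)
    sd_d <- stats::sd(d)
    df <- length(d) - 1
    if (sd_d == 0) {
      tval <- if (est == 0) 0 else Inf * sign(est)
      p_raw <- if (est == 0) 1 else 0
    } else {
      tval <- est / (sd_d / sqrt(length(d)))
      p_raw <- 2 * stats::pt(-abs(tval), df)
    }
    rows[[idx]] <- data.frame(
      comparison = paste(nm[i], "vs", nm[j]), estimate = est, t = tval,
      df = df, p_raw = p_raw, p_adj = min(1, p_raw * m),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}
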