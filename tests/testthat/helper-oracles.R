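# Independent oracles used across the test files.  Each oracle is written
# from the defining formula, separately from the package implementation.

# frozen scikit-image colorimetry oracle (generated once by
# tools/make_oracles.py; D65 2-degree white on the Y = 100 scale)
skimage_white <- c(95.047, 100, 108.883)

read_colour_oracle <- function() {
  read.csv(test_path("oracle_colour.csv"))
}

read_srgb_oracle <- function() {
  read.csv(test_path("oracle_srgb.csv"))
}

# Box's Greenhouse-Geisser epsilon straight from the covariance matrix of
# the q condition scores (element-wise formula, no contrast matrices)
box_epsilon <- function(S) {
  q <- nrow(S)
  dbar <- mean(diag(S))
  sbar <- mean(S)
  num <- (q * (dbar - sbar))^2
  den <- (q - 1) * (sum(S^2) - 2 * q * mean(rowMeans(S)^2) * q +
                    q^2 * sbar^2)
  num / den
}

# textbook within-subject ANOVA via stats::aov with an Error() stratum
aov_oracle <- function(Y, p = 2, q = 3) {
  n <- nrow(Y)
  long <- data.frame(
    y = as.vector(t(Y)),
    subj = factor(rep(seq_len(n), each = p * q)),
    A = factor(rep(rep(seq_len(p), each = q), n)),
    B = factor(rep(rep(seq_len(q), p), n))
  )
  fit <- summary(stats::aov(y ~ A * B + Error(subj / (A * B)), data = long))
  get_row <- function(stratum, term) {
    tab <- fit[[stratum]][[1]]
    idx <- trimws(rownames(tab)) == term
    list(F = tab[idx, "F value"], p = tab[idx, "Pr(>F)"],
         ss = tab[idx, "Sum Sq"], ss_err = tab[trimws(rownames(tab)) ==
                                                 "Residuals", "Sum Sq"])
  }
  list(A = get_row("Error: subj:A", "A"),
       B = get_row("Error: subj:B", "B"),
       AB = get_row("Error: subj:A:B", "A:B"))
}

# exact two-sided signed-rank p-value by enumerating all sign assignments
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  mu <- n * (n + 1) / 4
  min(1, 2 * min(mean(v_all >= v_obs), mean(v_all <= v_obs)))
}

# significance matrix reconstructed from a letter display
letters_to_sig <- function(ld) {
  labs <- names(ld)
  k <- length(labs)
  m <- matrix(FALSE, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      m[i, j] <- m[j, i] <- !shares_letter(ld, labs[i], labs[j])
    }
  }
  m
}

# letter strings printed in the published bootstrap table, display order
table2_letters <- list(
  most.general  = c("a", "b", "b", "b", "abc", "ac", "bc", "b", "b"),
  least.general = c("ab", "a", "c", "ab", "ab", "ab", "b", "a", "ab"),
  most.walls    = c("a", "abc", "abc", "bc", "bc", "abc", "b", "abc", "ac"),
  least.walls   = c("a", "abc", "abc", "bc", "abc", "bc", "b", "abc", "ac"),
  most.tshirt   = c("a", "b", "bc", "bc", "bc", "abc", "abc", "bc", "ac"),
  least.tshirt  = c("abc", "ad", "d", "abc", "abc", "b", "b", "acd", "bc")
)

# shared-letter (non-significance) matrix implied by printed letter strings
printed_letter_sig <- function(lets) {
  k <- length(lets)
  m <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      sh <- length(intersect(strsplit(lets[i], "")[[1]],
                             strsplit(lets[j], "")[[1]])) > 0
      m[i, j] <- m[j, i] <- !sh
    }
  }
  m
}

# small complete within-subject choice dataset for pipeline tests
tiny_dataset <- function(n = 12, seed = 99) {
  generate_dataset(default_generator_config(n = n), seed = seed)
}
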