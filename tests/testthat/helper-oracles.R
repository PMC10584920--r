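# Independent oracles used across tests.

# Exhaustive PWM null-score distribution on the same discretization grid as
# the dynamic program: word scores are sums of per-position rounded units.
enumerate_pwm_word_units <- function(pwm, granularity = 1e-4) {
  k <- pwm$k
  units <- round(pwm$logodds / granularity)
  words <- as.matrix(expand.grid(rep(list(1:4), k)))
  wu <- numeric(nrow(words))
  for (i in seq_len(k)) wu <- wu + units[cbind(words[, i], i)]
  wu
}

enumerate_pwm_pvalues <- function(pwm, scores, granularity = 1e-4) {
  wu <- enumerate_pwm_word_units(pwm, granularity)
  vapply(scores, function(s) mean(wu >= round(s / granularity)), numeric(1))
}

# Exhaustive survival function over all 4^k words: P(U >= u) at every
# distinct word score u (integer units).
enumerate_pwm_survival <- function(pwm, granularity = 1e-4) {
  wu <- enumerate_pwm_word_units(pwm, granularity)
  tab <- table(wu)
  u <- as.numeric(names(tab))
  sf <- rev(cumsum(rev(as.numeric(tab)))) / length(wu)
  data.frame(units = u, sf = sf)
}

# Score-only global affine-gap alignment (Gotoh) oracle; checks the optimum
# found by the alignment engine used in percent_identity. Gap cost
# convention matches Biostrings: a gap of length L costs open + L * ext.
gotoh_score <- function(a, b, submat, gap_open = 10, gap_ext = 0.5) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  first <- gap_open + gap_ext
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - (i - 1) * gap_ext
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - (j - 1) * gap_ext
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[a[i - 1], b[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - first, X[i - 1, j] - gap_ext,
                     Y[i - 1, j] - first)
      Y[i, j] <- max(M[i, j - 1] - first, Y[i, j - 1] - gap_ext,
                     X[i, j - 1] - first)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Uniform enumeration of all perfect matchings of an n x n bipartite graph
# (all degrees one): every permutation of targets.
enumerate_matchings <- function(n) {
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms[apply(perms, 1, function(x) length(unique(x)) == n), , drop = FALSE]
}

# A small measurement table builder for scoring tests.
toy_measurements <- function(I, A, class, strain = NULL) {
  n <- length(I)
  data.frame(row = rep(1L, n), col = seq_len(n), A = A, I = I,
             missing = A == 0, touching = FALSE, low_confidence = FALSE,
             strain = strain %||% sprintf("s%d", seq_len(n)), class = class,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
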