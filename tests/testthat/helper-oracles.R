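# Independent oracles, coded separately from the package implementation.

# Single-component NIPALS PLS1: the reference the OPLS fit must reduce to
# when no orthogonal components are removed. Takes an already-scaled X and
# a centered numeric response.
pls1_oracle <- function(Xs, yc) {
  w <- t(Xs) %*% yc
  w <- w / sqrt(sum(w^2))
  t <- Xs %*% w
  p <- t(Xs) %*% t / sum(t^2)
  c <- sum(yc * t) / sum(t^2)
  list(w = drop(w), t = drop(t), p = drop(p), c = c,
       y_hat = drop(t) * c)
}

# Pairwise-enumeration Cliff's delta.
cliffs_delta_oracle <- function(x, y) {
  gt <- lt <- 0
  for (xi in x) {
    gt <- gt + sum(xi > y)
    lt <- lt + sum(xi < y)
  }
  (gt - lt) / (length(x) * length(y))
}

# Numerical quadrature of the area above CS under S(t) = a e^{bt} + c.
d_prime_quadrature <- function(a, b, cc, cs, t1, n = 200000) {
  t <- seq(0, t1, length.out = n + 1)
  s <- pmax(a * exp(b * t) + cc - cs, 0)
  sum((s[-1] + s[-length(s)]) / 2) * (t1 / n)
}

# All multisets (sorted vectors) of the given length over the given values.
all_multisets <- function(len, values) {
  if (len == 1) return(lapply(values, identity))
  grid <- do.call(expand.grid, rep(list(values), len))
  sorted <- unique(t(apply(as.matrix(grid), 1, sort)))
  lapply(seq_len(nrow(sorted)), function(i) sorted[i, ])
}

# Small fully-crossed cohort used across LMM tests: planted pre->post
# changes per trial on the log2 scale, participant intercepts, per-trial
# residual SDs.
make_lmm_data <- function(n_participants = 16,
                          change_by_trial = c(moderate = 0, heavy = 0,
                                              severe = 0),
                          sd_participant = 0.3,
                          sd_residual = c(moderate = 0.2, heavy = 0.2,
                                          severe = 0.2),
                          sex_effect = 0, seed = 1) {
  set.seed(seed)
  trials <- c("moderate", "heavy", "severe")
  grid <- expand.grid(timepoint = c("pre", "post"), trial = trials,
                      participant_id = sprintf("P%02d", 1:n_participants),
                      stringsAsFactors = FALSE)
  sex <- rep(c("male", "female"), length.out = n_participants)
  grid$sex <- sex[match(grid$participant_id,
                        sprintf("P%02d", 1:n_participants))]
  u <- rnorm(n_participants, 0, sd_participant)
  grid$value <- 5 +
    u[match(grid$participant_id, sprintf("P%02d", 1:n_participants))] +
    ifelse(grid$timepoint == "post", change_by_trial[grid$trial], 0) +
    ifelse(grid$sex == "male", sex_effect, 0) +
    rnorm(nrow(grid), 0, sd_residual[grid$trial])
  grid$metabolite_id <- "met1"
  class(grid) <- c("LongTable", "data.frame")
  grid
}

# Two-class fold-change-like matrix with a planted mean shift on a subset
# of columns; returns list(X, y).
make_two_class <- function(n_per_class = 12, p = 50, n_signal = 10,
                           shift = 2, noise_sd = 1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_class * p, 0, noise_sd), 2 * n_per_class, p)
  y <- rep(c("a", "b"), each = n_per_class)
  X[y == "b", seq_len(n_signal)] <- X[y == "b", seq_len(n_signal)] + shift
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = y)
}
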