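# Independent brute-force oracles: literal loop transcriptions of the ten
# feature definitions and the pair-counting AUC. Deliberately written as
# naive loops, independent of the package's vectorized implementations.

oracle_min <- function(x) {
  m <- x[1]
  for (v in x) if (v < m) m <- v
  m
}

oracle_max <- function(x) {
  m <- x[1]
  for (v in x) if (v > m) m <- v
  m
}

oracle_mean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}

oracle_sd <- function(x) {
  mu <- oracle_mean(x)
  s <- 0
  for (v in x) s <- s + (v - mu)^2
  sqrt(s / (length(x) - 1))
}

oracle_zc <- function(x) {
  n <- 0L
  for (i in seq_len(length(x) - 1))
    if (x[i] * x[i + 1] < 0) n <- n + 1L
  n
}

oracle_rms <- function(x) {
  s <- 0
  for (v in x) s <- s + v^2
  sqrt(s / length(x))
}

oracle_aac <- function(x) {
  s <- 0
  for (i in seq_len(length(x) - 1))
    s <- s + abs(x[i + 1] - x[i])
  s / (length(x) - 1)
}

oracle_afb <- function(x, threshold, window) {
  tc <- NA
  for (i in seq_along(x)) {
    if (x[i] >= threshold) { tc <- i; break }
  }
  if (is.na(tc)) return(0)
  hi <- min(tc + window, length(x))
  m <- x[tc]
  for (i in tc:hi) if (x[i] > m) m <- x[i]
  m
}

oracle_mav <- function(x) {
  s <- 0
  for (v in x) s <- s + abs(v)
  s / length(x)
}

oracle_len <- function(x) {
  s <- 0
  for (i in seq_len(length(x) - 1))
    s <- s + abs(x[i + 1] - x[i])
  s
}

oracle_wamp <- function(x, threshold) {
  n <- 0L
  for (i in seq_len(length(x) - 1))
    if (abs(x[i + 1] - x[i]) >= threshold) n <- n + 1L
  n
}

# AUC as explicit enumeration of positive-negative pairs, ties counted 1/2
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]
  sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

rel_equal <- function(a, b, tol = 1e-12) {
  abs(a - b) <= tol * pmax(1, abs(a), abs(b))
}
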