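# Independent brute-force metric implementations used as oracles.

bf_mse <- function(y, yhat) {
  s <- 0
  for (i in seq_along(y)) s <- s + (y[i] - yhat[i])^2
  s / length(y)
}

bf_cindex <- function(y, yhat, half = TRUE) {
  pairs <- expand.grid(i = seq_along(y), j = seq_along(y))
  pairs <- pairs[y[pairs$i] > y[pairs$j], ]
  conc <- ifelse(yhat[pairs$i] > yhat[pairs$j], 1,
                 ifelse(yhat[pairs$i] == yhat[pairs$j] & half, 0.5, 0))
  sum(conc) / nrow(pairs)
}

bf_spearman <- function(y, yhat) {
  d <- rank(y) - rank(yhat)
  1 - 6 * sum(d^2) / (length(y) * (length(y)^2 - 1))
}

bf_ef <- function(labels, scores, fraction) {
  ord <- order(-scores, seq_along(scores))
  m <- ceiling(fraction * length(labels))
  mean(labels[ord][1:m]) / mean(labels)
}

bf_bedroc <- function(labels, scores, alpha) {
  N <- length(labels)
  ord <- order(-scores, seq_along(scores))
  w <- function(ranks) sum(exp(-alpha * ranks / N))
  s <- w(which(labels[ord] == 1))
  n <- sum(labels)
  (s - w((N - n + 1):N)) / (w(1:n) - w((N - n + 1):N))
}
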