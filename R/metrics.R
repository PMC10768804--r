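# Evaluation statistics for affinity regression and virtual screening:
# MSE, concordance index, Spearman rank correlation, enrichment factor,
# BEDROC, the IC50 activity-labelling rule and a random-guessing baseline
# simulator.

#' Mean squared error
#'
#' @param y numeric vector of observed values.
#' @param yhat numeric vector of predictions, same length.
#' @return mean of squared residuals.
#' @export
#' @examples
#' mse(c(0, 0), c(1, 3))  # 5
mse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (length(y) < 1L) stop("need at least one observation")
  mean((y - yhat)^2)
}

#' Concordance index
#'
#' Fraction of pairs ordered by the true values whose predictions agree in
#' order. By default prediction ties receive half credit (Harrell's
#' convention). `ties = "strict"` scores a tied prediction as discordant,
#' i.e. only strictly concordant pairs count.
#'
#' @param y numeric observed values.
#' @param yhat numeric predictions.
#' @param ties "half" (default) or "strict".
#' @return concordance in \[0, 1\].
#' @export
c_index <- function(y, yhat, ties = c("half", "strict")) {
  ties <- match.arg(ties)
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  n <- length(y)
  if (n < 2L) stop("need at least two observations")
  num <- 0
  den <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (y[i] == y[j]) next
      den <- den + 1
      hi <- if (y[i] > y[j]) yhat[i] else yhat[j]
      lo <- if (y[i] > y[j]) yhat[j] else yhat[i]
      if (hi > lo) num <- num + 1
      else if (hi == lo && ties == "half") num <- num + 0.5
    }
  }
  if (den == 0) stop("concordance undefined: all observed values are equal")
  num / den
}

#' Spearman rank correlation
#'
#' Computed from the classical rank-difference closed form
#' `rho = 1 - 6 * sum(d^2) / (n (n^2 - 1))` on average (mid) ranks.
#'
#' @param y,yhat numeric vectors of equal length, neither constant.
#' @return correlation in \[-1, 1\].
#' @export
spearman_rho <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  n <- length(y)
  if (n < 2L) stop("need at least two observations")
  if (length(unique(y)) == 1L || length(unique(yhat)) == 1L) {
    stop("spearman undefined for a constant vector")
  }
  d <- rank(y, ties.method = "average") - rank(yhat, ties.method = "average")
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

#' Enrichment factor at a top fraction of the ranking
#'
#' Ratio of the active rate within the top `fraction` of items (descending
#' score, ties broken by original index) to the overall active rate. The
#' top-window size is `ceiling(fraction * N)`.
#'
#' @param labels binary 0/1 vector (1 = active).
#' @param scores numeric scores, higher means ranked earlier.
#' @param fraction top fraction in (0, 1); default 0.01 (EF1\%).
#' @return enrichment factor, bounded by `1 / fraction`.
#' @export
enrichment_factor <- function(labels, scores, fraction = 0.01) {
  stopifnot(length(labels) == length(scores))
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0,1)")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  n <- length(labels)
  npos <- sum(labels)
  if (npos == 0L) stop("enrichment factor undefined without positives")
  m <- ceiling(fraction * n)
  ord <- order(-scores, seq_len(n))
  top_pos <- sum(labels[ord[seq_len(m)]])
  (top_pos / m) / (npos / n)
}

#' BEDROC early-recognition score
#'
#' Exponentially rank-weighted score of Truchon and Bayly, min-max
#' normalised so that ranking every active first yields exactly 1 and
#' ranking every active last yields exactly 0:
#' `S = sum_i exp(-alpha r_i / N)` over active ranks `r_i`, mapped through
#' `(S - S_min) / (S_max - S_min)`.
#'
#' @param labels binary 0/1 vector with at least one 0 and one 1.
#' @param scores numeric scores, higher ranked earlier (index tie-break).
#' @param alpha early-recognition exponent (> 0); 80.5 focuses on roughly
#'   the top 2\% of the ranking.
#' @return BEDROC in \[0, 1\].
#' @export
bedroc <- function(labels, scores, alpha = 80.5) {
  stopifnot(length(labels) == length(scores))
  if (alpha <= 0) stop("alpha must be positive")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  n <- length(labels)
  npos <- sum(labels)
  if (npos == 0L || npos == n) stop("need at least one positive and one negative")
  ord <- order(-scores, seq_len(n))
  ranks <- which(labels[ord] == 1)
  s <- sum(exp(-alpha * ranks / n))
  smax <- sum(exp(-alpha * seq_len(npos) / n))
  smin <- sum(exp(-alpha * seq.int(n - npos + 1L, n) / n))
  (s - smin) / (smax - smin)
}

#' Label an interaction from its IC50
#'
#' Interactions with IC50 below 100 nM are positive, above 10,000 nM
#' negative; the intermediate band is excluded from classification sets.
#'
#' @param ic50_nM positive IC50 in nanomolar.
#' @return one of "positive", "negative", "excluded" (vectorised).
#' @export
label_activity <- function(ic50_nM) {
  if (any(!is.finite(ic50_nM)) || any(ic50_nM <= 0)) {
    stop("IC50 must be positive and finite")
  }
  out <- rep("excluded", length(ic50_nM))
  out[ic50_nM < 100] <- "positive"
  out[ic50_nM > 10000] <- "negative"
  out
}

#' Random-guessing screening baseline
#'
#' Assigns every item an independent Uniform(0,1) score and computes the
#' enrichment factor and BEDROC of that ranking, averaged over `n_reps`
#' independent repetitions.
#'
#' @param n_pos,n_neg class composition of the simulated screening set.
#' @param n_reps number of repetitions to average (default 3).
#' @param seed integer seed.
#' @param fraction EF top fraction (default 0.01).
#' @param alpha BEDROC exponent (default 80.5).
#' @return list with `ef`, `bedroc` (means), and per-rep vectors
#'   `ef_reps`, `bedroc_reps`.
#' @export
random_baseline <- function(n_pos, n_neg, n_reps = 3L, seed = 1L,
                            fraction = 0.01, alpha = 80.5) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, n_reps >= 1L)
  labels <- c(rep(1, n_pos), rep(0, n_neg))
  with_seed(seed, {
    efs <- numeric(n_reps)
    bds <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      scores <- stats::runif(n_pos + n_neg)
      efs[r] <- enrichment_factor(labels, scores, fraction)
      bds[r] <- bedroc(labels, scores, alpha)
    }
    list(ef = mean(efs), bedroc = mean(bds), ef_reps = efs, bedroc_reps = bds)
  })
}

#' Assemble a metrics report for a prediction table
#'
#' @param predictions data.frame with columns `y_true`, `y_pred`, and for
#'   per-target aggregation a `protein_id` column.
#' @param task "regression" or "classification".
#' @param per_target if TRUE also compute per-protein metrics and their
#'   averages (the aggregation used for screening tables).
#' @param ef_fraction,alpha screening-metric parameters.
#' @return object of class `metrics_report` (a list).
#' @export
evaluate_predictions <- function(predictions, task = c("regression", "classification"),
                                 per_target = FALSE, ef_fraction = 0.01,
                                 alpha = 80.5) {
  task <- match.arg(task)
  stopifnot(all(c("y_true", "y_pred") %in% names(predictions)))
  y <- predictions$y_true
  yh <- predictions$y_pred
  rep_one <- function(y, yh) {
    if (task == "regression") {
      list(mse = mse(y, yh),
           c_index = tryCatch(c_index(y, yh), error = function(e) NA_real_),
           spearman = tryCatch(spearman_rho(y, yh), error = function(e) NA_real_))
    } else {
      list(ef = tryCatch(enrichment_factor(y, yh, ef_fraction),
                         error = function(e) NA_real_),
           bedroc = tryCatch(bedroc(y, yh, alpha), error = function(e) NA_real_))
    }
  }
  out <- rep_one(y, yh)
  if (per_target) {
    stopifnot("protein_id" %in% names(predictions))
    per <- lapply(split(predictions, predictions$protein_id),
                  function(df) rep_one(df$y_true, df$y_pred))
    out$per_target <- per
    for (f in names(per[[1]])) {
      vals <- vapply(per, function(p) p[[f]], numeric(1))
      out[[paste0(f, "_per_target_mean")]] <- mean(vals, na.rm = TRUE)
      out[[paste0(f, "_per_target_sd")]] <- stats::sd(vals, na.rm = TRUE)
    }
  }
  out$task <- task
  out$n <- length(y)
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>", x$task, "on", x$n, "interactions\n")
  for (f in setdiff(names(x), c("task", "n", "per_target"))) {
    if (is.numeric(x[[f]])) cat(sprintf("  %-28s %.4f\n", f, x[[f]]))
  }
  invisible(x)
}
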