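# Lightweight reverse-mode automatic differentiation on dense matrices.
#
# All model training in this package (contrastive pretraining, the fusion
# network) runs on this engine. Values are numeric matrices; a tape records
# nodes in creation order, so iterating the tape backwards is a valid
# topological order for backpropagation. Parameters live in a parameter
# store (ps_*) and are materialised as leaf nodes once per tape so that
# gradients from multiple uses accumulate.

#' Create an empty autodiff tape
#'
#' @return an environment of class `ad_tape` recording nodes in creation
#'   order together with the parameter leaves materialised on it.
#' @keywords internal
ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t$leaves <- new.env(parent = emptyenv())
  class(t) <- "ad_tape"
  t
}

ad_node <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  class(nd) <- "ad_node"
  nd
}

ad_const <- function(tape, value) {
  ad_node(tape, as_ad_matrix(value))
}

as_ad_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

ad_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' Backpropagate from a scalar loss node through the tape
#' @keywords internal
ad_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  for (i in seq_len(tape$n)) tape$nodes[[i]]$grad <- NULL
  loss$grad <- matrix(1, 1L, 1L)
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible(NULL)
}

# ---- parameter store ---------------------------------------------------

#' Create a parameter store
#'
#' Holds named parameter matrices plus Adam moments and a set of frozen
#' parameter names excluded from updates.
#' @keywords internal
ps_new <- function() {
  ps <- new.env(parent = emptyenv())
  ps$values <- list()
  ps$m <- list()
  ps$v <- list()
  ps$step <- 0L
  ps$frozen <- character(0)
  class(ps) <- "param_store"
  ps
}

ps_add <- function(ps, name, value) {
  ps$values[[name]] <- as_ad_matrix(value)
  invisible(ps)
}

ps_init_dense <- function(ps, name, nin, nout, scale = NULL) {
  # Glorot-style init; callers must have seeded the RNG.
  if (is.null(scale)) scale <- sqrt(2 / (nin + nout))
  ps_add(ps, name, matrix(stats::rnorm(nin * nout, sd = scale), nin, nout))
}

ps_init_zero <- function(ps, name, nin, nout) {
  ps_add(ps, name, matrix(0, nin, nout))
}

#' Materialise a named parameter as a tape leaf (cached per tape)
#' @keywords internal
ad_p <- function(tape, ps, name) {
  nd <- tape$leaves[[name]]
  if (!is.null(nd)) return(nd)
  v <- ps$values[[name]]
  if (is.null(v)) stop("unknown parameter: ", name)
  nd <- ad_node(tape, v)
  nd$param_name <- name
  tape$leaves[[name]] <- nd
  nd
}

ad_collect_grads <- function(tape) {
  out <- list()
  for (name in ls(tape$leaves)) {
    nd <- tape$leaves[[name]]
    out[[name]] <- if (is.null(nd$grad)) 0 * nd$value else nd$grad
  }
  out
}

#' One Adam update over unfrozen parameters
#' @keywords internal
adam_step <- function(ps, grads, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  ps$step <- ps$step + 1L
  t <- ps$step
  for (name in names(grads)) {
    if (name %in% ps$frozen) next
    g <- grads[[name]]
    if (is.null(ps$m[[name]])) {
      ps$m[[name]] <- 0 * g
      ps$v[[name]] <- 0 * g
    }
    ps$m[[name]] <- beta1 * ps$m[[name]] + (1 - beta1) * g
    ps$v[[name]] <- beta2 * ps$v[[name]] + (1 - beta2) * g * g
    mhat <- ps$m[[name]] / (1 - beta1^t)
    vhat <- ps$v[[name]] / (1 - beta2^t)
    upd <- ps$values[[name]] - lr * mhat / (sqrt(vhat) + eps)
    dimnames(upd) <- NULL
    ps$values[[name]] <- upd
  }
  invisible(ps)
}

# ---- elementwise and linear-algebra ops --------------------------------

ad_add <- function(a, b, tape) {
  ad_node(tape, a$value + b$value, list(a, b), function(nd) {
    ad_accum(a, nd$grad)
    ad_accum(b, nd$grad)
  })
}

ad_sub <- function(a, b, tape) {
  ad_node(tape, a$value - b$value, list(a, b), function(nd) {
    ad_accum(a, nd$grad)
    ad_accum(b, -nd$grad)
  })
}

ad_mul <- function(a, b, tape) {
  ad_node(tape, a$value * b$value, list(a, b), function(nd) {
    ad_accum(a, nd$grad * b$value)
    ad_accum(b, nd$grad * a$value)
  })
}

ad_scale <- function(a, s, tape) {
  ad_node(tape, a$value * s, list(a), function(nd) ad_accum(a, nd$grad * s))
}

ad_add_num <- function(a, x, tape) {
  ad_node(tape, a$value + x, list(a), function(nd) ad_accum(a, nd$grad))
}

# multiply each column by a fixed numeric column vector (no grad through v)
ad_mul_colvec <- function(a, v, tape) {
  ad_node(tape, a$value * v, list(a), function(nd) ad_accum(a, nd$grad * v))
}

ad_matmul <- function(a, b, tape) {
  ad_node(tape, a$value %*% b$value, list(a, b), function(nd) {
    ad_accum(a, nd$grad %*% t(b$value))
    ad_accum(b, t(a$value) %*% nd$grad)
  })
}

# a %*% t(b) without an explicit transpose node
ad_matmul_bt <- function(a, b, tape) {
  ad_node(tape, tcrossprod(a$value, b$value), list(a, b), function(nd) {
    ad_accum(a, nd$grad %*% b$value)
    ad_accum(b, crossprod(nd$grad, a$value))
  })
}

# add a 1 x d bias row to every row of an n x d matrix
ad_addbias <- function(a, b, tape) {
  ad_node(tape, sweep(a$value, 2L, as.vector(b$value), "+"), list(a, b),
          function(nd) {
    ad_accum(a, nd$grad)
    ad_accum(b, matrix(colSums(nd$grad), 1L))
  })
}

# multiply every row elementwise by a 1 x d gain row
ad_mul_rowvec <- function(a, b, tape) {
  ad_node(tape, sweep(a$value, 2L, as.vector(b$value), "*"), list(a, b),
          function(nd) {
    ad_accum(a, sweep(nd$grad, 2L, as.vector(b$value), "*"))
    ad_accum(b, matrix(colSums(nd$grad * a$value), 1L))
  })
}

ad_relu <- function(a, tape) {
  mask <- a$value > 0
  ad_node(tape, a$value * mask, list(a), function(nd) {
    ad_accum(a, nd$grad * mask)
  })
}

ad_leakyrelu <- function(a, tape, slope = 0.01) {
  mask <- ifelse(a$value > 0, 1, slope)
  ad_node(tape, a$value * mask, list(a), function(nd) {
    ad_accum(a, nd$grad * mask)
  })
}

ad_sigmoid <- function(a, tape) {
  s <- 1 / (1 + exp(-a$value))
  ad_node(tape, s, list(a), function(nd) ad_accum(a, nd$grad * s * (1 - s)))
}

ad_softplus <- function(a, tape) {
  v <- a$value
  # stable: log(1 + e^v) = max(v, 0) + log1p(exp(-|v|))
  out <- pmax(v, 0) + log1p(exp(-abs(v)))
  ad_node(tape, out, list(a), function(nd) {
    ad_accum(a, nd$grad / (1 + exp(-v)))
  })
}

ad_exp <- function(a, tape) {
  e <- exp(a$value)
  ad_node(tape, e, list(a), function(nd) ad_accum(a, nd$grad * e))
}

ad_log <- function(a, tape) {
  ad_node(tape, log(a$value), list(a), function(nd) {
    ad_accum(a, nd$grad / a$value)
  })
}

ad_sum <- function(a, tape) {
  dims <- dim(a$value)
  ad_node(tape, matrix(sum(a$value), 1L, 1L), list(a), function(nd) {
    ad_accum(a, matrix(nd$grad[1L], dims[1L], dims[2L]))
  })
}

ad_mean <- function(a, tape) {
  dims <- dim(a$value)
  n <- length(a$value)
  ad_node(tape, matrix(mean(a$value), 1L, 1L), list(a), function(nd) {
    ad_accum(a, matrix(nd$grad[1L] / n, dims[1L], dims[2L]))
  })
}

ad_rowsums <- function(a, tape) {
  nc <- ncol(a$value)
  ad_node(tape, matrix(rowSums(a$value), ncol = 1L), list(a), function(nd) {
    ad_accum(a, matrix(nd$grad, nrow(a$value), nc))
  })
}

# column means -> 1 x d (mean pooling over rows)
ad_colmeans <- function(a, tape) {
  nr <- nrow(a$value)
  ad_node(tape, matrix(colMeans(a$value), 1L), list(a), function(nd) {
    ad_accum(a, matrix(rep(nd$grad / nr, each = nr), nr, ncol(a$value)))
  })
}

ad_softmax_rows <- function(a, tape) {
  v <- a$value
  m <- apply(v, 1L, max)
  e <- exp(v - m)
  s <- e / rowSums(e)
  ad_node(tape, s, list(a), function(nd) {
    g <- nd$grad
    ad_accum(a, s * (g - rowSums(g * s)))
  })
}

ad_l2normalize_rows <- function(a, tape, eps = 1e-12) {
  v <- a$value
  nrm <- sqrt(rowSums(v * v) + eps)
  y <- v / nrm
  ad_node(tape, y, list(a), function(nd) {
    g <- nd$grad
    ad_accum(a, (g - y * rowSums(g * y)) / nrm)
  })
}

# ---- reshaping / indexing ops ------------------------------------------

ad_rows <- function(a, idx, tape) {
  idx <- as.integer(idx)
  ad_node(tape, a$value[idx, , drop = FALSE], list(a), function(nd) {
    gz <- matrix(0, nrow(a$value), ncol(a$value))
    acc <- rowsum(nd$grad, group = idx)
    gz[as.integer(rownames(acc)), ] <- acc
    ad_accum(a, gz)
  })
}

ad_cols <- function(a, idx, tape) {
  idx <- as.integer(idx)
  ad_node(tape, a$value[, idx, drop = FALSE], list(a), function(nd) {
    gz <- matrix(0, nrow(a$value), ncol(a$value))
    for (j in seq_along(idx)) gz[, idx[j]] <- gz[, idx[j]] + nd$grad[, j]
    ad_accum(a, gz)
  })
}

ad_rbind <- function(nodes, tape) {
  vals <- lapply(nodes, function(x) x$value)
  nr <- vapply(vals, nrow, 1L)
  ends <- cumsum(nr)
  starts <- ends - nr + 1L
  ad_node(tape, do.call(rbind, vals), nodes, function(nd) {
    for (i in seq_along(nodes)) {
      ad_accum(nodes[[i]], nd$grad[starts[i]:ends[i], , drop = FALSE])
    }
  })
}

ad_cbind <- function(nodes, tape) {
  vals <- lapply(nodes, function(x) x$value)
  nc <- vapply(vals, ncol, 1L)
  ends <- cumsum(nc)
  starts <- ends - nc + 1L
  ad_node(tape, do.call(cbind, vals), nodes, function(nd) {
    for (i in seq_along(nodes)) {
      ad_accum(nodes[[i]], nd$grad[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

# Gather arbitrary elements of the column-major flattening of `a` into a new
# nrow_out x ncol_out matrix (repetition allowed). One primitive covers
# im2col for 1D/2D convolutions, reshapes, transposes and tiling.
ad_gather_flat <- function(a, flat_idx, nrow_out, ncol_out, tape) {
  flat_idx <- as.integer(flat_idx)
  dims <- dim(a$value)
  ad_node(tape,
          matrix(a$value[flat_idx], nrow_out, ncol_out),
          list(a), function(nd) {
    gv <- numeric(dims[1L] * dims[2L])
    acc <- rowsum(as.vector(nd$grad), group = flat_idx)
    gv[as.integer(rownames(acc))] <- acc
    ad_accum(a, matrix(gv, dims[1L], dims[2L]))
  })
}

# ---- segment (grouped-row) aggregation ---------------------------------

# Aggregate rows of `a` by integer group id in 1..ngroups. Groups may be
# empty (result row 0, no gradient). op: "sum", "mean", "max", "min", "sdev".
# sdev is the population standard deviation with a small eps for smooth
# gradients, as used by PNA aggregators.
ad_segment <- function(a, groups, ngroups, op, tape, eps = 1e-5) {
  groups <- as.integer(groups)
  v <- a$value
  d <- ncol(v)
  cnt <- tabulate(groups, nbins = ngroups)
  if (op %in% c("sum", "mean")) {
    acc <- rowsum(v, group = groups)
    out <- matrix(0, ngroups, d)
    gid <- as.integer(rownames(acc))
    out[gid, ] <- acc
    if (op == "mean") out[gid, ] <- out[gid, , drop = FALSE] / cnt[gid]
    return(ad_node(tape, out, list(a), function(nd) {
      g <- nd$grad[groups, , drop = FALSE]
      if (op == "mean") g <- g / cnt[groups]
      ad_accum(a, g)
    }))
  }
  if (op %in% c("max", "min")) {
    rows_by_group <- split(seq_along(groups), factor(groups, levels = seq_len(ngroups)))
    out <- matrix(0, ngroups, d)
    argrow <- matrix(NA_integer_, ngroups, d)
    for (gidx in seq_len(ngroups)) {
      rows <- rows_by_group[[gidx]]
      if (length(rows) == 0L) next
      sub <- v[rows, , drop = FALSE]
      if (op == "min") sub <- -sub
      w <- max.col(t(sub), ties.method = "first")  # per-column argmax
      sel <- sub[cbind(w, seq_len(d))]
      out[gidx, ] <- if (op == "min") -sel else sel
      argrow[gidx, ] <- rows[w]
    }
    return(ad_node(tape, out, list(a), function(nd) {
      gz <- matrix(0, nrow(v), d)
      for (gidx in seq_len(ngroups)) {
        rows <- argrow[gidx, ]
        if (anyNA(rows)) next
        ij <- cbind(rows, seq_len(d))
        gz[ij] <- gz[ij] + nd$grad[gidx, ]
      }
      ad_accum(a, gz)
    }))
  }
  if (op == "sdev") {
    acc <- rowsum(v, group = groups)
    acc2 <- rowsum(v * v, group = groups)
    mu <- matrix(0, ngroups, d)
    ex2 <- matrix(0, ngroups, d)
    gid <- as.integer(rownames(acc))
    mu[gid, ] <- acc / cnt[gid]
    ex2[gid, ] <- acc2 / cnt[gid]
    s <- sqrt(pmax(ex2 - mu * mu, 0) + eps)
    out <- s
    out[cnt == 0L, ] <- 0
    return(ad_node(tape, out, list(a), function(nd) {
      # d s/d x_i = (x_i - mu_g) / (n_g * s_g)
      g <- nd$grad[groups, , drop = FALSE]
      dev <- v - mu[groups, , drop = FALSE]
      ad_accum(a, g * dev / (cnt[groups] * s[groups, , drop = FALSE]))
    }))
  }
  stop("unknown segment op: ", op)
}

# row-wise layer normalisation (population variance), no affine part;
# compose with ad_mul_rowvec / ad_addbias for gain and bias
ad_rownorm <- function(a, tape, eps = 1e-5) {
  v <- a$value
  d <- ncol(v)
  mu <- rowMeans(v)
  va <- rowMeans(v * v) - mu * mu
  s <- sqrt(va + eps)
  y <- (v - mu) / s
  ad_node(tape, y, list(a), function(nd) {
    g <- nd$grad
    gm <- rowMeans(g)
    gym <- rowMeans(g * y)
    ad_accum(a, (g - gm - y * gym) / s)
  })
}

# ---- small shared helpers ----------------------------------------------

# dense layer: x %*% W + b with parameters named <prefix>.W / <prefix>.b
ad_dense <- function(x, ps, prefix, tape) {
  h <- ad_matmul(x, ad_p(tape, ps, paste0(prefix, ".W")), tape)
  ad_addbias(h, ad_p(tape, ps, paste0(prefix, ".b")), tape)
}

ps_init_dense_layer <- function(ps, prefix, nin, nout) {
  ps_init_dense(ps, paste0(prefix, ".W"), nin, nout)
  ps_init_zero(ps, paste0(prefix, ".b"), 1L, nout)
}

#' Evaluate a scalar-valued tape function and check its gradient numerically
#'
#' Used by the test-suite as the independent oracle for the AD engine.
#' `fn(ps)` must build a fresh tape, run a forward pass reading parameters
#' from `ps`, call [ad_backward()] and return `list(loss =, grads =)`.
#' @keywords internal
ad_gradcheck <- function(fn, ps, h = 1e-5) {
  res <- fn(ps)
  worst <- 0
  for (name in names(ps$values)) {
    v <- ps$values[[name]]
    g <- res$grads[[name]]
    for (k in seq_len(min(length(v), 5L))) {
      i <- if (length(v) <= 5L) k else sample.int(length(v), 1L)
      orig <- v[i]
      ps$values[[name]][i] <- orig + h
      lp <- fn(ps)$loss
      ps$values[[name]][i] <- orig - h
      lm <- fn(ps)$loss
      ps$values[[name]][i] <- orig
      num <- (lp - lm) / (2 * h)
      worst <- max(worst, abs(num - g[i]) / max(1, abs(num)))
    }
  }
  worst
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
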