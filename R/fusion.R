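# The fine-tuning network. Compound side: pretrained PNA node features
# ("what", keys/values) fused by cross-attention with learnable embeddings
# of the Morgan fingerprint's set bits ("where", queries). Protein side: a
# 1D convolutional tower over the atomic one-hot matrix ("what") fused
# with a 2D convolutional tower over the Fourier-mapped distance map
# ("where"). The pooled views are concatenated and passed through a
# two-layer MLP head; training minimises MSE (regression) or binary
# cross-entropy (classification).

#' Fusion network configuration
#'
#' @param embed_dim cross-attention embedding width C (divisible by
#'   `n_heads`).
#' @param n_heads number of attention heads.
#' @param fp_embed_dim width of fingerprint bit embeddings.
#' @param conv1d_channels,conv2d_channels channel widths of the three 1D /
#'   2D convolution layers.
#' @param conv1d_kernel,conv2d_kernel kernel sizes (odd).
#' @param conv1d_pool,conv2d_pool max-pool factors applied after each
#'   layer.
#' @param head_hidden hidden width of the MLP head.
#' @param fourier_F frequency pairs of the distance-map Fourier mapping.
#' @param lr,epochs,patience training defaults (Adam learning rate,
#'   full-batch epochs, early-stopping patience on validation loss; set
#'   `patience = Inf` to disable).
#' @return a `fusion_config` list.
#' @export
fusion_config <- function(embed_dim = 16L, n_heads = 2L, fp_embed_dim = 16L,
                          conv1d_channels = c(8L, 8L, 8L),
                          conv2d_channels = c(4L, 4L, 4L),
                          conv1d_kernel = 7L, conv2d_kernel = 3L,
                          conv1d_pool = 4L, conv2d_pool = 2L,
                          head_hidden = 32L, fourier_F = 4L,
                          lr = 1e-4, epochs = 50L, patience = Inf) {
  if (embed_dim %% n_heads != 0L) {
    stop("embed_dim must be divisible by n_heads")
  }
  structure(as.list(environment()), class = "fusion_config")
}

#' Assemble a model bundle around a pretrained compound encoder
#'
#' Copies the pretrained PNA (and 3D-encoder) parameters, initialises the
#' fingerprint table, attention projections, convolution towers and MLP
#' head, and applies the freeze mask.
#'
#' @param pretrained a `pretrain_result` from [pretrain()].
#' @param cfg a [fusion_config()].
#' @param task "regression" or "classification".
#' @param n_bits fingerprint length (rows of the lookup table).
#' @param freeze_fraction fraction of PNA depth to freeze in \[0, 0.95\].
#' @param seed integer seed for initialisation.
#' @return object of class `model_bundle`.
#' @export
model_bundle <- function(pretrained, cfg = fusion_config(),
                         task = c("regression", "classification"),
                         n_bits = 2048L, freeze_fraction = 0,
                         seed = 1L) {
  task <- match.arg(task)
  stopifnot(inherits(pretrained, "pretrain_result"))
  ps <- ps_new()
  for (nm in names(pretrained$ps$values)) {
    ps$values[[nm]] <- pretrained$ps$values[[nm]]
  }
  C <- cfg$embed_dim
  d <- pretrained$cfg$hidden_dim
  with_seed(seed, {
    ps_add(ps, "fp.table",
           matrix(stats::rnorm(n_bits * cfg$fp_embed_dim, sd = 0.1),
                  n_bits, cfg$fp_embed_dim))
    ps_init_dense_layer(ps, "catt.q", cfg$fp_embed_dim, C)
    ps_init_dense_layer(ps, "catt.k", d, C)
    ps_init_dense_layer(ps, "catt.v", d, C)
    ps_add(ps, "catt.ln.gain", matrix(1, 1, C))
    ps_add(ps, "catt.ln.bias", matrix(0, 1, C))
    n_in1 <- 64L  # atom-name (38) + amino-acid (21) + element (5)
    ch1 <- c(n_in1, cfg$conv1d_channels)
    for (i in 1:3) {
      ps_init_dense_layer(ps, paste0("p1.c", i),
                          cfg$conv1d_kernel * ch1[i], ch1[i + 1L])
    }
    ch2 <- c(2L * cfg$fourier_F + 1L, cfg$conv2d_channels)
    for (i in 1:3) {
      ps_init_dense_layer(ps, paste0("p2.c", i),
                          cfg$conv2d_kernel^2 * ch2[i], ch2[i + 1L])
    }
    ps_init_dense_layer(ps, "patt.q", ch2[4L], C)
    ps_init_dense_layer(ps, "patt.k", ch1[4L], C)
    ps_init_dense_layer(ps, "patt.v", ch1[4L], C)
    ps_add(ps, "patt.ln.gain", matrix(1, 1, C))
    ps_add(ps, "patt.ln.bias", matrix(0, 1, C))
    ps_init_dense_layer(ps, "head.z", 2L * C, cfg$head_hidden)
    ps_init_dense_layer(ps, "head.o", cfg$head_hidden, 1L)
  })
  mask <- freeze_mask(freeze_fraction, pretrained$cfg)
  apply_freeze(ps, mask)
  structure(list(ps = ps, cfg = cfg, pna_cfg = pretrained$cfg, task = task,
                 n_bits = n_bits, freeze = mask),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  npar <- sum(vapply(x$ps$values, length, 1L))
  cat("<model_bundle>", x$task, "-", length(x$ps$values),
      "parameter tensors (", npar, "values ),",
      length(x$ps$frozen), "frozen\n")
  invisible(x)
}

#' Embed the set bits of a fingerprint through the lookup table
#'
#' One embedding row is gathered per set bit, in bit order ("where" view).
#'
#' @param fp a `fingerprint_vector` with at least one set bit.
#' @param bundle a `model_bundle` (or a numeric table matrix).
#' @return n_set_bits x d matrix.
#' @export
embed_fingerprint <- function(fp, bundle) {
  stopifnot(inherits(fp, "fingerprint_vector"))
  if (length(fp$on_bits) == 0L) stop("fingerprint has no set bits")
  table <- if (is.matrix(bundle)) bundle else bundle$ps$values[["fp.table"]]
  if (fp$n_bits != nrow(table)) stop("fingerprint length does not match table")
  table[fp$on_bits, , drop = FALSE]
}

# multi-head scaled dot-product cross-attention on tape nodes;
# key_mask: logical, FALSE marks padded keys
ca_forward <- function(tape, ps, prefix, qsrc, kvsrc, n_heads,
                       key_mask = NULL) {
  Q <- ad_dense(qsrc, ps, paste0(prefix, ".q"), tape)
  K <- ad_dense(kvsrc, ps, paste0(prefix, ".k"), tape)
  V <- ad_dense(kvsrc, ps, paste0(prefix, ".v"), tape)
  C <- ncol(Q$value)
  dh <- C %/% n_heads
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    Qh <- ad_cols(Q, cols, tape)
    Kh <- ad_cols(K, cols, tape)
    Vh <- ad_cols(V, cols, tape)
    logits <- ad_scale(ad_matmul_bt(Qh, Kh, tape), 1 / sqrt(dh), tape)
    if (!is.null(key_mask) && any(!key_mask)) {
      pen <- matrix(0, nrow(Qh$value), length(key_mask))
      pen[, !key_mask] <- -1e30
      logits <- ad_add(logits, ad_const(tape, pen), tape)
    }
    A <- ad_softmax_rows(logits, tape)
    heads[[h]] <- ad_matmul(A, Vh, tape)
  }
  list(attended = ad_cbind(heads, tape), Q = Q)
}

# attention + residual on the query path + layer norm with learnable affine
ca_block <- function(tape, ps, prefix, qsrc, kvsrc, n_heads,
                     key_mask = NULL) {
  out <- ca_forward(tape, ps, prefix, qsrc, kvsrc, n_heads, key_mask)
  h <- ad_rownorm(ad_add(out$attended, out$Q, tape), tape)
  h <- ad_mul_rowvec(h, ad_p(tape, ps, paste0(prefix, ".ln.gain")), tape)
  ad_addbias(h, ad_p(tape, ps, paste0(prefix, ".ln.bias")), tape)
}

#' Multi-head cross-attention (standalone)
#'
#' `softmax(Q K^T / sqrt(C/h)) V` per head, heads concatenated. `params`
#' holds the three projections as matrices `Wq`, `bq`, `Wk`, `bk`, `Wv`,
#' `bv` (an identity projection is `W = diag, b = 0`).
#'
#' @param Q_src query-source matrix (nq x dq).
#' @param KV_src key/value-source matrix (nk x dk).
#' @param n_heads number of heads; the projected width must be divisible
#'   by it.
#' @param params named list of projection matrices.
#' @param key_mask optional logical vector; FALSE marks padded key rows
#'   excluded from the softmax.
#' @return fused matrix with `nrow(Q_src)` rows.
#' @export
cross_attention <- function(Q_src, KV_src, n_heads = 1L, params,
                            key_mask = NULL) {
  ps <- ps_new()
  ps_add(ps, "ca.q.W", params$Wq); ps_add(ps, "ca.q.b", params$bq)
  ps_add(ps, "ca.k.W", params$Wk); ps_add(ps, "ca.k.b", params$bk)
  ps_add(ps, "ca.v.W", params$Wv); ps_add(ps, "ca.v.b", params$bv)
  C <- ncol(as_ad_matrix(params$Wq))
  if (C %% n_heads != 0L) stop("projected width not divisible by n_heads")
  tape <- ad_tape()
  out <- ca_forward(tape, ps, "ca", ad_const(tape, as.matrix(Q_src)),
                    ad_const(tape, as.matrix(KV_src)), n_heads, key_mask)
  out$attended$value
}

# ---- convolution towers ------------------------------------------------

# "same"-padded 1D convolution along rows via an index gather (im2col):
# the input is augmented with one zero row that out-of-range taps map to
conv1d_node <- function(tape, x, ps, prefix, k, Cin) {
  Lin <- nrow(x$value)
  pad <- (k - 1L) %/% 2L
  xp <- ad_rbind(list(x, ad_const(tape, matrix(0, 1L, Cin))), tape)
  cc <- rep(seq_len(k * Cin), each = Lin)
  tt <- rep(seq_len(Lin), k * Cin)
  j <- (cc - 1L) %/% Cin + 1L
  ch <- (cc - 1L) %% Cin + 1L
  pos <- tt + j - 1L - pad
  pos[pos < 1L | pos > Lin] <- Lin + 1L
  flat <- (ch - 1L) * (Lin + 1L) + pos
  patches <- ad_gather_flat(xp, flat, Lin, k * Cin, tape)
  ad_leakyrelu(ad_dense(patches, ps, prefix, tape), tape)
}

maxpool1d_node <- function(tape, x, pool) {
  Lin <- nrow(x$value)
  groups <- ceiling(seq_len(Lin) / pool)
  ad_segment(x, groups, max(groups), "max", tape)
}

# 2D convolution over an Lx x Ly map stored as a (Lx*Ly) x C matrix with
# cell index = x + (y-1)*Lx
conv2d_node <- function(tape, x, ps, prefix, k, Cin, Lx, Ly) {
  pad <- (k - 1L) %/% 2L
  ncell <- Lx * Ly
  xp <- ad_rbind(list(x, ad_const(tape, matrix(0, 1L, Cin))), tape)
  cc <- rep(seq_len(k * k * Cin), each = ncell)
  cell <- rep(seq_len(ncell), k * k * Cin)
  tx <- (cell - 1L) %% Lx + 1L
  ty <- (cell - 1L) %/% Lx + 1L
  j <- (cc - 1L) %/% Cin + 1L
  ch <- (cc - 1L) %% Cin + 1L
  dx <- (j - 1L) %% k - pad
  dy <- (j - 1L) %/% k - pad
  px <- tx + dx
  py <- ty + dy
  prow <- px + (py - 1L) * Lx
  bad <- px < 1L | px > Lx | py < 1L | py > Ly
  prow[bad] <- ncell + 1L
  flat <- (ch - 1L) * (ncell + 1L) + prow
  patches <- ad_gather_flat(xp, flat, ncell, k * k * Cin, tape)
  ad_leakyrelu(ad_dense(patches, ps, prefix, tape), tape)
}

maxpool2d_node <- function(tape, x, pool, Lx, Ly) {
  ncell <- Lx * Ly
  cell <- seq_len(ncell)
  tx <- (cell - 1L) %% Lx + 1L
  ty <- (cell - 1L) %/% Lx + 1L
  gx <- ceiling(tx / pool)
  gy <- ceiling(ty / pool)
  Lxo <- ceiling(Lx / pool)
  groups <- gx + (gy - 1L) * Lxo
  list(node = ad_segment(x, groups, max(groups), "max", tape),
       Lx = Lxo, Ly = ceiling(Ly / pool))
}

# ---- encoders (tape level) ---------------------------------------------

comp_forward <- function(tape, bundle, mol) {
  ps <- bundle$ps
  batch <- batch_graphs(list(mol$graph))
  o_what <- pna_forward(tape, ps, bundle$pna_cfg, batch)$node_h
  o_where <- ad_rows(ad_p(tape, ps, "fp.table"), mol$fingerprint$on_bits,
                     tape)
  fused <- ca_block(tape, ps, "catt", o_where, o_what, bundle$cfg$n_heads)
  ad_colmeans(fused, tape)
}

prot_forward <- function(tape, bundle, pf) {
  ps <- bundle$ps
  cfg <- bundle$cfg
  # 1D tower over atoms
  h <- ad_const(tape, pf$A)
  ch1 <- c(ncol(pf$A), cfg$conv1d_channels)
  for (i in 1:3) {
    h <- conv1d_node(tape, h, ps, paste0("p1.c", i), cfg$conv1d_kernel,
                     ch1[i])
    h <- maxpool1d_node(tape, h, cfg$conv1d_pool)
  }
  t_what <- h
  # 2D tower over the Fourier-mapped distance map
  g <- ad_const(tape, pf$Gmat)
  ch2 <- c(ncol(pf$Gmat), cfg$conv2d_channels)
  Lx <- pf$L; Ly <- pf$L
  for (i in 1:3) {
    g <- conv2d_node(tape, g, ps, paste0("p2.c", i), cfg$conv2d_kernel,
                     ch2[i], Lx, Ly)
    pooled <- maxpool2d_node(tape, g, cfg$conv2d_pool, Lx, Ly)
    g <- pooled$node; Lx <- pooled$Lx; Ly <- pooled$Ly
  }
  t_where <- g
  fused <- ca_block(tape, ps, "patt", t_where, t_what, cfg$n_heads)
  ad_colmeans(fused, tape)
}

head_forward <- function(tape, bundle, xpair) {
  z <- ad_relu(ad_dense(xpair, bundle$ps, "head.z", tape), tape)
  ad_dense(z, bundle$ps, "head.o", tape)  # logits / raw outputs
}

#' Prepare the protein-side features consumed by the fusion network
#'
#' @param s a `protein_structure`.
#' @param cfg a [fusion_config()] (for the Fourier frequency count).
#' @return list with `A` (atom one-hot matrix), `Gmat` (L^2 x (2F+1)
#'   flattening of the Fourier features), `L`, `id`.
#' @export
protein_features <- function(s, cfg = fusion_config()) {
  afm <- build_atom_feature_matrix(s)
  D <- build_distance_map(s)
  G <- fourier_map(D, F = cfg$fourier_F)
  L <- nrow(D)
  Gmat <- matrix(G, L * L, dim(G)[3])
  list(A = afm$A, Gmat = Gmat, L = L, id = s$id)
}

#' Encode a compound into its fused representation
#'
#' PNA node features are the keys/values ("what"); fingerprint bit
#' embeddings are the queries ("where"); the attended queries pass through
#' a residual + layer-norm block and are mean-pooled.
#'
#' @param mol a `molecule_record`.
#' @param bundle a `model_bundle`.
#' @return numeric vector of length `embed_dim`.
#' @export
encode_compound <- function(mol, bundle) {
  tape <- ad_tape()
  as.vector(comp_forward(tape, bundle, mol)$value)
}

#' Encode a protein into its fused representation
#'
#' The 1D convolution tower over the atom matrix provides keys/values
#' ("what"); the 2D tower over the Fourier distance map provides queries
#' ("where"). Optional masks select valid rows (atoms / residues) before
#' the towers, so appending masked padding rows leaves the output
#' unchanged.
#'
#' @param pf output of [protein_features()] (or a `protein_structure`).
#' @param bundle a `model_bundle`.
#' @param atom_mask,res_mask optional logical validity masks over atom
#'   rows of `A` and residues of the distance map.
#' @return numeric vector of length `embed_dim`.
#' @export
encode_protein <- function(pf, bundle, atom_mask = NULL, res_mask = NULL) {
  if (inherits(pf, "protein_structure")) pf <- protein_features(pf, bundle$cfg)
  if (!is.null(atom_mask)) {
    if (length(atom_mask) != nrow(pf$A)) stop("atom_mask length mismatch")
    pf$A <- pf$A[atom_mask, , drop = FALSE]
  }
  if (!is.null(res_mask)) {
    if (length(res_mask) != pf$L) stop("res_mask length mismatch")
    G <- array(pf$Gmat, dim = c(pf$L, pf$L, ncol(pf$Gmat)))
    G <- G[res_mask, res_mask, , drop = FALSE]
    pf$L <- sum(res_mask)
    pf$Gmat <- matrix(G, pf$L * pf$L, dim(G)[3])
  }
  tape <- ad_tape()
  as.vector(prot_forward(tape, bundle, pf)$value)
}

#' Predict an interaction from encoded views
#'
#' Concatenation head: `z = relu(Wz [x_comp; x_prot] + bz)`,
#' `yhat = Wo z + bo`, passed through the logistic function for
#' classification bundles.
#'
#' @param x_comp,x_prot numeric vectors from [encode_compound()] /
#'   [encode_protein()].
#' @param bundle a `model_bundle`.
#' @return scalar prediction (affinity, or probability for
#'   classification).
#' @export
predict_interaction <- function(x_comp, x_prot, bundle) {
  tape <- ad_tape()
  xp <- ad_const(tape, matrix(c(x_comp, x_prot), 1L))
  out <- head_forward(tape, bundle, xp)$value[1L]
  if (bundle$task == "classification") 1 / (1 + exp(-out)) else out
}

# one full-batch forward pass; returns the prediction node (logits for
# classification) in interaction order
.fusion_forward <- function(tape, bundle, interactions, molecules, proteins) {
  comp_ids <- unique(interactions$compound_id)
  prot_ids <- unique(interactions$protein_id)
  xc <- ad_rbind(lapply(comp_ids, function(ci) {
    comp_forward(tape, bundle, molecules[[ci]])
  }), tape)
  xp <- ad_rbind(lapply(prot_ids, function(pi) {
    prot_forward(tape, bundle, proteins[[pi]])
  }), tape)
  pair <- ad_cbind(list(
    ad_rows(xc, match(interactions$compound_id, comp_ids), tape),
    ad_rows(xp, match(interactions$protein_id, prot_ids), tape)), tape)
  head_forward(tape, bundle, pair)
}

#' Train the fusion network
#'
#' Full-batch Adam. Each epoch encodes every unique compound and protein
#' once and reuses the encodings across interactions. The loss is MSE for
#' regression and logit binary cross-entropy for classification. Frozen
#' parameters (see [freeze_mask()]) are never updated. If `val_idx` is
#' given, training keeps the best-validation parameters and stops after
#' `cfg$patience` epochs without improvement.
#'
#' @param interactions data.frame with `compound_id`, `protein_id` and a
#'   `label` column (numeric, or 0/1 for classification).
#' @param molecules named list of `molecule_record`s keyed by compound id.
#' @param proteins named list of [protein_features()] outputs keyed by
#'   protein id.
#' @param bundle a `model_bundle` (modified in place and returned).
#' @param epochs,lr override the bundle config.
#' @param seed integer seed.
#' @param val_idx optional integer indices of validation interactions.
#' @return list of class `train_result`: `bundle`, `losses` (training
#'   loss per epoch), `val_losses` (if validation used).
#' @export
train_model <- function(interactions, molecules, proteins, bundle,
                        epochs = NULL, lr = NULL, seed = 1L,
                        val_idx = NULL) {
  stopifnot(inherits(bundle, "model_bundle"))
  if (nrow(interactions) == 0L) stop("empty interaction table")
  if (!all(interactions$compound_id %in% names(molecules))) {
    stop("missing molecule records for some interactions")
  }
  if (!all(interactions$protein_id %in% names(proteins))) {
    stop("missing protein features for some interactions")
  }
  y <- interactions$label
  if (any(!is.finite(y))) stop("labels must be finite")
  if (bundle$task == "classification" && !all(y %in% c(0, 1))) {
    stop("classification labels must be 0/1")
  }
  epochs <- if (is.null(epochs)) bundle$cfg$epochs else epochs
  lr <- if (is.null(lr)) bundle$cfg$lr else lr
  train_rows <- if (is.null(val_idx)) seq_len(nrow(interactions)) else
    setdiff(seq_len(nrow(interactions)), val_idx)
  tr <- interactions[train_rows, , drop = FALSE]
  ytr <- matrix(y[train_rows], ncol = 1L)
  losses <- numeric(0)
  val_losses <- numeric(0)
  best <- Inf
  best_values <- NULL
  wait <- 0L
  loss_node <- function(tape, pred, ycol) {
    yc <- ad_const(tape, ycol)
    if (bundle$task == "regression") {
      d <- ad_sub(pred, yc, tape)
      ad_mean(ad_mul(d, d, tape), tape)
    } else {
      ad_mean(ad_sub(ad_softplus(pred, tape), ad_mul(yc, pred, tape), tape),
              tape)
    }
  }
  with_seed(seed, for (ep in seq_len(epochs)) {
    tape <- ad_tape()
    pred <- .fusion_forward(tape, bundle, tr, molecules, proteins)
    loss <- loss_node(tape, pred, ytr)
    losses <- c(losses, loss$value[1L])
    ad_backward(tape, loss)
    adam_step(bundle$ps, ad_collect_grads(tape), lr = lr)
    if (!is.null(val_idx)) {
      vtape <- ad_tape()
      vpred <- .fusion_forward(vtape, bundle,
                               interactions[val_idx, , drop = FALSE],
                               molecules, proteins)
      vl <- loss_node(vtape, vpred, matrix(y[val_idx], ncol = 1L))$value[1L]
      val_losses <- c(val_losses, vl)
      if (vl < best - 1e-9) {
        best <- vl
        best_values <- bundle$ps$values
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= bundle$cfg$patience) break
      }
    }
  })
  if (!is.null(best_values)) bundle$ps$values <- best_values
  structure(list(bundle = bundle, losses = losses, val_losses = val_losses),
            class = "train_result")
}

#' Predict interactions with a trained bundle
#'
#' @param bundle a trained `model_bundle`.
#' @param interactions data.frame with `compound_id`, `protein_id`
#'   (a `label` column, if present, is copied to `y_true`).
#' @param molecules,proteins named feature lists as in [train_model()].
#' @return the interaction table with a `y_pred` column (probabilities for
#'   classification).
#' @export
predict_interactions <- function(bundle, interactions, molecules, proteins) {
  tape <- ad_tape()
  pred <- .fusion_forward(tape, bundle, interactions, molecules, proteins)
  out <- interactions
  p <- as.vector(pred$value)
  if (bundle$task == "classification") p <- 1 / (1 + exp(-p))
  out$y_pred <- p
  if ("label" %in% names(out)) out$y_true <- out$label
  out
}
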