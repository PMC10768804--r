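# Contrastive 3D pretraining. A principal-neighborhood-aggregation (PNA)
# encoder embeds the 2D molecular graph; a distance-based message-passing
# encoder embeds each conformer (rigid-motion invariant by construction,
# since it only consumes interatomic distances through a radial-basis
# expansion). The NT-Xent loss pulls the 2D embedding of a molecule toward
# the 3D embeddings of its own conformers and away from other molecules'.

#' PNA encoder configuration
#'
#' @param hidden_dim width of node representations.
#' @param n_layers number of message-passing layers (>= 1).
#' @param emb_dim graph-embedding width.
#' @param aggregators subset of mean/max/min/sdev (all four by default).
#' @param scalers subset of identity/amplification/attenuation.
#' @param readouts subset of min/max/mean/sum.
#' @param avg_degree average node degree of the training molecules; the
#'   degree-scaler normaliser. Set from data by [pretrain()].
#' @return a `pna_config` list.
#' @export
pna_config <- function(hidden_dim = 16L, n_layers = 2L, emb_dim = 16L,
                       aggregators = c("mean", "max", "min", "sdev"),
                       scalers = c("identity", "amplification", "attenuation"),
                       readouts = c("min", "max", "mean", "sum"),
                       avg_degree = 2) {
  stopifnot(n_layers >= 1L,
            all(aggregators %in% c("mean", "max", "min", "sdev")),
            all(scalers %in% c("identity", "amplification", "attenuation")),
            all(readouts %in% c("min", "max", "mean", "sum")),
            avg_degree > 0)
  structure(list(hidden_dim = hidden_dim, n_layers = n_layers,
                 emb_dim = emb_dim, aggregators = aggregators,
                 scalers = scalers, readouts = readouts,
                 avg_degree = avg_degree),
            class = "pna_config")
}

N_ATOM_FEATURES <- 27L
N_BOND_FEATURES <- 5L

#' Initialise PNA parameters into a store
#' @keywords internal
pna_init_params <- function(ps, cfg) {
  d <- cfg$hidden_dim
  nagg <- length(cfg$aggregators) * length(cfg$scalers)
  ps_init_dense_layer(ps, "pna.embed", N_ATOM_FEATURES, d)
  for (l in seq_len(cfg$n_layers)) {
    ps_init_dense_layer(ps, sprintf("pna.l%d.msg", l), d + N_BOND_FEATURES, d)
    ps_init_dense_layer(ps, sprintf("pna.l%d.upd", l), d + nagg * d, d)
  }
  ps_init_dense_layer(ps, "pna.read", length(cfg$readouts) * d, cfg$emb_dim)
  invisible(ps)
}

# Collate graphs into one node/edge batch. Edges are doubled (both
# directions) so aggregation is over incoming messages.
batch_graphs <- function(graphs) {
  nn <- vapply(graphs, function(g) g$n_atoms, 1L)
  offs <- cumsum(c(0L, nn[-length(nn)]))
  X <- do.call(rbind, lapply(graphs, function(g) g$node_features))
  src <- integer(0); dst <- integer(0); bf <- NULL
  for (k in seq_along(graphs)) {
    e <- graphs[[k]]$edges
    if (nrow(e) > 0L) {
      src <- c(src, e[, "i"] + offs[k], e[, "j"] + offs[k])
      dst <- c(dst, e[, "j"] + offs[k], e[, "i"] + offs[k])
      bf <- rbind(bf, graphs[[k]]$bond_features, graphs[[k]]$bond_features)
    }
  }
  if (is.null(bf)) bf <- matrix(0, 0L, N_BOND_FEATURES)
  list(X = X, src = src, dst = dst, bond_features = bf,
       mol_of_node = rep(seq_along(graphs), nn),
       degree = tabulate(dst, nbins = sum(nn)), n_nodes = sum(nn),
       n_mols = length(graphs))
}

# PNA forward pass on a batch; returns node representations and graph
# embeddings as tape nodes.
pna_forward <- function(tape, ps, cfg, batch) {
  d <- cfg$hidden_dim
  n <- batch$n_nodes
  h <- ad_leakyrelu(ad_dense(ad_const(tape, batch$X), ps, "pna.embed", tape),
                    tape)
  deg <- batch$degree
  s_amp <- log(deg + 1) / log(cfg$avg_degree + 1)
  s_att <- ifelse(deg > 0, 1 / pmax(s_amp, 1e-12), 0)
  for (l in seq_len(cfg$n_layers)) {
    if (length(batch$src) > 0L) {
      m_in <- ad_cbind(list(ad_rows(h, batch$src, tape),
                            ad_const(tape, batch$bond_features)), tape)
      msg <- ad_leakyrelu(ad_dense(m_in, ps, sprintf("pna.l%d.msg", l), tape),
                          tape)
      aggs <- list()
      for (ag in cfg$aggregators) {
        base <- ad_segment(msg, batch$dst, n, ag, tape)
        for (sc in cfg$scalers) {
          aggs[[length(aggs) + 1L]] <- switch(sc,
            identity = base,
            amplification = ad_mul_colvec(base, s_amp, tape),
            attenuation = ad_mul_colvec(base, s_att, tape))
        }
      }
    } else {
      nagg <- length(cfg$aggregators) * length(cfg$scalers)
      aggs <- list(ad_const(tape, matrix(0, n, nagg * d)))
    }
    upd_in <- ad_cbind(c(list(h), aggs), tape)
    h <- ad_leakyrelu(ad_dense(upd_in, ps, sprintf("pna.l%d.upd", l), tape),
                      tape)
  }
  reads <- lapply(cfg$readouts, function(rd) {
    op <- if (rd == "sum") "sum" else rd
    ad_segment(h, batch$mol_of_node, batch$n_mols, op, tape)
  })
  emb <- ad_dense(ad_cbind(reads, tape), ps, "pna.read", tape)
  list(node_h = h, graph_emb = emb)
}

#' Encode a molecular graph with the PNA encoder
#'
#' @param graph a `molecular_graph`.
#' @param cfg a [pna_config()].
#' @param ps parameter store holding PNA parameters (see
#'   [pna_init_params()] / [pretrain()]).
#' @return list with `embedding` (numeric vector, length `emb_dim`) and
#'   `node_features` (n_atoms x hidden_dim matrix): the "what" view.
#' @export
encode_2d <- function(graph, cfg, ps) {
  stopifnot(inherits(graph, "molecular_graph"), graph$n_atoms >= 1L)
  tape <- ad_tape()
  out <- pna_forward(tape, ps, cfg, batch_graphs(list(graph)))
  list(embedding = as.vector(out$graph_emb$value),
       node_features = out$node_h$value)
}

# ---- 3D conformer encoder ----------------------------------------------

E3D_RBF_CENTERS <- seq(0, 8, length.out = 16L)
E3D_RBF_SIGMA <- 0.6
E3D_ROUNDS <- 3L

rbf_expand <- function(d) {
  exp(-(outer(d, E3D_RBF_CENTERS, "-") / E3D_RBF_SIGMA)^2)
}

e3d_init_params <- function(ps, cfg) {
  d <- cfg$hidden_dim
  ps_init_dense_layer(ps, "e3d.embed", N_ATOM_FEATURES, d)
  for (r in seq_len(E3D_ROUNDS)) {
    ps_init_dense_layer(ps, sprintf("e3d.r%d.gate", r), 16L, d)
    ps_init_dense_layer(ps, sprintf("e3d.r%d.src", r), d, d)
    ps_init_dense_layer(ps, sprintf("e3d.r%d.upd", r), 2L * d, d)
  }
  ps_init_dense_layer(ps, "e3d.read", 2L * d, cfg$emb_dim)
  invisible(ps)
}

e3d_forward <- function(tape, ps, cfg, graph, coords) {
  n <- graph$n_atoms
  if (any(!is.finite(coords))) stop("non-finite conformer coordinates")
  if (nrow(coords) != n) stop("conformer rows do not match graph nodes")
  h <- ad_leakyrelu(ad_dense(ad_const(tape, graph$node_features), ps,
                             "e3d.embed", tape), tape)
  if (n > 1L) {
    pr <- which(matrix(TRUE, n, n) & !diag(TRUE, n), arr.ind = TRUE)
    src <- pr[, 2L]; dst <- pr[, 1L]
    dists <- sqrt(rowSums((coords[src, , drop = FALSE] -
                             coords[dst, , drop = FALSE])^2))
    rbf <- ad_const(tape, rbf_expand(dists))
    for (r in seq_len(E3D_ROUNDS)) {
      gate <- ad_sigmoid(ad_dense(rbf, ps, sprintf("e3d.r%d.gate", r), tape),
                         tape)
      hs <- ad_dense(ad_rows(h, src, tape), ps, sprintf("e3d.r%d.src", r),
                     tape)
      m <- ad_segment(ad_mul(gate, hs, tape), dst, n, "mean", tape)
      h <- ad_leakyrelu(ad_dense(ad_cbind(list(h, m), tape), ps,
                                 sprintf("e3d.r%d.upd", r), tape), tape)
    }
  }
  read <- ad_cbind(list(ad_segment(h, rep(1L, n), 1L, "mean", tape),
                        ad_segment(h, rep(1L, n), 1L, "sum", tape)), tape)
  ad_dense(read, ps, "e3d.read", tape)
}

#' Encode one conformer with the 3D message-passing encoder
#'
#' The encoder sees coordinates only through interatomic distances
#' (Gaussian radial basis, 16 centres on 0-8 A), so its output is
#' invariant to global rotations and translations by construction.
#'
#' @param graph a `molecular_graph`.
#' @param coords n_atoms x 3 coordinate matrix (Angstrom).
#' @param cfg a [pna_config()] (shares widths with the 2D encoder).
#' @param ps parameter store holding `e3d.*` parameters.
#' @return numeric embedding vector of length `emb_dim`.
#' @export
encode_3d <- function(graph, coords, cfg, ps) {
  tape <- ad_tape()
  as.vector(e3d_forward(tape, ps, cfg, graph, coords)$value)
}

# ---- NT-Xent loss ------------------------------------------------------

# builds the loss as a tape node; z2d: N x d node, z3d: (sum c_i) x d node,
# mol_of_conf: molecule index of each z3d row
ntxent_node <- function(tape, z2d, z3d, mol_of_conf, tau,
                        exclude_positive = TRUE) {
  N <- nrow(z2d$value)
  sims <- ad_matmul_bt(ad_l2normalize_rows(z2d, tape),
                       ad_l2normalize_rows(z3d, tape), tape)
  S <- ad_exp(ad_scale(sims, 1 / tau, tape), tape)
  pos_mask <- outer(seq_len(N), mol_of_conf, "==") * 1
  neg_mask <- if (exclude_positive) 1 - pos_mask else
    matrix(1, N, length(mol_of_conf))
  num <- ad_rowsums(ad_mul(S, ad_const(tape, pos_mask), tape), tape)
  den <- ad_rowsums(ad_mul(S, ad_const(tape, neg_mask), tape), tape)
  per_mol <- ad_sub(ad_log(num, tape), ad_log(den, tape), tape)
  ad_scale(ad_mean(per_mol, tape), -1, tape)
}

#' NT-Xent contrastive loss between 2D and 3D embeddings
#'
#' Normalised temperature-scaled cross-entropy with cosine similarity.
#' For molecule i the numerator sums `exp(sim(z2d_i, z3d_ij)/tau)` over
#' its own conformers j; the denominator sums over the conformers of all
#' other molecules (k != i). With `exclude_positive = FALSE` the positive
#' terms are also included in the denominator (the canonical NT-Xent
#' convention); the default follows the printed form, under which the
#' loss of an all-identical embedding batch with one conformer each is
#' exactly `log(N - 1)` and the loss may be negative.
#'
#' @param z2d N x d matrix of graph embeddings.
#' @param z3d matrix of conformer embeddings (one row per conformer).
#' @param mol_of_conf integer vector mapping each z3d row to its molecule.
#' @param tau temperature (> 0).
#' @param exclude_positive see above.
#' @return scalar loss.
#' @export
ntxent_loss <- function(z2d, z3d, mol_of_conf, tau = 0.1,
                        exclude_positive = TRUE) {
  if (tau <= 0) stop("tau must be positive")
  z2d <- as.matrix(z2d); z3d <- as.matrix(z3d)
  if (nrow(z2d) < 2L) stop("NT-Xent needs at least two molecules")
  if (nrow(z3d) != length(mol_of_conf)) {
    stop("mol_of_conf must map every conformer embedding row")
  }
  if (any(!is.finite(z2d)) || any(!is.finite(z3d))) {
    stop("embeddings must be finite")
  }
  tape <- ad_tape()
  nd <- ntxent_node(tape, ad_const(tape, z2d), ad_const(tape, z3d),
                    mol_of_conf, tau, exclude_positive)
  nd$value[1L]
}

# ---- pretraining loop --------------------------------------------------

#' Contrastive pretraining of the PNA encoder on conformer-bearing molecules
#'
#' Full-batch Adam on the NT-Xent loss between PNA graph embeddings and
#' 3D conformer embeddings. The degree normaliser of the PNA scalers
#' (`avg_degree`) is computed once from the input molecules.
#'
#' @param molecules list of `molecule_record`s, each with >= 1 conformer.
#' @param cfg a [pna_config()].
#' @param epochs number of full-batch epochs.
#' @param seed integer seed (initialisation).
#' @param tau temperature.
#' @param lr Adam learning rate.
#' @param exclude_positive NT-Xent denominator convention (see
#'   [ntxent_loss()]).
#' @return list of class `pretrain_result`: `ps` (parameter store), `cfg`
#'   (with avg_degree filled), `losses` (per epoch, including the final
#'   state), `seed`.
#' @export
pretrain <- function(molecules, cfg = pna_config(), epochs = 30L, seed = 1L,
                     tau = 0.1, lr = 1e-3, exclude_positive = TRUE) {
  if (length(molecules) < 2L) {
    stop("pretraining needs at least two molecules (NT-Xent is undefined for N=1)")
  }
  nconf <- vapply(molecules, function(m) length(m$conformers), 1L)
  if (any(nconf == 0L)) stop("every molecule needs at least one conformer")
  graphs <- lapply(molecules, function(m) m$graph)
  batch <- batch_graphs(graphs)
  cfg$avg_degree <- max(mean(batch$degree), 1e-6)
  ps <- ps_new()
  with_seed(seed, {
    pna_init_params(ps, cfg)
    e3d_init_params(ps, cfg)
  })
  mol_of_conf <- rep(seq_along(molecules), nconf)
  losses <- numeric(epochs + 1L)
  for (ep in seq_len(epochs + 1L)) {
    tape <- ad_tape()
    z2d <- pna_forward(tape, ps, cfg, batch)$graph_emb
    z3d_rows <- list()
    for (i in seq_along(molecules)) {
      for (cf in molecules[[i]]$conformers) {
        z3d_rows[[length(z3d_rows) + 1L]] <-
          e3d_forward(tape, ps, cfg, graphs[[i]], cf)
      }
    }
    loss <- ntxent_node(tape, z2d, ad_rbind(z3d_rows, tape), mol_of_conf,
                        tau, exclude_positive)
    losses[ep] <- loss$value[1L]
    if (ep > epochs) break  # final loss recorded without updating
    ad_backward(tape, loss)
    adam_step(ps, ad_collect_grads(tape), lr = lr)
  }
  structure(list(ps = ps, cfg = cfg, losses = losses, seed = seed),
            class = "pretrain_result")
}

#' @export
print.pretrain_result <- function(x, ...) {
  cat("<pretrain_result>", length(x$losses) - 1L, "epochs; NT-Xent",
      sprintf("%.4f -> %.4f", x$losses[1L], x$losses[length(x$losses)]), "\n")
  invisible(x)
}

# ---- freezing ----------------------------------------------------------

#' Build a freeze mask over the PNA depth
#'
#' Covers the first `floor(fraction * n_layers)` PNA message-passing
#' layers counted from the input (their message and update parameters).
#'
#' @param fraction fraction of PNA depth to freeze, in \[0, 0.95\].
#' @param cfg the [pna_config()] of the trained encoder.
#' @return list of class `freeze_mask` with `fraction` and
#'   `frozen_parameter_ids`.
#' @export
freeze_mask <- function(fraction, cfg) {
  if (!is.numeric(fraction) || fraction < 0 || fraction > 0.95) {
    stop("freeze fraction must lie in [0, 0.95]")
  }
  k <- floor(fraction * cfg$n_layers)
  ids <- character(0)
  if (k >= 1L) {
    ids <- as.vector(vapply(seq_len(k), function(l) {
      c(sprintf("pna.l%d.msg.W", l), sprintf("pna.l%d.msg.b", l),
        sprintf("pna.l%d.upd.W", l), sprintf("pna.l%d.upd.b", l))
    }, character(4L)))
  }
  structure(list(fraction = fraction, frozen_parameter_ids = ids),
            class = "freeze_mask")
}

#' Apply a freeze mask to a parameter store
#'
#' Frozen parameters are excluded from optimiser updates and remain
#' bitwise unchanged through training.
#'
#' @param ps a parameter store.
#' @param mask a [freeze_mask()].
#' @return the store, with its frozen set replaced.
#' @export
apply_freeze <- function(ps, mask) {
  stopifnot(inherits(mask, "freeze_mask"))
  missing <- setdiff(mask$frozen_parameter_ids, names(ps$values))
  if (length(missing) > 0L) {
    stop("freeze mask names unknown parameters: ",
         paste(missing, collapse = ", "))
  }
  ps$frozen <- mask$frozen_parameter_ids
  invisible(ps)
}
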