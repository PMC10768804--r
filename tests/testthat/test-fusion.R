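identity_ca_params <- function(d = 1L) {
  list(Wq = diag(d), bq = matrix(0, 1, d),
       Wk = diag(d), bk = matrix(0, 1, d),
       Wv = diag(d), bv = matrix(0, 1, d))
}

test_that("cross-attention reduces to projected values for a single key", {
  set.seed(41)
  p <- list(Wq = matrix(rnorm(12), 3, 4), bq = matrix(0, 1, 4),
            Wk = matrix(rnorm(8), 2, 4), bk = matrix(rnorm(4), 1),
            Wv = matrix(rnorm(8), 2, 4), bv = matrix(rnorm(4), 1))
  KV <- matrix(rnorm(2), 1, 2)
  Q <- matrix(rnorm(15), 5, 3)
  out <- cross_attention(Q, KV, n_heads = 2L, p)
  projected_v <- sweep(KV %*% p$Wv, 2, as.vector(p$bv), "+")
  for (r in 1:5) expect_equal(out[r, ], as.vector(projected_v),
                              tolerance = 1e-12)
})

test_that("equal key logits average the projected values", {
  # two identical keys -> softmax weights 1/2 each
  p <- identity_ca_params(1L)
  out <- cross_attention(matrix(0.3), rbind(1, 1) * 0.7, n_heads = 1L, p)
  expect_equal(out[1, 1], 0.7, tolerance = 1e-12)
  # different values, equal logits (zero query)
  out2 <- cross_attention(matrix(0), rbind(1, -1), n_heads = 1L, p)
  # keys 1,-1 with q=0 -> equal weights -> mean of values
  expect_equal(out2[1, 1], 0, tolerance = 1e-12)
})

test_that("hand-computed softmax weighting is reproduced", {
  # h = 1, C = 1, identity query/key projections, Q = 2, K = (1, -1);
  # Wv/bv chosen so the projected values are (1, 0)
  p <- identity_ca_params(1L)
  p$Wv <- matrix(0.5); p$bv <- matrix(0.5)
  out <- cross_attention(matrix(2), rbind(1, -1), n_heads = 1L, p)
  w <- exp(2) / (exp(2) + exp(-2))  # 0.98201...
  expect_equal(out[1, 1], w, tolerance = 1e-9)
  expect_equal(out[1, 1], 0.9820, tolerance = 1e-4)
})

test_that("attention outputs are convex combinations of projected values", {
  set.seed(42)
  for (rep in 1:10) {
    nq <- sample(1:4, 1); nk <- sample(1:5, 1)
    dq <- sample(2:4, 1); dk <- sample(2:4, 1); C <- 4L
    p <- list(Wq = matrix(rnorm(dq * C), dq, C), bq = matrix(0, 1, C),
              Wk = matrix(rnorm(dk * C), dk, C), bk = matrix(0, 1, C),
              Wv = matrix(rnorm(dk * C), dk, C), bv = matrix(rnorm(C), 1))
    Q <- matrix(rnorm(nq * dq), nq, dq)
    KV <- matrix(rnorm(nk * dk), nk, dk)
    out <- cross_attention(Q, KV, n_heads = 2L, p)
    PV <- sweep(KV %*% p$Wv, 2, as.vector(p$bv), "+")
    for (h in 1:2) {
      cols <- ((h - 1) * 2 + 1):(h * 2)
      lo <- apply(PV[, cols, drop = FALSE], 2, min) - 1e-9
      hi <- apply(PV[, cols, drop = FALSE], 2, max) + 1e-9
      for (r in seq_len(nq)) {
        expect_true(all(out[r, cols] >= lo & out[r, cols] <= hi))
      }
    }
  }
})

test_that("masked keys are excluded from attention", {
  p <- identity_ca_params(1L)
  out <- cross_attention(matrix(2), rbind(1, -1, 50), n_heads = 1L, p,
                         key_mask = c(TRUE, TRUE, FALSE))
  w <- exp(2) / (exp(2) + exp(-2))
  expect_equal(out[1, 1], w - (1 - w), tolerance = 1e-9)
})

test_that("fingerprint embedding gathers one row per set bit", {
  b <- fx_bundle()
  fp1 <- fx_fp(17L, n_bits = 2048L)
  e1 <- embed_fingerprint(fp1, b)
  expect_equal(dim(e1), c(1L, b$cfg$fp_embed_dim))
  expect_equal(e1[1, ], b$ps$values$fp.table[17, ])
  fp3 <- fx_fp(c(5L, 17L, 100L), n_bits = 2048L)
  expect_equal(embed_fingerprint(fp3, b)[2, ], e1[1, ])
  expect_error(embed_fingerprint(fx_fp(integer(0), 2048L), b), "set bits")
  # molecules sharing set bits share O_where
  m1 <- fx_mols()[[1]]
  expect_equal(embed_fingerprint(m1$fingerprint, b),
               b$ps$values$fp.table[m1$fingerprint$on_bits, , drop = FALSE])
})

test_that("compound encoding is deterministic, permutation invariant and discriminative", {
  b <- fx_bundle()
  m1 <- parse_molecule("Cc1ccc(O)cc1", "p1")
  m2 <- parse_molecule("Oc1ccc(C)cc1", "p2")
  m3 <- parse_molecule("CCN(CC)CCO", "p3")
  x1 <- encode_compound(m1, b)
  expect_identical(x1, encode_compound(m1, b))
  expect_equal(x1, encode_compound(m2, b), tolerance = 1e-10)
  expect_gt(max(abs(x1 - encode_compound(m3, b))), 1e-4)
  expect_length(x1, b$cfg$embed_dim)
})

test_that("protein encoding is deterministic and mask-consistent", {
  b <- fx_bundle()
  pf <- fx_protein_features()
  x1 <- encode_protein(pf, b)
  expect_identical(x1, encode_protein(pf, b))
  expect_length(x1, b$cfg$embed_dim)
  # appending masked padding rows leaves the encoding unchanged
  pf_pad <- pf
  pf_pad$A <- rbind(pf$A, matrix(0L, 5, ncol(pf$A)))
  mask <- c(rep(TRUE, nrow(pf$A)), rep(FALSE, 5))
  expect_equal(encode_protein(pf_pad, b, atom_mask = mask), x1,
               tolerance = 1e-12)
  # a different fold gives a different encoding
  other <- protein_features(make_toy_protein(20L, seed = 99L)$structure,
                            b$cfg)
  expect_gt(max(abs(encode_protein(other, b) - x1)), 1e-5)
  expect_error(encode_protein(pf, b, atom_mask = TRUE), "mismatch")
})

test_that("the MLP head follows its closed form", {
  b <- fx_bundle()
  C <- b$cfg$embed_dim
  bz <- b
  bz$ps <- cpifuse:::ps_new()
  for (nm in names(b$ps$values)) bz$ps$values[[nm]] <- b$ps$values[[nm]]
  bz$ps$values$head.z.W <- matrix(0, 2 * C, b$cfg$head_hidden)
  bz$ps$values$head.z.b <- matrix(0, 1, b$cfg$head_hidden)
  bz$ps$values$head.o.W <- matrix(0, b$cfg$head_hidden, 1)
  bz$ps$values$head.o.b <- matrix(0, 1, 1)
  x <- rep(0.5, C)
  expect_equal(predict_interaction(x, x, bz), 0)
  bz$task <- "classification"
  expect_equal(predict_interaction(x, x, bz), 0.5)
  # hand-set 2 -> 1 -> 1 head on a fixed input
  b2 <- bz; b2$task <- "regression"
  b2$cfg <- fusion_config(embed_dim = 1L, n_heads = 1L, head_hidden = 1L)
  b2$ps$values$head.z.W <- matrix(c(2, -1), 2, 1)
  b2$ps$values$head.z.b <- matrix(0.5, 1, 1)
  b2$ps$values$head.o.W <- matrix(3, 1, 1)
  b2$ps$values$head.o.b <- matrix(-1, 1, 1)
  # z = relu(2*0.4 + (-1)*0.1 + 0.5) = 1.2 ; y = 3*1.2 - 1 = 2.6
  expect_equal(predict_interaction(0.4, 0.1, b2), 2.6, tolerance = 1e-12)
})

test_that("gradient flows to every unfrozen parameter", {
  b <- model_bundle(fx_pretrain(), fx_fusion_cfg(), task = "regression",
                    n_bits = 2048L, freeze_fraction = 0.95, seed = 3L)
  mols <- fx_named_mols()[1:4]
  pfs <- list(fxp = fx_protein_features())
  ints <- data.frame(compound_id = names(mols),
                     protein_id = "fxp",
                     label = c(0.2, -0.4, 1.1, 0.9))
  tape <- cpifuse:::ad_tape()
  pred <- cpifuse:::.fusion_forward(tape, b, ints, mols, pfs)
  d <- cpifuse:::ad_sub(pred, cpifuse:::ad_const(tape, matrix(ints$label)),
                        tape)
  loss <- cpifuse:::ad_mean(cpifuse:::ad_mul(d, d, tape), tape)
  cpifuse:::ad_backward(tape, loss)
  grads <- cpifuse:::ad_collect_grads(tape)
  unfrozen <- setdiff(names(grads), b$ps$frozen)
  # the 3D encoder and the PNA graph readout are pretraining-only heads;
  # fine-tuning consumes the PNA node features
  unfrozen <- unfrozen[!startsWith(unfrozen, "e3d.") &
                         !startsWith(unfrozen, "pna.read")]
  for (nm in unfrozen) {
    expect_gt(max(abs(grads[[nm]])), 0, label = paste("grad of", nm))
  }
  # fp.table rows never gathered must have zero gradient, used rows not
  used_bits <- sort(unique(unlist(lapply(mols, function(m)
    m$fingerprint$on_bits))))
  expect_gt(max(abs(grads$fp.table[used_bits, ])), 0)
})

test_that("forward passes stay finite across many random initialisations", {
  mols <- fx_named_mols()[1:2]
  pf <- fx_protein_features()
  pr <- fx_pretrain()
  for (seed in 1:100) {
    b <- model_bundle(pr, fx_fusion_cfg(), task = "regression",
                      n_bits = 2048L, seed = seed)
    x <- predict_interaction(encode_compound(mols[[1]], b),
                             encode_protein(pf, b), b)
    expect_true(is.finite(x))
  }
})

test_that("training reduces the loss, respects freezing and validates input", {
  mols <- fx_named_mols()
  pfs <- list(fxp = fx_protein_features(),
              oth = protein_features(make_toy_protein(20L, seed = 77L,
                                                      id = "oth")$structure,
                                     fx_fusion_cfg()))
  set.seed(51)
  ints <- expand.grid(compound_id = names(mols),
                      protein_id = names(pfs),
                      stringsAsFactors = FALSE)
  ints$label <- rnorm(nrow(ints)) + ifelse(ints$protein_id == "fxp", 1, -1)
  b <- model_bundle(fx_pretrain(), fx_fusion_cfg(), task = "regression",
                    n_bits = 2048L, freeze_fraction = 0.95, seed = 5L)
  frozen_before <- b$ps$values[b$ps$frozen]
  res <- train_model(ints, mols, pfs, b, epochs = 8L, lr = 3e-3, seed = 6L)
  expect_lt(res$losses[8], res$losses[1])
  expect_identical(res$bundle$ps$values[b$ps$frozen], frozen_before)
  expect_error(train_model(ints[0, ], mols, pfs, b), "empty")
  bad <- ints; bad$label[1] <- NA
  expect_error(train_model(bad, mols, pfs, b), "finite")
  bc <- model_bundle(fx_pretrain(), fx_fusion_cfg(),
                     task = "classification", n_bits = 2048L, seed = 5L)
  expect_error(train_model(ints, mols, pfs, bc), "0/1")
})

test_that("classification training uses logit BCE and outputs probabilities", {
  mols <- fx_named_mols()[1:6]
  pfs <- list(fxp = fx_protein_features())
  ints <- data.frame(compound_id = names(mols), protein_id = "fxp",
                     label = c(1, 0, 1, 0, 1, 0))
  b <- model_bundle(fx_pretrain(), fx_fusion_cfg(),
                    task = "classification", n_bits = 2048L, seed = 8L)
  res <- train_model(ints, mols, pfs, b, epochs = 5L, lr = 3e-3, seed = 1L)
  expect_lt(res$losses[5], res$losses[1] + 1e-9)
  preds <- predict_interactions(res$bundle, ints, mols, pfs)
  expect_true(all(preds$y_pred > 0 & preds$y_pred < 1))
})
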