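test_that("NT-Xent matches its closed forms at identical embeddings", {
  z4 <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  expect_equal(ntxent_loss(z4[1:2, ], z4[1:2, ], 1:2, tau = 0.3), 0,
               tolerance = 1e-12)
  expect_equal(ntxent_loss(z4[1:3, ], z4[1:3, ], 1:3, tau = 0.7), log(2),
               tolerance = 1e-12)
  expect_equal(ntxent_loss(z4, z4, 1:4, tau = 0.1), log(3),
               tolerance = 1e-12)
  # orthogonal pair: sim(i,i)=1, cross sims 0, tau=1
  z2 <- rbind(c(1, 0), c(0, 1))
  expect_equal(ntxent_loss(z2, z2, 1:2, tau = 1), -1, tolerance = 1e-9)
})

test_that("NT-Xent equals the brute-force double loop on random batches", {
  set.seed(21)
  for (rep in 1:25) {
    N <- sample(2:5, 1)
    c_per <- sample(1:3, N, replace = TRUE)
    d <- sample(2:6, 1)
    z2d <- matrix(rnorm(N * d), N, d)
    mol_of_conf <- rep(seq_len(N), c_per)
    z3d <- matrix(rnorm(length(mol_of_conf) * d), ncol = d)
    tau <- runif(1, 0.05, 2)
    for (excl in c(TRUE, FALSE)) {
      expect_equal(ntxent_loss(z2d, z3d, mol_of_conf, tau, excl),
                   bf_ntxent(z2d, z3d, mol_of_conf, tau, excl),
                   tolerance = 1e-6)
    }
  }
})

test_that("NT-Xent gradient is finite at the all-identical point", {
  z <- matrix(1, 3, 4)
  tape <- cpifuse:::ad_tape()
  ps <- cpifuse:::ps_new()
  cpifuse:::ps_add(ps, "z", z)
  zn <- cpifuse:::ad_p(tape, ps, "z")
  loss <- cpifuse:::ntxent_node(tape, zn, zn, 1:3, tau = 0.5)
  cpifuse:::ad_backward(tape, loss)
  expect_true(all(is.finite(cpifuse:::ad_collect_grads(tape)$z)))
})

test_that("NT-Xent rejects degenerate inputs", {
  z <- matrix(rnorm(8), 2, 4)
  expect_error(ntxent_loss(z, z, 1:2, tau = 0), "tau")
  expect_error(ntxent_loss(z[1, , drop = FALSE], z[1, , drop = FALSE], 1L),
               "two molecules")
})

test_that("PNA degree scalers follow the log-degree law on a star graph", {
  # star: center 1 bonded to leaves 2..6
  g <- parse_molecule("C(C)(C)(C)C", "neopentane")$graph  # degree 4 center
  batch <- cpifuse:::batch_graphs(list(g))
  avg_deg <- mean(batch$degree)
  tape <- cpifuse:::ad_tape()
  set.seed(31)
  msgs <- matrix(rnorm(length(batch$src) * 3), ncol = 3)
  m <- cpifuse:::ad_const(tape, msgs)
  base <- cpifuse:::ad_segment(m, batch$dst, batch$n_nodes, "mean", tape)
  s_amp <- log(batch$degree + 1) / log(avg_deg + 1)
  amp <- cpifuse:::ad_mul_colvec(base, s_amp, tape)
  att <- cpifuse:::ad_mul_colvec(base, 1 / s_amp, tape)
  for (v in seq_len(batch$n_nodes)) {
    direct <- colMeans(msgs[batch$dst == v, , drop = FALSE])
    expect_equal(base$value[v, ], direct, tolerance = 1e-12)
    expect_equal(amp$value[v, ],
                 direct * log(batch$degree[v] + 1) / log(avg_deg + 1),
                 tolerance = 1e-12)
    expect_equal(att$value[v, ],
                 direct * log(avg_deg + 1) / log(batch$degree[v] + 1),
                 tolerance = 1e-12)
  }
})

test_that("on a degree-regular graph amplification and identity scalers agree", {
  pr <- fx_pretrain()
  g <- parse_molecule("c1ccccc1", "benzene")$graph  # 2-regular
  cfg_id <- pr$cfg; cfg_id$scalers <- "identity"; cfg_id$avg_degree <- 2
  cfg_amp <- pr$cfg; cfg_amp$scalers <- "amplification"; cfg_amp$avg_degree <- 2
  # identical parameter shapes: single-scaler configs share layer widths
  ps <- cpifuse:::ps_new()
  cpifuse:::with_seed(5, {
    cpifuse:::pna_init_params(ps, cfg_id)
  })
  e1 <- encode_2d(g, cfg_id, ps)$embedding
  e2 <- encode_2d(g, cfg_amp, ps)$embedding
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("graph embeddings are invariant to atom relabelling", {
  pr <- fx_pretrain()
  pairs <- list(c("Cc1ccc(O)cc1", "Oc1ccc(C)cc1"),
                c("CCO", "OCC"),
                c("CC(=O)Nc1ccc(O)cc1", "Oc1ccc(NC(C)=O)cc1"))
  for (p in pairs) {
    e1 <- encode_2d(parse_molecule(p[1])$graph, pr$cfg, pr$ps)
    e2 <- encode_2d(parse_molecule(p[2])$graph, pr$cfg, pr$ps)
    expect_equal(e1$embedding, e2$embedding, tolerance = 1e-10)
  }
  # single-node graph: min = max = mean readouts coincide
  g1 <- parse_molecule("C")$graph
  out <- encode_2d(g1, pr$cfg, pr$ps)
  expect_length(out$embedding, pr$cfg$emb_dim)
  expect_true(all(is.finite(out$embedding)))
})

test_that("the 3D encoder is rigid-motion invariant but scale sensitive", {
  pr <- fx_pretrain()
  m <- fx_mols()[[3]]
  cf <- m$conformers[[1]]
  base <- encode_3d(m$graph, cf, pr$cfg, pr$ps)
  th <- pi / 2
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(encode_3d(m$graph, cf %*% t(R), pr$cfg, pr$ps), base,
               tolerance = 1e-9)
  expect_equal(encode_3d(m$graph, sweep(cf, 2, c(5, -3, 2), "+"), pr$cfg,
                         pr$ps), base, tolerance = 1e-9)
  expect_gt(max(abs(encode_3d(m$graph, cf * 2, pr$cfg, pr$ps) - base)), 1e-6)
  badcf <- cf; badcf[1, 1] <- NaN
  expect_error(encode_3d(m$graph, badcf, pr$cfg, pr$ps), "finite")
})

test_that("pretraining reduces the contrastive loss and is reproducible", {
  pr <- fx_pretrain()
  expect_lt(pr$losses[length(pr$losses)], pr$losses[1])
  pr2 <- pretrain(fx_mols(), pna_config(hidden_dim = 8L, emb_dim = 8L),
                  epochs = 6L, seed = 1L, lr = 3e-3)
  expect_identical(pr$losses, pr2$losses)
  expect_error(pretrain(fx_mols()[1], pna_config()), "two molecules")
  bare <- parse_molecule("CCO", "noconf")
  expect_error(pretrain(list(bare, bare), pna_config()), "conformer")
})

test_that("freeze masks obey the printed range and cover the input layers", {
  cfg <- pna_config(n_layers = 2L)
  expect_error(freeze_mask(1.0, cfg), "0.95")
  expect_error(freeze_mask(-0.1, cfg), "0.95")
  expect_length(freeze_mask(0, cfg)$frozen_parameter_ids, 0L)
  m <- freeze_mask(0.95, cfg)  # floor(0.95 * 2) = 1 layer
  expect_setequal(m$frozen_parameter_ids,
                  c("pna.l1.msg.W", "pna.l1.msg.b",
                    "pna.l1.upd.W", "pna.l1.upd.b"))
})

test_that("frozen parameters stay bitwise unchanged through optimisation", {
  pr <- pretrain(fx_mols()[1:6], pna_config(hidden_dim = 8L, emb_dim = 8L),
                 epochs = 0L, seed = 3L)
  apply_freeze(pr$ps, freeze_mask(0.95, pr$cfg))
  frozen_ids <- pr$ps$frozen
  values_before <- pr$ps$values
  # ten optimisation steps
  mols <- fx_mols()[1:6]
  graphs <- lapply(mols, function(m) m$graph)
  batch <- cpifuse:::batch_graphs(graphs)
  mol_of_conf <- rep(seq_along(mols), vapply(mols, function(m)
    length(m$conformers), 1L))
  for (step in 1:10) {
    tape <- cpifuse:::ad_tape()
    z2d <- cpifuse:::pna_forward(tape, pr$ps, pr$cfg, batch)$graph_emb
    z3d <- cpifuse:::ad_rbind(unlist(lapply(seq_along(mols), function(i) {
      lapply(mols[[i]]$conformers, function(cf) {
        cpifuse:::e3d_forward(tape, pr$ps, pr$cfg, graphs[[i]], cf)
      })
    }), recursive = FALSE), tape)
    loss <- cpifuse:::ntxent_node(tape, z2d, z3d, mol_of_conf, 0.1)
    cpifuse:::ad_backward(tape, loss)
    cpifuse:::adam_step(pr$ps, cpifuse:::ad_collect_grads(tape), lr = 1e-2)
  }
  expect_identical(pr$ps$values[frozen_ids], values_before[frozen_ids])
  unfrozen <- setdiff(names(pr$ps$values), frozen_ids)
  changed <- vapply(unfrozen, function(nm) {
    !identical(pr$ps$values[[nm]], values_before[[nm]])
  }, logical(1))
  expect_true(all(changed))
})
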