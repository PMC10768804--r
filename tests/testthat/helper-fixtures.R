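# Shared fixtures, built once per test run and memoised. Everything is
# generated in code; no files ship with the tests.

.fx_cache <- new.env(parent = emptyenv())

fx_memo <- function(key, builder) {
  if (is.null(.fx_cache[[key]])) .fx_cache[[key]] <- builder()
  .fx_cache[[key]]
}

fx_mols <- function() {
  fx_memo("mols", function() make_toy_molecules(12L, seed = 42L))
}

fx_named_mols <- function() {
  fx_memo("named_mols", function() {
    m <- fx_mols()
    names(m) <- vapply(m, function(x) x$id, "")
    m
  })
}

fx_protein <- function() {
  fx_memo("protein", function() make_toy_protein(20L, seed = 7L, id = "fxp"))
}

fx_pretrain <- function() {
  fx_memo("pretrain", function() {
    pretrain(fx_mols(), pna_config(hidden_dim = 8L, emb_dim = 8L),
             epochs = 6L, seed = 1L, lr = 3e-3)
  })
}

fx_fusion_cfg <- function() {
  fusion_config(embed_dim = 8L, n_heads = 2L, fp_embed_dim = 8L,
                head_hidden = 16L)
}

fx_bundle <- function() {
  fx_memo("bundle", function() {
    model_bundle(fx_pretrain(), fx_fusion_cfg(), task = "regression",
                 n_bits = 2048L, freeze_fraction = 0, seed = 2L)
  })
}

fx_protein_features <- function() {
  fx_memo("pfeat", function() {
    protein_features(fx_protein()$structure, fx_fusion_cfg())
  })
}

# a hand-made fingerprint over a small bit universe
fx_fp <- function(on, n_bits = 64L) {
  bits <- integer(n_bits)
  bits[on] <- 1L
  structure(list(bits = bits, on_bits = sort(unique(as.integer(on))),
                 radius = 2L, n_bits = as.integer(n_bits)),
            class = "fingerprint_vector")
}

# brute-force NT-Xent (double loop, both denominator conventions)
bf_ntxent <- function(z2d, z3d, mol_of_conf, tau, exclude_positive = TRUE) {
  cossim <- function(a, b) sum(a * b) / sqrt(sum(a * a) * sum(b * b))
  N <- nrow(z2d)
  total <- 0
  for (i in seq_len(N)) {
    num <- 0
    for (j in which(mol_of_conf == i)) {
      num <- num + exp(cossim(z2d[i, ], z3d[j, ]) / tau)
    }
    den <- 0
    ks <- if (exclude_positive) setdiff(seq_len(N), i) else seq_len(N)
    for (k in ks) {
      for (j in which(mol_of_conf == k)) {
        den <- den + exp(cossim(z2d[i, ], z3d[j, ]) / tau)
      }
    }
    total <- total + log(num / den)
  }
  -total / N
}
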