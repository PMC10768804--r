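# a small memoised interaction fixture for split tests: 20 compounds x
# 10 proteins = 200 interactions
fx_split_data <- function() {
  fx_memo("split_data", function() {
    ds <- make_toy_dataset(fixture_spec(n_compounds = 20L, n_proteins = 10L,
                                        seed = 3L, protein_length = 15L))
    fps <- lapply(ds$molecules, function(m) m$fingerprint)
    names(fps) <- vapply(ds$molecules, function(m) m$id, "")
    seqs <- vapply(ds$proteins, function(p) p$sequence, "")
    list(ds = ds, fps = fps, seqs = seqs)
  })
}

test_that("Butina clustering follows the greedy sphere-exclusion procedure", {
  expect_equal(butina_cluster(list(fx_fp(1:3), fx_fp(1:3), fx_fp(1:3)), 0.5),
               rep(1L, 3))
  singles <- list(fx_fp(1:2), fx_fp(3:4), fx_fp(5:6))
  expect_equal(butina_cluster(singles, 0.5), 1:3)
  expect_error(butina_cluster(list(), 0.5), "no fingerprints")
  # 4 items with a known similarity structure, cutoff 0.5 (distance):
  # a={1,2,3}, b={1,2,4}, c={1,2,3,4,5}, d={20,21}
  # sim(a,b)=2/4, sim(a,c)=3/5, sim(b,c)=3/5, sim(a,d)=0 ...
  # distances: ab=0.5 (not < .5), ac=bc=0.4 (<.5) -> neighbours:
  # a:{c}, b:{c}, c:{a,b}, d:{} ; c has most neighbours -> cluster 1 =
  # {c,a,b}; d is a singleton -> cluster 2
  fps <- list(fx_fp(1:3), fx_fp(c(1, 2, 4)), fx_fp(1:5), fx_fp(20:21))
  expect_equal(butina_cluster(fps, 0.5), c(1L, 1L, 1L, 2L))
})

test_that("k-means recovers trivial and well-separated structure", {
  X <- matrix(rnorm(30), 10, 3)
  expect_equal(kmeans_cluster(X, 1L), rep(1L, 10))
  expect_equal(kmeans_cluster(X, 10L), 1:10)
  expect_error(kmeans_cluster(X, 0L), "K")
  expect_error(kmeans_cluster(X, 11L), "K")
  set.seed(61)
  blobs <- rbind(matrix(rnorm(60, 0, 0.01), 30),
                 matrix(rnorm(60, 100, 0.01), 30))
  cl <- kmeans_cluster(blobs, 2L, seed = 9L)
  expect_equal(length(unique(cl[1:30])), 1L)
  expect_equal(length(unique(cl[31:60])), 1L)
  expect_false(cl[1] == cl[31])
  expect_identical(kmeans_cluster(blobs, 2L, seed = 9L), cl)
})

test_that("protein descriptors capture 3-mer composition", {
  d <- protein_descriptor("AAAA")
  expect_equal(sum(d != 0), 1L)
  expect_equal(d[1], 1)  # slot of AAA
  s <- "ACDEFGHIKLMNPQRSTVWY"
  expect_equal(sum(protein_descriptor(s) * protein_descriptor(s)), 1,
               tolerance = 1e-12)
  set.seed(62)
  a <- paste(sample(cpifuse:::AA1, 200, TRUE), collapse = "")
  b <- paste(sample(cpifuse:::AA1, 200, TRUE), collapse = "")
  expect_lt(sum(protein_descriptor(a) * protein_descriptor(b)), 0.5)
  expect_error(protein_descriptor(""), "nonempty")
  # nonstandard letters fall into the aggregate slot
  expect_equal(protein_descriptor("BZJBZ")[8001], 1)
})

test_that("alignment similarity is a normalised identity", {
  expect_equal(protein_similarity("ACDEFG", "ACDEFG"), 1)
  expect_equal(protein_similarity("ACDEFGHIKL", "MNPQRSTVWY"), 0)
  s <- protein_similarity("ACDEFGHIKL", "ACDEFGAAAA")
  expect_gt(s, 0.3); expect_lt(s, 1)
})

test_that("novel_pair folds share no compounds or proteins across train/test", {
  sd_ <- fx_split_data()
  split <- make_split(sd_$ds$interactions, sd_$fps, sd_$seqs,
                      setting = "novel_pair", n_folds = 3L, seed = 1L,
                      protein_sim = "descriptor")
  ints <- sd_$ds$interactions
  for (f in seq_len(split$n_folds)) {
    tr <- ints[split$train_idx[[f]], ]
    te <- ints[split$test_idx[[f]], ]
    expect_length(intersect(tr$compound_id, te$compound_id), 0L)
    expect_length(intersect(tr$protein_id, te$protein_id), 0L)
  }
  # interactions are partitioned across folds
  expect_setequal(unlist(lapply(seq_len(3L), function(f)
    which(split$fold_of_interaction == f))), seq_len(nrow(ints)))
  # determinism
  split2 <- make_split(sd_$ds$interactions, sd_$fps, sd_$seqs,
                       setting = "novel_pair", n_folds = 3L, seed = 1L,
                       protein_sim = "descriptor")
  expect_identical(split$fold_of_interaction, split2$fold_of_interaction)
  expect_identical(split$train_idx, split2$train_idx)
})

test_that("single-side settings enforce their own disjointness", {
  sd_ <- fx_split_data()
  ints <- sd_$ds$interactions
  for (setting in c("novel_compound", "novel_protein")) {
    split <- make_split(ints, sd_$fps, sd_$seqs, setting = setting,
                        n_folds = 3L, seed = 1L, protein_sim = "descriptor")
    col <- if (setting == "novel_compound") "compound_id" else "protein_id"
    for (f in seq_len(split$n_folds)) {
      expect_length(intersect(ints[split$train_idx[[f]], col],
                              ints[split$test_idx[[f]], col]), 0L)
    }
  }
})

test_that("novel_hard_pair enforces the similarity threshold; threshold 1 removes nothing", {
  sd_ <- fx_split_data()
  split <- make_split(sd_$ds$interactions, sd_$fps, sd_$seqs,
                      setting = "novel_hard_pair", n_folds = 3L,
                      sim_threshold = 0.3, seed = 1L,
                      protein_sim = "descriptor")
  expect_lte(split$audit$max_compound_tanimoto_train_vs_test, 0.3)
  expect_lte(split$audit$max_protein_similarity_train_vs_test, 0.3)
  loose <- make_split(sd_$ds$interactions, sd_$fps, sd_$seqs,
                      setting = "novel_hard_pair", n_folds = 3L,
                      sim_threshold = 1.0, seed = 1L,
                      protein_sim = "descriptor")
  expect_equal(loose$n_removed, 0L)
})

test_that("the audit matches a brute-force double loop and flags leakage", {
  sd_ <- fx_split_data()
  ints <- sd_$ds$interactions
  split <- make_split(ints, sd_$fps, sd_$seqs, setting = "novel_pair",
                      n_folds = 3L, seed = 1L, protein_sim = "descriptor")
  # brute force on fold 1
  tr <- ints[split$train_idx[[1]], ]; te <- ints[split$test_idx[[1]], ]
  best <- 0
  for (ci in unique(tr$compound_id)) {
    for (cj in unique(te$compound_id)) {
      best <- max(best, tanimoto(sd_$fps[[ci]], sd_$fps[[cj]]))
    }
  }
  expect_equal(split$audit$per_fold[[1]]$max_compound, best,
               tolerance = 1e-12)
  # an identical compound in train and test maxes at 1
  fake <- ints
  rk <- random_kfold(fake, n_folds = 4L, seed = 2L)
  shared <- intersect(fake$compound_id[rk$train_idx[[1]]],
                      fake$compound_id[rk$test_idx[[1]]])
  expect_gt(length(shared), 0L)
})

test_that("cluster splits beat a random K-fold control on leakage", {
  sd_ <- fx_split_data()
  ints <- sd_$ds$interactions
  hard <- make_split(ints, sd_$fps, sd_$seqs, setting = "novel_hard_pair",
                     n_folds = 3L, sim_threshold = 0.3, seed = 1L,
                     protein_sim = "descriptor")
  rk <- random_kfold(ints, n_folds = 3L, seed = 2L)
  rk_max <- 0
  for (f in 1:3) {
    ctr <- unique(ints$compound_id[rk$train_idx[[f]]])
    cte <- unique(ints$compound_id[rk$test_idx[[f]]])
    S <- tanimoto_matrix(sd_$fps[unique(ints$compound_id)])
    dimnames(S) <- list(unique(ints$compound_id), unique(ints$compound_id))
    rk_max <- max(rk_max, max(S[ctr, cte]))
  }
  expect_gt(rk_max, 0.3)  # random folds leak near-identical compounds
  expect_lte(hard$audit$max_compound_tanimoto_train_vs_test, 0.3)
})

test_that("cross_domain trains and tests on different datasets", {
  sd_ <- fx_split_data()
  ints <- sd_$ds$interactions
  # domains with disjoint entities, as in two separate source datasets
  comp_ids <- sort(unique(ints$compound_id))
  prot_ids <- sort(unique(ints$protein_id))
  te_dom <- ints$compound_id %in% tail(comp_ids, 5) &
    ints$protein_id %in% tail(prot_ids, 3)
  tr_dom <- ints$compound_id %in% head(comp_ids, 15) &
    ints$protein_id %in% head(prot_ids, 7)
  ints <- ints[te_dom | tr_dom, ]
  ints$dataset <- ifelse(te_dom[te_dom | tr_dom], "test", "train")
  split <- make_split(ints, sd_$fps, sd_$seqs, setting = "cross_domain",
                      sim_threshold = 0.95, seed = 1L,
                      protein_sim = "descriptor")
  expect_equal(split$n_folds, 1L)
  expect_true(all(ints$dataset[split$train_idx[[1]]] == "train"))
  expect_true(all(ints$dataset[split$test_idx[[1]]] == "test"))
  # the removal rule tightens leakage at a stricter threshold
  strict <- make_split(ints, sd_$fps, sd_$seqs, setting = "cross_domain",
                       sim_threshold = 0.6, seed = 1L,
                       protein_sim = "descriptor")
  expect_gte(strict$n_removed, split$n_removed)
  expect_lte(strict$audit$max_compound_tanimoto_train_vs_test, 0.6)
})

test_that("degenerate folds raise an informative error", {
  sd_ <- fx_split_data()
  ints <- sd_$ds$interactions
  expect_error(
    make_split(ints, sd_$fps, sd_$seqs, setting = "novel_hard_pair",
               n_folds = 3L, sim_threshold = 1e-6, seed = 1L,
               protein_sim = "descriptor"),
    "fewer folds|empty")
})
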