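# Leakage-controlled cluster cross-validation. Compounds are grouped by
# Butina sphere-exclusion clustering on Tanimoto distances, proteins by
# k-means on 3-mer composition descriptors; whole clusters are assigned to
# folds, and the harder settings additionally remove training interactions
# that are too similar to any test item.

#' Butina sphere-exclusion clustering of fingerprints
#'
#' Classic greedy scheme: items are ranked by their number of neighbours
#' (Tanimoto distance strictly below `cutoff`); the highest-ranked
#' unassigned item becomes a cluster centroid and claims its unassigned
#' neighbours; repeat. Ties are broken by the original index, so the
#' labelling is deterministic.
#'
#' @param fps list of `fingerprint_vector` objects.
#' @param cutoff Tanimoto-distance threshold in (0, 1] defining
#'   neighbourhood (distance = 1 - similarity). Default 0.6.
#' @return integer cluster labels (1 = largest-neighbourhood centroid
#'   first).
#' @export
butina_cluster <- function(fps, cutoff = 0.6) {
  if (length(fps) == 0L) stop("no fingerprints to cluster")
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
  n <- length(fps)
  if (n == 1L) return(1L)
  S <- tanimoto_matrix(fps)
  Dm <- 1 - S
  nb <- lapply(seq_len(n), function(i) {
    setdiff(which(Dm[i, ] < cutoff), i)
  })
  counts <- lengths(nb)
  ord <- order(-counts, seq_len(n))
  labels <- rep(NA_integer_, n)
  cl <- 0L
  for (i in ord) {
    if (!is.na(labels[i])) next
    cl <- cl + 1L
    labels[i] <- cl
    free <- nb[[i]][is.na(labels[nb[[i]]])]
    labels[free] <- cl
  }
  labels
}

#' Seeded k-means with k-means++ initialisation
#'
#' k-means++ seeding followed by Lloyd iterations (via [stats::kmeans]).
#'
#' @param vectors numeric matrix (one row per item) or list of vectors.
#' @param K number of clusters, 1 <= K <= n.
#' @param seed integer seed for the ++ initialisation.
#' @return integer cluster labels.
#' @export
kmeans_cluster <- function(vectors, K, seed = 1L) {
  X <- if (is.list(vectors)) do.call(rbind, vectors) else as.matrix(vectors)
  n <- nrow(X)
  if (K < 1L) stop("K must be >= 1")
  if (K > n) stop("K must be <= number of items")
  if (K == 1L) return(rep(1L, n))
  if (K == n) return(seq_len(n))
  centers <- with_seed(seed, .kmeanspp_init(X, K))
  fit <- suppressWarnings(stats::kmeans(X, centers = centers,
                                        iter.max = 100L, algorithm = "Lloyd"))
  as.integer(fit$cluster)
}

.kmeanspp_init <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(0, K, ncol(X))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- X[idx, ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  for (k in 2:K) {
    p <- d2 / sum(d2)
    if (any(!is.finite(p)) || sum(d2) == 0) {
      idx <- sample.int(n, 1L)
    } else {
      idx <- sample.int(n, 1L, prob = p)
    }
    centers[k, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[k, ])^2))
  }
  centers
}

#' 3-mer composition descriptor of a protein sequence
#'
#' L2-normalised counts of overlapping amino-acid 3-mers: 8000 slots for
#' the standard-alphabet 3-mers plus one aggregate slot for any 3-mer
#' containing a nonstandard letter.
#'
#' @param sequence one-letter amino-acid string (length >= 1; sequences
#'   shorter than 3 fall back to padding with the nonstandard slot).
#' @return numeric vector of length 8001 with unit L2 norm.
#' @export
protein_descriptor <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L) {
    stop("sequence must be a nonempty string")
  }
  v <- numeric(8001L)
  chars <- strsplit(toupper(sequence), "")[[1]]
  idx <- match(chars, AA1)
  L <- length(chars)
  if (L < 3L) {
    v[8001L] <- 1
    return(v)
  }
  for (i in seq_len(L - 2L)) {
    tri <- idx[i:(i + 2L)]
    if (anyNA(tri)) {
      v[8001L] <- v[8001L] + 1
    } else {
      slot <- (tri[1] - 1L) * 400L + (tri[2] - 1L) * 20L + tri[3]
      v[slot] <- v[slot] + 1
    }
  }
  v / sqrt(sum(v * v))
}

#' Normalised global-alignment identity between two sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0, linear
#' gap -1; the score is divided by the longer sequence length, clamped to
#' \[0, 1\]. Used as the protein similarity for the 0.3 leakage threshold.
#'
#' @param a,b amino-acid strings.
#' @return similarity in \[0, 1\].
#' @export
protein_similarity <- function(a, b) {
  # alphabet-agnostic substitution matrix: +1 match / 0 mismatch
  letters_all <- unique(strsplit(paste0(a, b, "X"), "")[[1]])
  sm <- matrix(0, length(letters_all), length(letters_all),
               dimnames = list(letters_all, letters_all))
  diag(sm) <- 1
  al <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = 0, gapExtension = 1)
  max(0, min(1, Biostrings::score(al) / max(nchar(a), nchar(b))))
}

#' Generate a cluster cross-validation split
#'
#' Settings:
#' * `novel_pair`: test fold f holds interactions whose compound cluster
#'   and protein cluster are both assigned to f; the train side excludes
#'   any interaction sharing a compound or protein cluster with the test
#'   fold.
#' * `novel_compound` / `novel_protein`: the same discipline on one side
#'   only.
#' * `novel_hard_pair`: `novel_pair` plus removal of training interactions
#'   whose compound Tanimoto similarity or protein similarity to any test
#'   item exceeds `sim_threshold`.
#' * `cross_domain`: train and test come from different values of a
#'   `dataset` column (one fold), with the same similarity-based removal.
#'
#' Whole clusters are assigned to folds by greedy interaction-count
#' balancing, largest cluster first, index tie-break.
#'
#' @param interactions data.frame with `compound_id`, `protein_id` and for
#'   cross_domain a `dataset` column (values "train"/"test").
#' @param fps named list of `fingerprint_vector`s keyed by compound id.
#' @param sequences named character vector of protein sequences keyed by
#'   protein id.
#' @param setting one of the five settings above.
#' @param n_folds number of folds (ignored for cross_domain).
#' @param sim_threshold similarity threshold for the removal rule
#'   (default 0.3).
#' @param butina_cutoff Tanimoto-distance cutoff for compound clustering.
#' @param K number of protein k-means clusters; default
#'   `ceiling(sqrt(n_proteins))`.
#' @param seed integer seed (protein k-means initialisation).
#' @param protein_sim "alignment" (default) or "descriptor" (cosine of
#'   3-mer descriptors) for the removal rule and the audit.
#' @return object of class `split_assignment`.
#' @export
make_split <- function(interactions, fps, sequences,
                       setting = c("novel_pair", "novel_compound",
                                   "novel_protein", "novel_hard_pair",
                                   "cross_domain"),
                       n_folds = 5L, sim_threshold = 0.3,
                       butina_cutoff = 0.6, K = NULL, seed = 1L,
                       protein_sim = c("alignment", "descriptor")) {
  setting <- match.arg(setting)
  protein_sim <- match.arg(protein_sim)
  stopifnot(all(c("compound_id", "protein_id") %in% names(interactions)))
  comp_ids <- unique(interactions$compound_id)
  prot_ids <- unique(interactions$protein_id)
  if (!all(comp_ids %in% names(fps))) stop("missing fingerprints for some compounds")
  if (!all(prot_ids %in% names(sequences))) stop("missing sequences for some proteins")
  n_int <- nrow(interactions)

  comp_cl <- butina_cluster(fps[comp_ids], cutoff = butina_cutoff)
  names(comp_cl) <- comp_ids
  if (is.null(K)) K <- ceiling(sqrt(length(prot_ids)))
  desc <- t(vapply(sequences[prot_ids], protein_descriptor, numeric(8001L)))
  prot_cl <- kmeans_cluster(desc, K = min(K, length(prot_ids)), seed = seed)
  names(prot_cl) <- prot_ids

  int_comp_cl <- comp_cl[interactions$compound_id]
  int_prot_cl <- prot_cl[interactions$protein_id]

  if (setting == "cross_domain") {
    stopifnot("dataset" %in% names(interactions))
    fold <- ifelse(interactions$dataset == "test", 1L, NA_integer_)
    n_folds <- 1L
    test_idx_of_fold <- list(which(!is.na(fold) & fold == 1L))
    train_pool_of_fold <- list(which(interactions$dataset != "test"))
    fold[is.na(fold)] <- 0L  # 0 marks train-domain interactions
  } else {
    balance_into_folds <- function(cl_of_int, n_folds) {
      sizes <- table(cl_of_int)
      ord <- order(-as.integer(sizes), as.integer(names(sizes)))
      load <- numeric(n_folds)
      fold_of_cluster <- integer(length(sizes))
      names(fold_of_cluster) <- names(sizes)
      for (ci in ord) {
        f <- which.min(load)
        fold_of_cluster[ci] <- f
        load[f] <- load[f] + sizes[ci]
      }
      fold_of_cluster
    }
    if (setting %in% c("novel_pair", "novel_hard_pair")) {
      fcomp <- balance_into_folds(int_comp_cl, n_folds)
      fprot <- balance_into_folds(int_prot_cl, n_folds)
      fold <- as.integer(fcomp[as.character(int_comp_cl)])
      test_idx_of_fold <- lapply(seq_len(n_folds), function(f) {
        which(fcomp[as.character(int_comp_cl)] == f &
                fprot[as.character(int_prot_cl)] == f)
      })
      train_pool_of_fold <- lapply(seq_len(n_folds), function(f) {
        which(fcomp[as.character(int_comp_cl)] != f &
                fprot[as.character(int_prot_cl)] != f)
      })
    } else if (setting == "novel_compound") {
      fcomp <- balance_into_folds(int_comp_cl, n_folds)
      fold <- as.integer(fcomp[as.character(int_comp_cl)])
      test_idx_of_fold <- lapply(seq_len(n_folds), function(f) which(fold == f))
      train_pool_of_fold <- lapply(seq_len(n_folds), function(f) which(fold != f))
    } else {
      fprot <- balance_into_folds(int_prot_cl, n_folds)
      fold <- as.integer(fprot[as.character(int_prot_cl)])
      test_idx_of_fold <- lapply(seq_len(n_folds), function(f) which(fold == f))
      train_pool_of_fold <- lapply(seq_len(n_folds), function(f) which(fold != f))
    }
  }

  # similarity-based removal for the hard settings
  n_removed <- 0L
  use_removal <- setting %in% c("novel_hard_pair", "cross_domain")
  psim_fun <- if (protein_sim == "alignment") {
    function(a, b) protein_similarity(sequences[[a]], sequences[[b]])
  } else {
    dcache <- lapply(sequences[prot_ids], protein_descriptor)
    function(a, b) sum(dcache[[a]] * dcache[[b]])
  }
  S_comp <- tanimoto_matrix(fps[comp_ids])
  dimnames(S_comp) <- list(comp_ids, comp_ids)
  psim_cache <- new.env(parent = emptyenv())
  prot_pair_sim <- function(a, b) {
    if (a == b) return(1)
    k <- paste(sort(c(a, b)), collapse = "|")
    v <- psim_cache[[k]]
    if (is.null(v)) {
      v <- psim_fun(a, b)
      psim_cache[[k]] <- v
    }
    v
  }

  train_idx_of_fold <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test_i <- test_idx_of_fold[[f]]
    train_i <- train_pool_of_fold[[f]]
    if (use_removal && length(test_i) > 0L && length(train_i) > 0L) {
      test_comps <- unique(interactions$compound_id[test_i])
      test_prots <- unique(interactions$protein_id[test_i])
      keep <- vapply(train_i, function(ti) {
        ci <- interactions$compound_id[ti]
        pi <- interactions$protein_id[ti]
        cmax <- max(S_comp[ci, test_comps])
        if (cmax > sim_threshold) return(FALSE)
        pmax_ <- max(vapply(test_prots, function(tp) prot_pair_sim(pi, tp),
                            numeric(1)))
        pmax_ <= sim_threshold
      }, logical(1))
      n_removed <- n_removed + sum(!keep)
      train_i <- train_i[keep]
    }
    if (length(test_i) == 0L || length(train_i) == 0L) {
      stop("fold ", f, " has an empty train or test side; ",
           "try fewer folds or a different setting")
    }
    train_idx_of_fold[[f]] <- train_i
    test_idx_of_fold[[f]] <- test_i
  }

  split <- structure(list(
    setting = setting, n_folds = n_folds,
    fold_of_interaction = fold,
    test_idx = test_idx_of_fold, train_idx = train_idx_of_fold,
    compound_cluster = comp_cl, protein_cluster = prot_cl,
    sim_threshold = sim_threshold, n_removed = n_removed,
    interactions = interactions[, c("compound_id", "protein_id")],
    protein_sim = protein_sim
  ), class = "split_assignment")
  split$audit <- audit_split(split, fps, sequences)
  split
}

#' Leakage audit of a split
#'
#' Exhaustive maxima over train x test pairs of compound Tanimoto
#' similarity and protein similarity, per fold, reduced to the overall
#' maxima.
#'
#' @param split a `split_assignment`.
#' @param fps named fingerprint list.
#' @param sequences named protein sequence vector.
#' @return list with `max_compound_tanimoto_train_vs_test`,
#'   `max_protein_similarity_train_vs_test`, `n_removed` and `per_fold`.
#' @export
audit_split <- function(split, fps, sequences) {
  stopifnot(inherits(split, "split_assignment"))
  ints <- split$interactions
  comp_ids <- unique(ints$compound_id)
  S_comp <- tanimoto_matrix(fps[comp_ids])
  dimnames(S_comp) <- list(comp_ids, comp_ids)
  prot_ids <- unique(ints$protein_id)
  if (split$protein_sim == "alignment") {
    Sp <- matrix(1, length(prot_ids), length(prot_ids),
                 dimnames = list(prot_ids, prot_ids))
    if (length(prot_ids) > 1L) {
      for (i in seq_len(length(prot_ids) - 1L)) {
        for (j in (i + 1L):length(prot_ids)) {
          s <- protein_similarity(sequences[[prot_ids[i]]],
                                  sequences[[prot_ids[j]]])
          Sp[i, j] <- s; Sp[j, i] <- s
        }
      }
    }
  } else {
    Dm <- t(vapply(sequences[prot_ids], protein_descriptor, numeric(8001L)))
    Sp <- Dm %*% t(Dm)
    dimnames(Sp) <- list(prot_ids, prot_ids)
  }
  per_fold <- lapply(seq_len(split$n_folds), function(f) {
    tr <- split$train_idx[[f]]; te <- split$test_idx[[f]]
    ctr <- unique(ints$compound_id[tr]); cte <- unique(ints$compound_id[te])
    ptr <- unique(ints$protein_id[tr]); pte <- unique(ints$protein_id[te])
    list(max_compound = max(S_comp[ctr, cte, drop = FALSE]),
         max_protein = max(Sp[ptr, pte, drop = FALSE]))
  })
  list(
    max_compound_tanimoto_train_vs_test =
      max(vapply(per_fold, function(x) x$max_compound, numeric(1))),
    max_protein_similarity_train_vs_test =
      max(vapply(per_fold, function(x) x$max_protein, numeric(1))),
    n_removed = split$n_removed,
    per_fold = per_fold
  )
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("<split_assignment>", x$setting, "with", x$n_folds, "fold(s);",
      nrow(x$interactions), "interactions;", x$n_removed, "removed\n")
  cat("  audit: max compound Tanimoto",
      sprintf("%.3f", x$audit$max_compound_tanimoto_train_vs_test),
      "| max protein similarity",
      sprintf("%.3f", x$audit$max_protein_similarity_train_vs_test), "\n")
  invisible(x)
}

#' Random K-fold control split (no cluster discipline)
#'
#' Plain seeded K-fold partition of interactions, used as the leakage
#' control against cluster splits.
#' @param interactions interaction table.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return list with `fold_of_interaction`, `train_idx`, `test_idx`.
#' @export
random_kfold <- function(interactions, n_folds = 5L, seed = 1L) {
  n <- nrow(interactions)
  fold <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  list(fold_of_interaction = fold,
       test_idx = lapply(seq_len(n_folds), function(f) which(fold == f)),
       train_idx = lapply(seq_len(n_folds), function(f) which(fold != f)))
}
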