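# Synthetic fixtures: small drug-like molecules with conformers, ideal
# alpha-helix protein structures, and interaction tables carrying a
# planted linear signal that a correct end-to-end model can partially
# recover. Fixtures exercise code paths and statistical contracts; they do
# not imitate real binding physics.

# scaffold x substituent grid of valid drug-like SMILES; the four scaffold
# families are structurally distant so Butina clustering at the default
# cutoff separates them
.toy_library <- function() {
  subs <- c("C", "CC", "O", "N", "F", "OC", "C(C)C", "CCO")
  scaffolds <- c(
    sulfonamide = "NS(=O)(=O)c1ccc(%s)cc1",
    pyridine_amide = "O=C(Nc1ccncc1)%s",
    piperidine = "OC(=O)C1CCN(C%s)CC1",
    indole = "c1ccc2c(c1)cc(C%s)[nH]2",
    aliphatic = "CCN(CC)CC(=O)O%s"
  )
  out <- character(0)
  for (sname in names(scaffolds)) {
    for (su in subs) {
      out <- c(out, sprintf(scaffolds[[sname]], su))
    }
  }
  unique(out)
}

#' Generate toy drug-like molecules with conformers
#'
#' Draws (deterministically for a given seed) from a fixed library of
#' valid SMILES built from several distant scaffold families, so the
#' emitted set spans multiple Butina clusters. Each record carries two
#' seeded conformers.
#'
#' @param n number of molecules (recycled over the library if larger).
#' @param seed integer seed.
#' @param n_conf conformers per molecule (default 2).
#' @return list of `molecule_record` objects with ids "cmpd_001", ...
#' @export
make_toy_molecules <- function(n, seed = 1L, n_conf = 2L) {
  stopifnot(n >= 1L)
  lib <- .toy_library()
  smiles <- with_seed(seed, {
    if (n <= length(lib)) sample(lib, n) else
      c(sample(lib), sample(lib, n - length(lib), replace = TRUE))
  })
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- parse_molecule(smiles[i], sprintf("cmpd_%03d", i))
    out[[i]] <- generate_conformers(rec, n_conf = n_conf, seed = seed + i)
  }
  out
}

#' Generate an ideal alpha-helix toy protein
#'
#' Backbone C-alphas on an ideal helix (rise 1.5 A per residue, 100 degrees
#' per residue, radius 2.3 A) with four heavy atoms per residue (N, CA, C,
#' O) placed in a per-residue local frame, and a seeded random amino-acid
#' sequence. Consecutive C-alpha distances are ~3.8 A and the distance map
#' is Toeplitz by construction.
#'
#' @param length number of residues (>= 3).
#' @param seed integer seed for the sequence.
#' @param id identifier.
#' @return list with `structure` (a `protein_structure`), `pdb_text`
#'   (character vector) and `sequence`.
#' @export
make_toy_protein <- function(length = 30L, seed = 1L, id = "prot") {
  stopifnot(length >= 3L)
  aa1 <- with_seed(seed, sample(AA1, length, replace = TRUE))
  aa3 <- AA3[match(aa1, AA1)]
  rise <- 1.5; twist <- 100 * pi / 180; radius <- 2.3
  atoms <- data.frame(name = character(0), res_index = integer(0),
                      element = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), stringsAsFactors = FALSE)
  ca <- matrix(0, length, 3L)
  for (r in seq_len(length)) {
    th <- twist * (r - 1L)
    e_r <- c(cos(th), sin(th), 0)
    e_t <- c(-sin(th), cos(th), 0)
    e_z <- c(0, 0, 1)
    ca_r <- radius * e_r + c(0, 0, rise * (r - 1L))
    ca[r, ] <- ca_r
    pos <- rbind(
      N = ca_r - 0.77 * e_t - 1.23 * e_z,  # |offset| ~1.45 (N-CA)
      CA = ca_r,
      C = ca_r + 0.85 * e_t + 1.26 * e_z,  # ~1.52 (CA-C)
      O = ca_r + 0.85 * e_t + 1.26 * e_z + 1.23 * e_r)  # ~1.23 (C=O)
    atoms <- rbind(atoms, data.frame(
      name = c("N", "CA", "C", "O"), res_index = r,
      element = c("N", "C", "C", "O"),
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      stringsAsFactors = FALSE))
  }
  s <- structure(list(
    id = id,
    residues = data.frame(index = seq_len(length), aa3 = aa3, aa1 = aa1,
                          stringsAsFactors = FALSE),
    atoms = atoms, ca_coords = ca,
    sequence = paste(aa1, collapse = "")
  ), class = "protein_structure")
  list(structure = s, pdb_text = write_pdb_text(s),
       sequence = s$sequence)
}

#' Fixture specification
#'
#' @param n_compounds,n_proteins,n_interactions counts (>= 1);
#'   `n_interactions = NULL` uses all compound x protein pairs.
#' @param noise_sd Gaussian label noise (>= 0), default 0.1.
#' @param seed integer seed.
#' @param protein_length residues per toy protein.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_compounds = 50L, n_proteins = 10L,
                         n_interactions = NULL, noise_sd = 0.1, seed = 1L,
                         protein_length = 30L) {
  stopifnot(n_compounds >= 1L, n_proteins >= 1L, noise_sd >= 0)
  structure(list(n_compounds = n_compounds, n_proteins = n_proteins,
                 n_interactions = n_interactions, noise_sd = noise_sd,
                 seed = seed, protein_length = protein_length),
            class = "fixture_spec")
}

# interpretable protein composition summary used by the planted signal:
# fractions of hydrophobic, charged and aromatic residues
.protein_signal_features <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  c(hydrophobic = mean(chars %in% c("A", "V", "L", "I", "M", "F", "W", "C")),
    charged = mean(chars %in% c("D", "E", "K", "R", "H")),
    aromatic = mean(chars %in% c("F", "W", "Y")))
}

#' Generate a planted-signal interaction dataset
#'
#' Labels are a linear function of (a) the one-hot Butina-cluster
#' indicator of the compound and (b) the hydrophobic/charged/aromatic
#' composition summary of the protein, plus Gaussian noise:
#' `y = w_c[cluster(c)] + w_p . comp(p) + N(0, noise_sd)`. A binary
#' variant thresholds the latent value at its median.
#'
#' @param spec a [fixture_spec()].
#' @return list with `interactions` (data.frame compound_id, protein_id,
#'   label, label_binary), `molecules`, `proteins` (list of
#'   [make_toy_protein()] outputs), `compound_cluster`, `signal` (the
#'   generating weights and feature matrix, for oracle checks).
#' @export
make_toy_dataset <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  mols <- make_toy_molecules(spec$n_compounds, seed = spec$seed)
  prots <- lapply(seq_len(spec$n_proteins), function(p) {
    make_toy_protein(spec$protein_length, seed = spec$seed * 100L + p,
                     id = sprintf("prot_%02d", p))
  })
  names(prots) <- vapply(prots, function(p) p$structure$id, "")
  fps <- lapply(mols, function(m) m$fingerprint)
  comp_cl <- butina_cluster(fps, cutoff = 0.6)
  ncl <- max(comp_cl)
  pfeat <- t(vapply(prots, function(p) .protein_signal_features(p$sequence),
                    numeric(3L)))
  pairs <- expand.grid(ci = seq_len(spec$n_compounds),
                       pi = seq_len(spec$n_proteins))
  if (!is.null(spec$n_interactions) && spec$n_interactions < nrow(pairs)) {
    pairs <- with_seed(spec$seed + 7L,
                       pairs[sample.int(nrow(pairs), spec$n_interactions), ])
  }
  gen <- with_seed(spec$seed + 11L, {
    w_cluster <- stats::rnorm(ncl, sd = 1)
    w_prot <- stats::rnorm(3L, sd = 2)
    noise <- stats::rnorm(nrow(pairs), sd = spec$noise_sd)
    list(w_cluster = w_cluster, w_prot = w_prot, noise = noise)
  })
  latent <- gen$w_cluster[comp_cl[pairs$ci]] +
    as.vector(pfeat[pairs$pi, , drop = FALSE] %*% gen$w_prot)
  label <- latent + gen$noise
  interactions <- data.frame(
    compound_id = vapply(mols, function(m) m$id, "")[pairs$ci],
    protein_id = names(prots)[pairs$pi],
    label = label,
    label_binary = as.integer(label > stats::median(label)),
    stringsAsFactors = FALSE)
  rownames(interactions) <- NULL
  list(interactions = interactions, molecules = mols, proteins = prots,
       compound_cluster = comp_cl,
       signal = list(w_cluster = gen$w_cluster, w_prot = gen$w_prot,
                     latent = latent, protein_features = pfeat,
                     pair_compound = pairs$ci, pair_protein = pairs$pi))
}

#' Write fixtures to a directory
#'
#' Emits `compounds.csv` (compound_id, smiles), one PDB file per protein,
#' and `interactions.csv`.
#'
#' @param dataset output of [make_toy_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(
    compound_id = vapply(dataset$molecules, function(m) m$id, ""),
    smiles = vapply(dataset$molecules, function(m) m$smiles, ""),
    stringsAsFactors = FALSE),
    file.path(dir, "compounds.csv"), row.names = FALSE)
  pdbdir <- file.path(dir, "structures")
  dir.create(pdbdir, showWarnings = FALSE)
  for (p in dataset$proteins) {
    writeLines(p$pdb_text, file.path(pdbdir, paste0(p$structure$id, ".pdb")))
  }
  ints <- dataset$interactions
  ints$structure_path <- file.path("structures",
                                   paste0(ints$protein_id, ".pdb"))
  utils::write.csv(ints, file.path(dir, "interactions.csv"),
                   row.names = FALSE)
  invisible(dir)
}
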