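# Compound featurisation: SMILES -> molecular graph ("what"), Morgan
# fingerprint ("where") and seeded 3D conformer coordinate sets (for the
# contrastive pretraining phase). SMILES parsing is delegated to
# ChemmineR/OpenBabel; hydrogens are implicit throughout (heavy atoms only).

CHEM_ELEMENTS <- c("C", "N", "O", "S", "F", "P", "Cl", "Br", "I", "other")
CHEM_ELECTRONEG <- c(C = 2.55, N = 3.04, O = 3.44, S = 2.58, F = 3.98,
                     P = 2.19, Cl = 3.16, Br = 2.96, I = 2.66, other = 2.20)
CHEM_COV_RADIUS <- c(C = 0.76, N = 0.71, O = 0.66, S = 1.05, F = 0.57,
                     P = 1.07, Cl = 1.02, Br = 1.20, I = 1.39, other = 0.77)
# bond-order codes: 1 single, 2 double, 3 triple, 4 aromatic
BOND_LENGTH_FACTOR <- c(1.00, 0.87, 0.78, 0.92)

one_hot <- function(value, levels) {
  v <- numeric(length(levels))
  i <- match(value, levels)
  if (is.na(i)) i <- length(levels)  # last level is the "other" slot
  v[i] <- 1
  v
}

#' Parse a SMILES string into a molecule record
#'
#' Builds the molecular graph (one-hot atom and bond features) and the
#' Morgan fingerprint. Conformers are left empty; attach them with
#' [generate_conformers()].
#'
#' Atom features: one-hot element (C,N,O,S,F,P,Cl,Br,I,other), one-hot
#' heavy-atom degree (0-5), one-hot formal charge (-2..+2), one-hot
#' hybridisation (sp, sp2, sp3, other), aromaticity flag, and Pauling
#' electronegativity scaled by 1/4. Bond features: one-hot bond order
#' (single, double, triple, aromatic) plus a ring membership flag.
#'
#' @param smiles a single SMILES string.
#' @param id identifier used in error messages and downstream tables.
#' @param fp_radius,fp_nbits Morgan fingerprint parameters.
#' @return object of class `molecule_record` with fields `id`, `smiles`,
#'   `graph`, `fingerprint`, `conformers`.
#' @export
#' @examples
#' \donttest{
#' mol <- parse_molecule("c1ccccc1", "benzene")
#' mol$graph$n_atoms  # 6
#' }
parse_molecule <- function(smiles, id = smiles, fp_radius = 2L,
                           fp_nbits = 2048L) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  sdf <- tryCatch({
    x <- smiles
    names(x) <- id
    suppressWarnings(ChemmineR::smiles2sdf(x))
  }, error = function(e) NULL)
  if (is.null(sdf) || length(sdf) < 1L) {
    stop("could not parse SMILES for compound '", id, "': ", smiles)
  }
  graph <- .sdf_to_graph(sdf[[1]], id)
  rec <- structure(list(id = id, smiles = smiles, graph = graph,
                        fingerprint = NULL, conformers = list()),
                   class = "molecule_record")
  rec$fingerprint <- compute_morgan_fingerprint(rec, radius = fp_radius,
                                                n_bits = fp_nbits)
  rec
}

.sdf_to_graph <- function(sdf, id) {
  ab <- ChemmineR::atomblock(sdf)
  if (is.null(ab) || nrow(ab) < 1L) {
    stop("could not parse SMILES for compound '", id, "': empty molecule")
  }
  n <- nrow(ab)
  elements <- sub("_.*$", "", rownames(ab))
  # V2000 old-style charge codes live in atom-block column "C6"
  codes <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, n)
  charge_map <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `5` = -1, `6` = -2,
                  `7` = -3, `4` = 0)
  charges <- unname(charge_map[as.character(codes)])
  charges[is.na(charges)] <- 0

  bb <- ChemmineR::bondblock(sdf)
  # bond-less molecules come back with a degenerate 2-column block
  has_bonds <- !is.null(bb) && ncol(bb) >= 3L && nrow(bb) >= 1L &&
    any(bb[, 1] > 0)
  bi <- if (has_bonds) as.integer(bb[, 1]) else integer(0)
  bj <- if (has_bonds) as.integer(bb[, 2]) else integer(0)
  border <- if (has_bonds) as.integer(bb[, 3]) else integer(0)
  if (any(bi < 1 | bi > n | bj < 1 | bj > n)) {
    stop("bond endpoint out of range for compound '", id, "'")
  }

  # ring perception -> ring bonds and aromatic atoms/bonds
  ring_atoms <- list()
  aromatic_atom <- rep(FALSE, n)
  ring_bond <- rep(FALSE, length(bi))
  aromatic_bond <- rep(FALSE, length(bi))
  if (has_bonds) {
    rr <- tryCatch(suppressWarnings(
      ChemmineR::rings(sdf, type = "all", arom = TRUE)),
      error = function(e) NULL)
    if (!is.null(rr) && length(rr$RINGS) > 0L) {
      for (k in seq_along(rr$RINGS)) {
        members <- as.integer(sub("^.*_", "", rr$RINGS[[k]]))
        arom <- isTRUE(rr$AROMATIC[[k]])
        if (arom) aromatic_atom[members] <- TRUE
        inring <- (bi %in% members) & (bj %in% members)
        ring_bond <- ring_bond | inring
        if (arom) aromatic_bond <- aromatic_bond | inring
      }
    }
  }
  border[aromatic_bond] <- 4L

  degree <- tabulate(c(bi, bj), nbins = n)
  n_double <- tabulate(c(bi[border == 2L], bj[border == 2L]), nbins = n)
  n_triple <- tabulate(c(bi[border == 3L], bj[border == 3L]), nbins = n)
  hybrid <- ifelse(n_triple > 0 | n_double >= 2, "sp",
                   ifelse(n_double > 0 | aromatic_atom, "sp2", "sp3"))

  node_features <- t(vapply(seq_len(n), function(a) {
    el <- if (elements[a] %in% CHEM_ELEMENTS) elements[a] else "other"
    c(one_hot(el, CHEM_ELEMENTS),
      one_hot(min(degree[a], 5L), 0:5),
      one_hot(max(-2L, min(2L, charges[a])), -2:2),
      one_hot(hybrid[a], c("sp", "sp2", "sp3", "other")),
      as.numeric(aromatic_atom[a]),
      CHEM_ELECTRONEG[[el]] / 4)
  }, numeric(27L)))
  colnames(node_features) <- c(paste0("el_", CHEM_ELEMENTS),
                               paste0("deg_", 0:5),
                               paste0("chg_", -2:2),
                               paste0("hyb_", c("sp", "sp2", "sp3", "other")),
                               "aromatic", "electroneg")

  bond_features <- NULL
  if (has_bonds) {
    bond_features <- t(vapply(seq_along(bi), function(b) {
      c(one_hot(border[b], c(1L, 2L, 3L, 4L)), as.numeric(ring_bond[b]))
    }, numeric(5L)))
    colnames(bond_features) <- c("single", "double", "triple", "aromatic",
                                 "in_ring")
  } else {
    bond_features <- matrix(0, 0L, 5L)
  }

  structure(list(n_atoms = n, elements = elements, degree = degree,
                 charges = charges, aromatic = aromatic_atom,
                 node_features = node_features,
                 edges = cbind(i = bi, j = bj, order = border),
                 bond_features = bond_features),
            class = "molecular_graph")
}

#' @export
print.molecule_record <- function(x, ...) {
  cat("<molecule_record>", x$id, ":", x$smiles, "-", x$graph$n_atoms,
      "atoms,", nrow(x$graph$edges), "bonds,",
      length(x$conformers), "conformers\n")
  invisible(x)
}

# deterministic polynomial hash of an integer vector into [0, 2^31 - 2]
.chem_hash <- function(ints) {
  h <- 5381
  for (x in ints) h <- (h * 33 + (x %% 2147483647)) %% 2147483647
  h
}

#' Compute a Morgan (circular) fingerprint
#'
#' Iteratively hashes each atom's neighbourhood out to the given radius
#' (the ECFP scheme): the radius-0 invariant combines element, degree,
#' formal charge and aromaticity; each iteration folds in the sorted
#' (bond order, neighbour invariant) list. An environment only emits a bit
#' when its atom set grew relative to the previous radius, and duplicate
#' environment hashes set a single bit.
#'
#' @param mol a `molecule_record`.
#' @param radius maximum environment radius (>= 0).
#' @param n_bits fingerprint length (>= 64).
#' @return object of class `fingerprint_vector` with fields `bits`
#'   (0/1 integer vector), `on_bits`, `radius`, `n_bits`.
#' @export
compute_morgan_fingerprint <- function(mol, radius = 2L, n_bits = 2048L) {
  stopifnot(inherits(mol, "molecule_record") || inherits(mol, "molecular_graph"))
  g <- if (inherits(mol, "molecule_record")) mol$graph else mol
  if (radius < 0) stop("radius must be >= 0")
  if (n_bits < 64) stop("n_bits must be >= 64")
  if (g$n_atoms < 1L) stop("empty molecule")
  hashes <- .morgan_environments(g, radius)
  bits <- integer(n_bits)
  bits[unique(hashes %% n_bits) + 1L] <- 1L
  structure(list(bits = bits, on_bits = which(bits == 1L),
                 radius = as.integer(radius), n_bits = as.integer(n_bits)),
            class = "fingerprint_vector")
}

# distinct circular-environment hash values out to `radius`
.morgan_environments <- function(g, radius) {
  n <- g$n_atoms
  nbrs <- vector("list", n)
  bond_of <- vector("list", n)
  if (nrow(g$edges) > 0L) {
    for (b in seq_len(nrow(g$edges))) {
      i <- g$edges[b, "i"]; j <- g$edges[b, "j"]; o <- g$edges[b, "order"]
      nbrs[[i]] <- c(nbrs[[i]], j); bond_of[[i]] <- c(bond_of[[i]], o)
      nbrs[[j]] <- c(nbrs[[j]], i); bond_of[[j]] <- c(bond_of[[j]], o)
    }
  }
  inv <- vapply(seq_len(n), function(a) {
    el <- match(g$elements[a], CHEM_ELEMENTS, nomatch = length(CHEM_ELEMENTS))
    .chem_hash(c(el, g$degree[a], g$charges[a] + 10L,
                 as.integer(g$aromatic[a])))
  }, numeric(1))
  env_set <- lapply(seq_len(n), function(a) a)
  hashes <- inv
  r <- 0L
  while (r < radius) {
    r <- r + 1L
    new_inv <- inv
    new_set <- env_set
    for (a in seq_len(n)) {
      if (length(nbrs[[a]]) == 0L) next
      ord <- order(bond_of[[a]], inv[nbrs[[a]]])
      pairs <- as.vector(rbind(bond_of[[a]][ord], inv[nbrs[[a]]][ord]))
      new_inv[a] <- .chem_hash(c(inv[a], pairs))
      new_set[[a]] <- sort(unique(c(env_set[[a]],
                                    unlist(env_set[nbrs[[a]]]))))
    }
    grew <- vapply(seq_len(n), function(a) {
      length(new_set[[a]]) > length(env_set[[a]])
    }, logical(1))
    hashes <- c(hashes, new_inv[grew])
    inv <- new_inv
    env_set <- new_set
  }
  unique(hashes)
}

#' Tanimoto similarity of two fingerprints
#'
#' @param a,b `fingerprint_vector` objects with equal `n_bits`.
#' @return `|a & b| / |a | b|` in \[0, 1\]; 0 (with a warning) when both
#'   fingerprints are empty.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint_vector"), inherits(b, "fingerprint_vector"))
  if (a$n_bits != b$n_bits) stop("fingerprints have different n_bits")
  inter <- sum(a$bits & b$bits)
  uni <- sum(a$bits | b$bits)
  if (uni == 0L) {
    warning("both fingerprints are empty; Tanimoto defined as 0")
    return(0)
  }
  inter / uni
}

#' Tanimoto similarity matrix for a list of fingerprints
#' @param fps list of `fingerprint_vector` objects.
#' @return symmetric matrix of pairwise similarities.
#' @export
tanimoto_matrix <- function(fps) {
  B <- vapply(fps, function(f) f$bits, integer(fps[[1]]$n_bits))
  inter <- crossprod(B)
  pc <- colSums(B)
  uni <- outer(pc, pc, "+") - inter
  out <- ifelse(uni == 0, 0, inter / uni)
  dimnames(out) <- NULL
  out
}

#' Attach seeded 3D conformers to a molecule record
#'
#' Coordinates are embedded deterministically by a light distance-geometry
#' scheme: seeded random initial placement followed by iterative projection
#' onto covalent-radius bond-length targets with a soft nonbonded repulsion.
#' This reproduces chemically plausible bonded distances (e.g. C-C single
#' bonds near 1.52 A) and is bit-reproducible for a given seed; it makes no
#' claim of locating force-field energy minima.
#'
#' @param mol a `molecule_record`.
#' @param n_conf number of conformers (>= 1).
#' @param seed integer seed; conformer k uses sub-seed `seed + k`.
#' @return the record with `conformers` set to a list of n_atoms x 3
#'   coordinate matrices (Angstrom).
#' @export
generate_conformers <- function(mol, n_conf = 2L, seed = 1L) {
  stopifnot(inherits(mol, "molecule_record"), n_conf >= 1L)
  g <- mol$graph
  confs <- vector("list", n_conf)
  for (k in seq_len(n_conf)) {
    coords <- with_seed(seed * 1000L + k, .embed_coords(g))
    if (is.null(coords)) {
      warning("conformer embedding failed for '", mol$id, "' (conformer ",
              k, "); skipping")
      next
    }
    confs[[k]] <- coords
  }
  mol$conformers <- Filter(Negate(is.null), confs)
  mol
}

.bond_targets <- function(g) {
  if (nrow(g$edges) == 0L) return(numeric(0))
  ri <- CHEM_COV_RADIUS[ifelse(g$elements[g$edges[, "i"]] %in% CHEM_ELEMENTS,
                               g$elements[g$edges[, "i"]], "other")]
  rj <- CHEM_COV_RADIUS[ifelse(g$elements[g$edges[, "j"]] %in% CHEM_ELEMENTS,
                               g$elements[g$edges[, "j"]], "other")]
  unname((ri + rj) * BOND_LENGTH_FACTOR[g$edges[, "order"]])
}

.embed_coords <- function(g, sweeps = 250L) {
  n <- g$n_atoms
  coords <- matrix(stats::rnorm(n * 3), n, 3) * max(1, n^(1 / 3))
  if (n == 1L) return(coords)
  tgt <- .bond_targets(g)
  bi <- g$edges[, "i"]; bj <- g$edges[, "j"]
  bonded <- matrix(FALSE, n, n)
  bonded[cbind(bi, bj)] <- TRUE
  bonded[cbind(bj, bi)] <- TRUE
  for (s in seq_len(sweeps)) {
    # project bonds toward their target lengths
    for (b in seq_along(tgt)) {
      i <- bi[b]; j <- bj[b]
      d <- coords[i, ] - coords[j, ]
      len <- sqrt(sum(d * d))
      if (len < 1e-9) d <- c(1e-3, 0, 0) else d <- d / len
      corr <- 0.5 * (len - tgt[b])
      coords[i, ] <- coords[i, ] - corr * d
      coords[j, ] <- coords[j, ] + corr * d
    }
    # push apart nonbonded atoms closer than 2.0 A
    if (n > 2L && s %% 2L == 0L) {
      dm <- as.matrix(stats::dist(coords))
      close <- which(dm < 2.0 & upper.tri(dm), arr.ind = TRUE)
      for (r in seq_len(nrow(close))) {
        i <- close[r, 1]; j <- close[r, 2]
        if (bonded[i, j]) next
        d <- coords[i, ] - coords[j, ]
        len <- sqrt(sum(d * d))
        if (len < 1e-9) { d <- c(1e-3, 0, 0); len <- 1e-3 }
        push <- 0.25 * (2.0 - len) / len
        coords[i, ] <- coords[i, ] + push * d
        coords[j, ] <- coords[j, ] - push * d
      }
    }
  }
  # final bond-only polish
  for (s in seq_len(50L)) {
    for (b in seq_along(tgt)) {
      i <- bi[b]; j <- bj[b]
      d <- coords[i, ] - coords[j, ]
      len <- sqrt(sum(d * d))
      d <- d / len
      corr <- 0.5 * (len - tgt[b])
      coords[i, ] <- coords[i, ] - corr * d
      coords[j, ] <- coords[j, ] + corr * d
    }
  }
  if (any(!is.finite(coords))) return(NULL)
  coords
}

#' Read compounds from a CSV/TSV table of SMILES
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (".tsv" -> tab, otherwise comma).
#' @param smiles_col,id_col column names.
#' @param ... forwarded to [parse_molecule()].
#' @return list of `molecule_record` objects.
#' @export
read_compounds <- function(path, smiles_col = "smiles", id_col = "compound_id",
                           ...) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  stopifnot(smiles_col %in% names(df), id_col %in% names(df))
  mapply(function(s, i) parse_molecule(s, i, ...), df[[smiles_col]],
         df[[id_col]], SIMPLIFY = FALSE, USE.NAMES = FALSE)
}
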