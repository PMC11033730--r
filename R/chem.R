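## Chemistry primitives: canonical SMILES, molecular graphs, Morgan
## fingerprints, Tanimoto similarity, Bemis-Murcko scaffolds and
## nearest-neighbor lookup.  SMILES parsing and canonical forms come from
## OpenBabel (ChemmineOB); the circular fingerprint hashing and scaffold
## pruning operate on the parsed graph.

#' Canonicalize SMILES strings
#'
#' Converts SMILES to the OpenBabel canonical form.  Canonicalization is
#' deterministic and idempotent: equivalent notations of the same molecule
#' map to the same string, and canonical strings are fixed points.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, same length as the input.
#' @examples
#' canonicalize(c("C1=CC=CC=C1", "c1ccccc1"))
#' @export
canonicalize <- function(smiles) {
  if (length(smiles) == 0L) return(character(0))
  if (!is.character(smiles) || anyNA(smiles) || any(!nzchar(smiles)))
    .stopf("smiles must be non-empty strings")
  if (any(grepl("[[:space:]]", smiles)))
    .stopf("invalid molecule: SMILES must not contain whitespace (%s)",
           smiles[grepl("[[:space:]]", smiles)][1])
  tags <- paste0("m", seq_along(smiles))
  src <- paste0(paste(smiles, tags, collapse = "\n"), "\n")
  out <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", src))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  got <- vapply(parts, function(p) if (length(p) >= 2L) p[[2]] else "", "")
  can <- vapply(parts, `[[`, "", 1L)
  res <- can[match(tags, got)]
  if (anyNA(res) || any(!nzchar(res)))
    .stopf("invalid molecule: could not parse SMILES '%s'",
           smiles[which(is.na(res) | !nzchar(res))[1]])
  unname(res)
}

#' Build a molecule table
#'
#' Validates and canonicalizes a set of molecules.  The table (columns
#' `id`, `smiles`, `canonical_smiles`, `name`) is the unit every pipeline
#' stage keys on.
#'
#' @param id Character vector of unique molecule identifiers.
#' @param smiles SMILES strings, one per id.
#' @param name Optional display names.
#' @return A `data.frame` with one row per molecule.
#' @export
molecule_table <- function(id, smiles, name = NULL) {
  id <- as.character(id)
  if (anyDuplicated(id)) .stopf("duplicate molecule id: %s", id[duplicated(id)][1])
  if (length(id) != length(smiles)) .stopf("id and smiles lengths differ")
  data.frame(id = id, smiles = as.character(smiles),
             canonical_smiles = canonicalize(smiles),
             name = if (is.null(name)) NA_character_ else as.character(name),
             stringsAsFactors = FALSE)
}

#' Read a molecule table from CSV
#'
#' Expects a header `id,smiles[,name]`.  Rows whose SMILES fail to parse
#' are dropped with a warning (real catalogues contain biologics without
#' usable SMILES).
#'
#' @param path CSV file path.
#' @return Molecule table as from [molecule_table()].
#' @export
read_molecules <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("id", "smiles") %in% names(df)))
    .stopf("molecule CSV must have columns id,smiles")
  ok <- vapply(df$smiles, function(s) !inherits(try(canonicalize(s), silent = TRUE), "try-error"),
               logical(1))
  if (any(!ok))
    .warnf("dropping %d molecules with unparseable SMILES (e.g. id %s)",
           sum(!ok), df$id[!ok][1])
  df <- df[ok, , drop = FALSE]
  molecule_table(df$id, df$smiles, if ("name" %in% names(df)) df$name else NULL)
}

#' @rdname read_molecules
#' @param mols Molecule table.
#' @export
write_molecules <- function(mols, path) {
  write.csv(mols[, intersect(c("id", "smiles", "name"), names(mols))],
            path, row.names = FALSE, quote = FALSE)
}

# ---- molecular graphs -------------------------------------------------

# Parse canonical SMILES into light graph records: element symbols, 2D
# coordinates (for molfile round trips), bond table (a1, a2, order) and
# derived degree / ring-membership flags.
.mol_graphs <- function(canonical_smiles) {
  uniq <- unique(canonical_smiles)
  sdfs <- suppressWarnings(ChemmineR::smiles2sdf(uniq))
  graphs <- lapply(seq_along(uniq), function(k) {
    sdf <- sdfs[[k]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elem <- sub("_.*$", "", rownames(ab))
    n <- length(elem)
    if (is.null(bb) || length(bb) == 0L || ncol(bb) < 3L) {
      bonds <- matrix(integer(0), ncol = 3)
    } else {
      if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1, dimnames = list(NULL, names(bb)))
      bonds <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
      bonds <- bonds[bonds[, 1] >= 1L & bonds[, 2] >= 1L, , drop = FALSE]
    }
    deg <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = n)
    ring_bond <- .cycle_edges(n, bonds)
    ring_atom <- rep(FALSE, n)
    if (any(ring_bond)) ring_atom[unique(c(bonds[ring_bond, 1], bonds[ring_bond, 2]))] <- TRUE
    list(elem = elem, xy = ab[, 1:2, drop = FALSE], bonds = bonds,
         degree = deg, ring_bond = ring_bond, ring_atom = ring_atom)
  })
  names(graphs) <- uniq
  graphs[canonical_smiles]
}

# An edge lies on a cycle iff it is not a bridge: removing it leaves its
# endpoints connected.  Molecule graphs are tiny, so per-edge BFS is fine.
.cycle_edges <- function(n_atoms, bonds) {
  m <- nrow(bonds)
  if (m == 0L) return(logical(0))
  adj <- lapply(seq_len(n_atoms), function(i) integer(0))
  for (e in seq_len(m)) {
    a <- bonds[e, 1]; b <- bonds[e, 2]
    adj[[a]] <- c(adj[[a]], e)
    adj[[b]] <- c(adj[[b]], e)
  }
  other <- function(e, v) if (bonds[e, 1] == v) bonds[e, 2] else bonds[e, 1]
  vapply(seq_len(m), function(e) {
    src <- bonds[e, 1]; dst <- bonds[e, 2]
    seen <- rep(FALSE, n_atoms); seen[src] <- TRUE
    queue <- src
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (e2 in adj[[v]]) {
        if (e2 == e) next
        w <- other(e2, v)
        if (!seen[w]) {
          if (w == dst) return(TRUE)
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    FALSE
  }, logical(1))
}

.ELEMENT_Z <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
                S = 16, Cl = 17, Br = 35, I = 53)

# ---- Morgan fingerprints ----------------------------------------------

#' Morgan (circular) fingerprints
#'
#' Hashes circular atom environments of increasing radius into a
#' fixed-length bit vector, the standard substructure descriptor behind
#' Tanimoto similarity searches and fingerprint baselines.  Bit positions
#' are the environment hash modulo `n_bits`, so halving a power-of-two
#' `n_bits` folds the vector exactly (OR over index mod `n_bits/2`).
#'
#' @param smiles Character vector of SMILES (canonicalized internally).
#' @param radius Neighborhood radius; 2 is the community default.
#' @param n_bits Vector length; power of two, at least 64.
#' @param ids Optional molecule ids attached to the fingerprints.
#' @return A list of `fingerprint` objects (`bits` holds the sorted
#'   0-based positions of set bits).
#' @export
morgan_fingerprint <- function(smiles, radius = 2L, n_bits = 2048L, ids = NULL) {
  if (!.is_count(n_bits) || n_bits < 64 || bitwAnd(n_bits, n_bits - 1L) != 0)
    .stopf("n_bits must be a power of two >= 64")
  if (!is.numeric(radius) || radius < 0) .stopf("radius must be >= 0")
  can <- canonicalize(smiles)
  graphs <- .mol_graphs(can)
  if (is.null(ids)) ids <- names(smiles)
  fps <- lapply(seq_along(graphs), function(k) {
    g <- graphs[[k]]
    n <- length(g$elem)
    z <- .ELEMENT_Z[g$elem]
    z[is.na(z)] <- 0
    nb <- lapply(seq_len(n), function(i) integer(0))   # rows of (order, atom)
    if (nrow(g$bonds)) {
      for (e in seq_len(nrow(g$bonds))) {
        a <- g$bonds[e, 1]; b <- g$bonds[e, 2]; o <- g$bonds[e, 3]
        nb[[a]] <- rbind(nb[[a]], c(o, b))
        nb[[b]] <- rbind(nb[[b]], c(o, a))
      }
    }
    env_ids <- vapply(seq_len(n), function(i)
      .hash_ints(c(z[i], g$degree[i], as.integer(g$ring_atom[i]))), numeric(1))
    all_ids <- env_ids
    if (radius >= 1) for (r in seq_len(radius)) {
      env_ids <- vapply(seq_len(n), function(i) {
        nbi <- nb[[i]]
        if (is.null(dim(nbi)) || !length(nbi)) return(.hash_ints(c(env_ids[i], r)))
        pairs <- cbind(nbi[, 1], env_ids[nbi[, 2]])
        ord <- order(pairs[, 1], pairs[, 2])
        .hash_ints(c(env_ids[i], r, as.numeric(t(pairs[ord, , drop = FALSE]))))
      }, numeric(1))
      all_ids <- c(all_ids, env_ids)
    }
    structure(list(bits = sort(unique(as.integer(all_ids %% n_bits))),
                   n_bits = as.integer(n_bits), radius = as.integer(radius),
                   molecule_id = if (is.null(ids)) NA_character_ else ids[k]),
              class = "fingerprint")
  })
  if (!is.null(ids)) names(fps) <- ids
  fps
}

#' Tanimoto similarity between two fingerprints
#'
#' `|A intersect B| / |A union B|` on the set-bit positions.  Two empty
#' fingerprints are defined to have similarity 1 so duplicate featureless
#' molecules self-match.
#'
#' @param a,b `fingerprint` objects of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (a$n_bits != b$n_bits) .stopf("fingerprint lengths differ (%d vs %d)", a$n_bits, b$n_bits)
  u <- length(union(a$bits, b$bits))
  if (u == 0L) return(1.0)
  length(intersect(a$bits, b$bits)) / u
}

# All-pairs Tanimoto between two fingerprint lists via sparse cross
# products; returns a dense |A| x |B| matrix.
.tanimoto_cross <- function(fpsA, fpsB) {
  nb <- fpsA[[1]]$n_bits
  sp <- function(fps) Matrix::sparseMatrix(
    i = rep(seq_along(fps), vapply(fps, function(f) length(f$bits), 0L)),
    j = unlist(lapply(fps, function(f) f$bits)) + 1L,
    x = 1, dims = c(length(fps), nb))
  A <- sp(fpsA); B <- sp(fpsB)
  inter <- as.matrix(A %*% Matrix::t(B))
  pa <- Matrix::rowSums(A); pb <- Matrix::rowSums(B)
  un <- outer(pa, pb, "+") - inter
  out <- ifelse(un == 0, 1, inter / pmax(un, 1e-300))
  dimnames(out) <- list(names(fpsA), names(fpsB))
  out
}

# ---- Bemis-Murcko scaffolds -------------------------------------------

#' Bemis-Murcko scaffolds
#'
#' Reduces each molecule to its ring systems plus the linkers connecting
#' them, by iteratively pruning terminal atoms; acyclic molecules yield
#' the empty scaffold `""`.  Scaffold strings are canonical SMILES, so
#' molecules sharing a framework map to the same string — the grouping key
#' for scaffold-based data splits.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of scaffold SMILES (possibly `""`).
#' @export
bemis_murcko_scaffold <- function(smiles) {
  can <- canonicalize(smiles)
  uniq <- unique(can)
  graphs <- .mol_graphs(uniq)
  blocks <- character(length(uniq))
  for (k in seq_along(uniq)) {
    g <- graphs[[k]]
    keep <- rep(TRUE, length(g$elem))
    bonds <- g$bonds
    repeat {
      deg <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = length(g$elem))
      deg[!keep] <- NA
      drop <- which(keep & deg <= 1 & !g$ring_atom)
      if (sum(keep) <= 1 && !any(g$ring_atom)) drop <- which(keep)
      if (!length(drop)) break
      keep[drop] <- FALSE
      if (nrow(bonds)) bonds <- bonds[keep[bonds[, 1]] & keep[bonds[, 2]], , drop = FALSE]
    }
    blocks[k] <- if (!any(keep)) "" else .molfile(g, keep, bonds, paste0("s", k))
  }
  nonempty <- which(nzchar(blocks))
  scaff <- character(length(uniq))
  if (length(nonempty)) {
    src <- paste(blocks[nonempty], collapse = "")
    out <- suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", src))
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    parts <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
    got <- vapply(parts, function(p) if (length(p) >= 2L) p[[2]] else "", "")
    val <- vapply(parts, `[[`, "", 1L)
    scaff[nonempty] <- val[match(paste0("s", nonempty), got)]
  }
  unname(scaff[match(can, uniq)])
}

# Minimal V2000 molfile for the kept-atom subgraph, titled for batch
# conversion back to canonical SMILES.
.molfile <- function(g, keep, bonds, tag) {
  idx <- which(keep)
  remap <- integer(length(keep)); remap[idx] <- seq_along(idx)
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", length(idx), nrow(bonds))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   g$xy[idx, 1], g$xy[idx, 2], 0, g$elem[idx])
  bl <- if (nrow(bonds)) sprintf("%3d%3d%3d  0  0  0  0",
                                 remap[bonds[, 1]], remap[bonds[, 2]], bonds[, 3]) else character(0)
  paste(c(tag, "", "", counts, atoms, bl, "M  END", "$$$$", ""), collapse = "\n")
}

# ---- nearest neighbor --------------------------------------------------

#' Most chemically similar library member
#'
#' Finds the library molecule with maximal Tanimoto similarity (Morgan
#' fingerprints) to the query, returning it only when that maximum reaches
#' `threshold`.  Ties are broken by the lexicographically smallest
#' neighbor id so downstream imputation is reproducible.
#'
#' @param query One-row molecule table (or a SMILES string with `id`).
#' @param library Molecule table to search; must not contain the query id.
#' @param threshold Minimum similarity in `[0, 1]`; 0.7 is the catalogue
#'   default.
#' @param radius,n_bits Fingerprint parameters.
#' @return `NULL` when no member qualifies, else
#'   `list(neighbor_id, similarity)`.
#' @export
most_similar <- function(query, library, threshold = 0.7, radius = 2L, n_bits = 2048L) {
  if (threshold < 0 || threshold > 1) .stopf("threshold must be in [0,1]")
  if (nrow(library) == 0L) return(NULL)
  if (query$id %in% library$id) .stopf("query id %s present in library", query$id)
  fq <- morgan_fingerprint(query$canonical_smiles, radius, n_bits, ids = query$id)
  fl <- morgan_fingerprint(library$canonical_smiles, radius, n_bits, ids = library$id)
  sims <- .tanimoto_cross(fq, fl)[1, ]
  mx <- max(sims)
  if (mx < threshold) return(NULL)
  cand <- sort(library$id[sims == mx])
  list(neighbor_id = cand[1], similarity = unname(mx))
}

#' Export fingerprints as hex-encoded TSV
#'
#' @param fps List of fingerprints from [morgan_fingerprint()].
#' @param path Output TSV path (`id<TAB>hex`).
#' @export
write_fingerprints <- function(fps, path) {
  hex <- vapply(fps, function(f) {
    v <- integer(f$n_bits); v[f$bits + 1L] <- 1L
    paste(sprintf("%x", colSums(matrix(v, nrow = 4) * c(8L, 4L, 2L, 1L))), collapse = "")
  }, "")
  writeLines(paste(vapply(fps, function(f) f$molecule_id, ""), hex, sep = "\t"), path)
}
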