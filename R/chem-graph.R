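# Circular atom-environment identifiers and canonical forms.
#
# Identifiers are unsigned 32-bit values carried in doubles (exact under
# IEEE doubles up to 2^53; all intermediates stay below 2^49).

.HASH_MOD <- 2^32

#' Construct a molecular graph from a SMILES string
#'
#' Parses a daylight-style SMILES string into an atom/bond graph, assigns
#' implicit hydrogen counts, and computes per-atom circular substructure
#' identifiers ("environment identifiers") at radii `0..id_radius_max`,
#' following the extended-connectivity fingerprint construction: the radius-0
#' identifier hashes the atom invariant (atomic number, formal charge,
#' aromaticity, heavy-atom degree, hydrogen count) and each further radius
#' hashes the previous identifier together with the sorted
#' (bond type, neighbor identifier) pairs. Identifiers are deterministic
#' functions of the graph, independent of the input atom order, and
#' topologically equivalent atoms receive identical identifier tuples.
#'
#' Multi-fragment inputs (e.g. salt pairs such as
#' `"...[B-](F)(F)F.[K+]"`) are kept as a single graph with no bonds between
#' fragments. Stereochemistry and isotopes are ignored; hydrogens are
#' implicit (heavy-atom graph only).
#'
#' @param smiles A single SMILES string.
#' @param id_radius_max Largest environment radius (default 3, i.e. the
#'   diameter-6 / ECFP6 convention).
#' @return An object of class `mol_graph`: a list with `atoms` (tibble:
#'   `element`, `charge`, `aromatic`, `hcount`, `masked`), `bonds` (tibble:
#'   `i`, `j`, `order`, `aromatic`), `env_ids` (numeric matrix, one row per
#'   atom, one column per radius), and `canonical_smiles`.
#' @examples
#' g <- graph_from_smiles("c1ccccc1")
#' nrow(g$atoms)                     # 6
#' nrow(unique(as.data.frame(g$env_ids)))  # 1: all atoms equivalent
#' @export
graph_from_smiles <- function(smiles, id_radius_max = 3L) {
  stopifnot(id_radius_max >= 0L)
  p <- parse_smiles(smiles)
  atoms <- p$atoms
  atoms$hcount <- implicit_hydrogens(atoms, p$bonds)
  atoms$explicit_h <- NULL
  atoms$masked <- FALSE
  g <- structure(
    list(atoms = atoms, bonds = p$bonds, env_ids = NULL,
         canonical_smiles = NA_character_, smiles = smiles,
         id_radius_max = as.integer(id_radius_max)),
    class = "mol_graph"
  )
  g$env_ids <- compute_env_ids(g, id_radius_max)
  g$canonical_smiles <- write_canonical_smiles(g)
  g
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %d atoms, %d bonds: %s\n",
              nrow(x$atoms), nrow(x$bonds), x$canonical_smiles))
  invisible(x)
}

#' Placeholder for an absent reaction component
#'
#' Some reaction tables use the literal value `"none"` for a role that is
#' not filled (for example a ligand-free entry). Such components are
#' represented by this sentinel rather than a graph; the model maps them to
#' a single all-zero pseudo-atom so downstream matrix shapes stay valid.
#'
#' @return An object of class `mol_absent`.
#' @export
mol_absent <- function() structure(list(), class = "mol_absent")

#' @rdname mol_absent
#' @param x An object.
#' @export
is_absent <- function(x) inherits(x, "mol_absent")

# Adjacency/neighbor list: for each atom, a matrix of (neighbor, bond_code)
# rows. Bond code: 1, 2, 3 for fixed orders, 4 for aromatic.
bond_code <- function(order, aromatic) ifelse(aromatic, 4, order)

neighbor_list <- function(g) {
  n <- nrow(g$atoms)
  nb <- vector("list", n)
  for (a in seq_len(n)) nb[[a]] <- matrix(numeric(0), ncol = 2)
  b <- g$bonds
  if (nrow(b) > 0) {
    code <- bond_code(b$order, b$aromatic)
    for (k in seq_len(nrow(b))) {
      nb[[b$i[k]]] <- rbind(nb[[b$i[k]]], c(b$j[k], code[k]))
      nb[[b$j[k]]] <- rbind(nb[[b$j[k]]], c(b$i[k], code[k]))
    }
  }
  nb
}

hash_seq <- function(v) {
  h <- 2166136261 %% .HASH_MOD
  for (x in v) h <- (h * 69069 + (x %% .HASH_MOD) + 1) %% .HASH_MOD
  # second mixing pass to break multiplicative structure
  (h * 40503 + (h %/% 65536)) %% .HASH_MOD
}

compute_env_ids <- function(g, rmax = g$id_radius_max %||% 3L) {
  atoms <- g$atoms
  n <- nrow(atoms)
  nb <- neighbor_list(g)
  ids <- matrix(0, nrow = n, ncol = rmax + 1L)
  z <- unname(.atomic_number[atoms$element])
  z[is.na(z)] <- 0
  deg <- vapply(nb, nrow, integer(1))
  for (a in seq_len(n)) {
    ids[a, 1L] <- hash_seq(c(
      z[a], atoms$charge[a] + 512, as.integer(atoms$aromatic[a]),
      deg[a], atoms$hcount[a]
    ))
  }
  if (rmax >= 1L) {
    # coverage[[a]]: atoms inside a's current circular substructure; when
    # it stops growing the environment is saturated and the identifier is
    # carried over unchanged (no spurious new hash for the same fragment)
    coverage <- as.list(seq_len(n))
    for (r in seq_len(rmax)) {
      prev <- ids[, r]
      new_cov <- coverage
      for (a in seq_len(n)) {
        if (deg[a] > 0) {
          grown <- sort(unique(c(coverage[[a]],
                                 unlist(coverage[nb[[a]][, 1]]))))
        } else {
          grown <- coverage[[a]]
        }
        if (identical(grown, coverage[[a]])) {
          ids[a, r + 1L] <- prev[a]
        } else {
          pairs <- cbind(nb[[a]][, 2], prev[nb[[a]][, 1]])
          ord <- order(pairs[, 1], pairs[, 2])
          flat <- as.vector(t(pairs[ord, , drop = FALSE]))
          ids[a, r + 1L] <- hash_seq(c(r, prev[a], flat))
        }
        new_cov[[a]] <- grown
      }
      coverage <- new_cov
    }
  }
  colnames(ids) <- paste0("r", 0:rmax)
  ids
}

# Canonical atom ranks by iterative neighborhood refinement seeded from the
# environment identifiers, with individualization of tied classes. Atoms
# still tied after refinement at radius >= 3 are taken to be topologically
# equivalent (true for typical organic molecules; regular-graph
# counterexamples do not arise in reaction tables).
canonical_ranks <- function(g) {
  atoms <- g$atoms
  n <- nrow(atoms)
  if (n == 1L) return(1L)
  nb <- neighbor_list(g)
  env <- if (!is.null(g$env_ids)) g$env_ids else compute_env_ids(g, 3L)
  key0 <- apply(cbind(atoms$element, atoms$charge, atoms$aromatic,
                      atoms$hcount, env), 1, paste, collapse = "|")
  rk <- match(key0, sort(unique(key0)))

  refine <- function(rk) {
    repeat {
      key <- vapply(seq_len(n), function(a) {
        nbr <- if (nrow(nb[[a]]) > 0) {
          pr <- cbind(nb[[a]][, 2], rk[nb[[a]][, 1]])
          pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
          paste(as.vector(t(pr)), collapse = ",")
        } else ""
        paste(rk[a], nbr, sep = ";")
      }, character(1))
      # new classes ordered by (old rank, neighbor key) so refinement only
      # subdivides, never reorders, existing classes
      lev <- unique(key[order(rk, key)])
      new_rk <- match(key, lev)
      if (identical(new_rk, rk)) return(rk)
      rk <- new_rk
    }
  }
  rk <- refine(rk)
  while (anyDuplicated(rk) > 0) {
    dup_ranks <- sort(unique(rk[duplicated(rk)]))
    target <- dup_ranks[1]
    a <- which(rk == target)[1]
    rk[rk >= target & seq_len(n) != a] <- rk[rk >= target & seq_len(n) != a] + 1L
    rk <- refine(rk)
  }
  rk
}

# Deterministic canonical SMILES writer: DFS from the lowest-ranked atom of
# each fragment, visiting neighbors in canonical-rank order; ring-closure
# digits for back edges. Atoms are written bare when the organic-subset
# implicit-hydrogen rules would reconstruct the stored hydrogen count.
write_canonical_smiles <- function(g) {
  atoms <- g$atoms
  bonds <- g$bonds
  n <- nrow(atoms)
  rk <- canonical_ranks(g)
  nb <- neighbor_list(g)

  bond_sym <- function(order, aromatic, ar_i, ar_j) {
    if (aromatic) {
      if (ar_i && ar_j) "" else ":"
    } else if (order == 2) {
      "="
    } else if (order == 3) {
      "#"
    } else if (ar_i && ar_j) {
      "-"   # biaryl single bond: must be explicit or it reparses aromatic
    } else {
      ""
    }
  }
  bkey <- function(i, j) paste(min(i, j), max(i, j))
  bmap <- new.env(parent = emptyenv())
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) assign(bkey(bonds$i[k], bonds$j[k]), k, envir = bmap)
  }

  atom_token <- function(a) {
    el <- atoms$element[a]
    ar <- atoms$aromatic[a]
    sym <- if (ar) tolower(el) else el
    bare_ok <- el %in% names(.default_valence) && atoms$charge[a] == 0L
    if (bare_ok) {
      # would the implicit rule reproduce hcount?
      bsum <- 0
      if (nrow(nb[[a]]) > 0) {
        codes <- nb[[a]][, 2]
        bsum <- sum(ifelse(codes == 4, 1.5, codes))
      }
      v <- .default_valence[[el]]
      imp <- max(0L, as.integer(v - ceiling(bsum - 1e-9)))
      if (imp == atoms$hcount[a]) return(sym)
    }
    h <- atoms$hcount[a]
    hs <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    ch <- atoms$charge[a]
    cs <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
          else if (ch > 0L) paste0("+", ch) else paste0("-", abs(ch))
    paste0("[", sym, hs, cs, "]")
  }

  next_digit <- local({ d <- 0L; function() { d <<- d + 1L; d } })
  digit_str <- function(d) if (d <= 9L) as.character(d) else paste0("%", d)

  # Two-pass emission: a rank-ordered DFS first identifies back edges, then
  # the writer emits atoms with ring-closure digits attached at both ends.
  visited <- logical(n)
  parent_bond <- rep(NA_integer_, n)
  back_edges <- integer(0)
  order_visit <- integer(0)
  dfs_scan <- function(a, from_bond) {
    visited[a] <<- TRUE
    order_visit[[length(order_visit) + 1L]] <<- a
    nbrs <- nb[[a]]
    if (nrow(nbrs) == 0) return(invisible())
    nbrs <- nbrs[order(rk[nbrs[, 1]]), , drop = FALSE]
    for (r in seq_len(nrow(nbrs))) {
      b <- nbrs[r, 1]
      k <- get(bkey(a, b), envir = bmap)
      if (!is.na(from_bond) && k == from_bond) next
      if (visited[b]) {
        if (!(k %in% back_edges)) back_edges[[length(back_edges) + 1L]] <<- k
      } else {
        parent_bond[b] <<- k
        dfs_scan(b, k)
      }
    }
  }
  frag_roots <- integer(0)
  repeat {
    todo <- which(!visited)
    if (length(todo) == 0) break
    root <- todo[which.min(rk[todo])]
    frag_roots <- c(frag_roots, root)
    dfs_scan(root, NA_integer_)
  }

  # assign digits to back edges in order of first-touched atom in DFS order
  ring_at <- vector("list", n)
  digit_of <- integer(0)
  pos <- match(seq_len(n), order_visit)
  for (k in back_edges) {
    d <- next_digit()
    digit_of[as.character(k)] <- d
    for (a in c(bonds$i[k], bonds$j[k])) {
      ring_at[[a]] <- c(ring_at[[a]], k)
    }
  }

  visited2 <- logical(n)
  emit_atom <- function(a, from_bond) {
    visited2[a] <<- TRUE
    parts <- atom_token(a)
    for (k in ring_at[[a]] %||% integer(0)) {
      b <- if (bonds$i[k] == a) bonds$j[k] else bonds$i[k]
      sym <- bond_sym(bonds$order[k], bonds$aromatic[k],
                      atoms$aromatic[a], atoms$aromatic[b])
      parts <- paste0(parts, sym, digit_str(digit_of[[as.character(k)]]))
    }
    nbrs <- nb[[a]]
    if (nrow(nbrs) > 0) {
      nbrs <- nbrs[order(rk[nbrs[, 1]]), , drop = FALSE]
      kids <- integer(0)
      for (r in seq_len(nrow(nbrs))) {
        b <- nbrs[r, 1]
        k <- get(bkey(a, b), envir = bmap)
        if (!is.na(from_bond) && k == from_bond) next
        if (k %in% back_edges) next
        kids <- c(kids, r)
      }
      for (idx in seq_along(kids)) {
        r <- kids[idx]
        b <- nbrs[r, 1]
        k <- get(bkey(a, b), envir = bmap)
        sym <- bond_sym(bonds$order[k], bonds$aromatic[k],
                        atoms$aromatic[a], atoms$aromatic[b])
        sub <- emit_atom(b, k)
        if (idx < length(kids)) {
          parts <- paste0(parts, "(", sym, sub, ")")
        } else {
          parts <- paste0(parts, sym, sub)
        }
      }
    }
    parts
  }
  frags <- vapply(frag_roots, function(root) emit_atom(root, NA_integer_),
                  character(1))
  paste(frags, collapse = ".")
}

# Graph distance matrix (BFS over bonds); used by augmentation locality
# checks and tests.
graph_distances <- function(g) {
  n <- nrow(g$atoms)
  nb <- neighbor_list(g)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- unique(unlist(lapply(frontier, function(a) nb[[a]][, 1])))
      nxt <- nxt[is.finite(nxt) & D[s, nxt] == Inf]
      if (length(nxt) == 0) break
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}
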