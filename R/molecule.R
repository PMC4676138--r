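# Internal molecular-graph representation.
#
# A `sr_mol` stores the heavy-atom graph of one structure: element, formal
# charge, implicit-hydrogen count and aromaticity per atom, plus a bond table
# (order 1/2/3 with an aromatic flag).  Parsing and canonicalisation are
# delegated to OpenBabel; graph algorithms (rings, shortest paths) and the
# fragment SMILES writer are implemented here because they must operate on
# atom subsets and edited graphs.

sr_mol_from_smiles <- function(smiles) {
  can <- ob_canonical(smiles)
  if (!nzchar(can)) return(NULL)
  sdf <- ob_convert("SMI", "SDF", smiles, options = ob_opts("h"))
  m2 <- ob_convert("SMI", "MOL2", smiles, options = ob_opts("h"))
  if (!nzchar(sdf) || !nzchar(m2)) return(NULL)
  mb <- parse_molblock(sdf)
  t2 <- parse_mol2(m2)
  if (is.null(mb) || is.null(t2)) return(NULL)
  if (length(mb$element) != nrow(t2$atoms)) return(NULL)
  heavy <- which(mb$element != "H")
  idx <- integer(length(mb$element))
  idx[heavy] <- seq_along(heavy)
  nH <- integer(length(heavy))
  keep <- logical(nrow(mb$bonds))
  if (nrow(mb$bonds)) {
    for (b in seq_len(nrow(mb$bonds))) {
      a1 <- mb$bonds$a1[b]; a2 <- mb$bonds$a2[b]
      h1 <- mb$element[a1] == "H"; h2 <- mb$element[a2] == "H"
      if (h1 && !h2) nH[idx[a2]] <- nH[idx[a2]] + 1L
      if (h2 && !h1) nH[idx[a1]] <- nH[idx[a1]] + 1L
      keep[b] <- !h1 && !h2
    }
  }
  bonds <- mb$bonds[keep, , drop = FALSE]
  # MOL2 writes "ar" also for delocalised groups (carboxylate, guanidinium);
  # a bond is aromatic only when both atoms carry an aromatic atom type too.
  arom_bond <- logical(nrow(bonds))
  if (nrow(t2$bonds)) {
    ar <- t2$bonds$type == "ar" &
      t2$atoms$aromatic[t2$bonds$a1] & t2$atoms$aromatic[t2$bonds$a2]
    ar_keys <- with(t2$bonds[ar, , drop = FALSE],
                    paste(pmin(a1, a2), pmax(a1, a2)))
    arom_bond <- paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2)) %in% ar_keys
  }
  bonds <- data.frame(a1 = idx[bonds$a1], a2 = idx[bonds$a2],
                      order = bonds$order, aromatic = arom_bond)
  mol <- structure(list(
    smiles = can,
    n = length(heavy),
    element = mb$element[heavy],
    charge = mb$charge[heavy],
    aromatic = t2$atoms$aromatic[heavy],
    nH = nH,
    bonds = bonds
  ), class = "sr_mol")
  mol$ring_bond <- sr_ring_bonds(mol)
  mol$ring_atom <- sr_ring_atoms(mol)
  mol
}

#' @export
print.sr_mol <- function(x, ...) {
  cat("<sr_mol> ", x$smiles, " (", x$n, " heavy atoms)\n", sep = "")
  invisible(x)
}

# Heavy-atom adjacency list.
sr_adj <- function(mol) {
  adj <- vector("list", mol$n)
  for (i in seq_len(mol$n)) adj[[i]] <- integer()
  if (nrow(mol$bonds)) {
    for (b in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$a1[b]; j <- mol$bonds$a2[b]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

sr_degree <- function(mol) {
  d <- integer(mol$n)
  if (nrow(mol$bonds)) {
    t1 <- tabulate(mol$bonds$a1, mol$n)
    t2 <- tabulate(mol$bonds$a2, mol$n)
    d <- t1 + t2
  }
  d
}

# A bond is a ring bond iff its endpoints stay connected without it.
sr_ring_bonds <- function(mol) {
  nb <- nrow(mol$bonds)
  out <- logical(nb)
  if (nb == 0L) return(out)
  adj <- sr_adj(mol)
  for (b in seq_len(nb)) {
    i <- mol$bonds$a1[b]; j <- mol$bonds$a2[b]
    seen <- logical(mol$n); seen[i] <- TRUE
    queue <- i
    skip_used <- FALSE
    while (length(queue) && !seen[j]) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (v == i && w == j && !skip_used) { skip_used <- TRUE; next }
        if (w == j && v == i) next
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    out[b] <- seen[j]
  }
  out
}

sr_ring_atoms <- function(mol) {
  out <- logical(mol$n)
  rb <- which(mol$ring_bond %||% sr_ring_bonds(mol))
  out[c(mol$bonds$a1[rb], mol$bonds$a2[rb])] <- TRUE
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All-pairs topological distances by BFS (small molecules).
sr_dist_matrix <- function(mol) {
  n <- mol$n
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  adj <- sr_adj(mol)
  for (s in seq_len(n)) {
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.infinite(D[s, w])) {
          D[s, w] <- D[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  D
}

# Connected components over an atom subset; returns list of index vectors
# (indices into `atoms`).
sr_components <- function(mol, atoms = seq_len(mol$n)) {
  sub <- seq_along(atoms)
  pos <- integer(mol$n); pos[atoms] <- sub
  adj <- vector("list", length(atoms))
  for (k in sub) adj[[k]] <- integer()
  if (nrow(mol$bonds)) {
    for (b in seq_len(nrow(mol$bonds))) {
      i <- pos[mol$bonds$a1[b]]; j <- pos[mol$bonds$a2[b]]
      if (i > 0L && j > 0L) {
        adj[[i]] <- c(adj[[i]], j)
        adj[[j]] <- c(adj[[j]], i)
      }
    }
  }
  seen <- logical(length(atoms))
  comps <- list()
  for (s in sub) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; comp <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; comp <- c(comp, w); queue <- c(queue, w) }
    }
    comps[[length(comps) + 1L]] <- atoms[sort(comp)]
  }
  comps
}

AROMATIC_OK <- c("C", "N", "O", "S", "P", "B", "Se", "As")

sr_atom_token <- function(mol, i) {
  el <- mol$element[i]
  sym <- if (mol$aromatic[i] && el %in% AROMATIC_OK) {
    paste0(tolower(substr(el, 1, 1)), substring(el, 2))
  } else el
  h <- mol$nH[i]
  hpart <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
  q <- mol$charge[i]
  qpart <- if (q == 0L) "" else if (q == 1L) "+" else if (q == -1L) "-" else
    sprintf("%+d", q)
  paste0("[", sym, hpart, qpart, "]")
}

sr_bond_token <- function(mol, b) {
  if (mol$bonds$aromatic[b]) return(":")
  o <- mol$bonds$order[b]
  if (o == 2L) return("=")
  if (o == 3L) return("#")
  i <- mol$bonds$a1[b]; j <- mol$bonds$a2[b]
  # explicit single bond between two aromatic atoms (e.g. biphenyl link)
  if (mol$aromatic[i] && mol$aromatic[j]) "-" else ""
}

# Write (a subset of) a sr_mol as SMILES.  Not canonical; callers pass the
# result through ob_canonical() when a canonical key is needed.
sr_write_smiles <- function(mol, atoms = seq_len(mol$n)) {
  if (length(atoms) == 0L) return("")
  inset <- logical(mol$n); inset[atoms] <- TRUE
  bond_id <- matrix(0L, mol$n, mol$n)
  if (nrow(mol$bonds)) {
    for (b in seq_len(nrow(mol$bonds))) {
      bond_id[mol$bonds$a1[b], mol$bonds$a2[b]] <- b
      bond_id[mol$bonds$a2[b], mol$bonds$a1[b]] <- b
    }
  }
  adj <- sr_adj(mol)
  comps <- sr_components(mol, atoms)
  pieces <- character(length(comps))
  for (ci in seq_along(comps)) {
    comp <- comps[[ci]]
    root <- comp[1]
    visited <- logical(mol$n)
    parent <- integer(mol$n)
    order <- integer(0)
    stack <- root; visited[root] <- TRUE
    children <- vector("list", mol$n)
    back_edges <- list()
    # iterative DFS recording tree children and back edges
    dfs_stack <- list(root)
    seen_edge <- matrix(FALSE, 0, 0)
    used_back <- character(0)
    walk <- function(v) {
      order <<- c(order, v)
      for (w in adj[[v]]) {
        if (!inset[w]) next
        if (!visited[w]) {
          visited[w] <<- TRUE
          parent[w] <<- v
          children[[v]] <<- c(children[[v]], w)
          walk(w)
        } else if (w != parent[v]) {
          key <- paste(min(v, w), max(v, w))
          if (!(key %in% used_back)) {
            used_back <<- c(used_back, key)
            back_edges[[length(back_edges) + 1L]] <<- c(v, w)
          }
        }
      }
    }
    walk(root)
    ring_digits <- vector("list", mol$n)
    for (k in seq_along(back_edges)) {
      e <- back_edges[[k]]
      d <- if (k <= 9) as.character(k) else paste0("%", k)
      btok <- sr_bond_token(mol, bond_id[e[1], e[2]])
      ring_digits[[e[1]]] <- c(ring_digits[[e[1]]], paste0(btok, d))
      ring_digits[[e[2]]] <- c(ring_digits[[e[2]]], paste0(btok, d))
    }
    emit <- function(v) {
      out <- paste0(sr_atom_token(mol, v), paste0(ring_digits[[v]], collapse = ""))
      kids <- children[[v]]
      if (length(kids)) {
        for (k in seq_along(kids)) {
          w <- kids[k]
          btok <- sr_bond_token(mol, bond_id[v, w])
          sub <- paste0(btok, emit(w))
          out <- if (k < length(kids)) paste0(out, "(", sub, ")") else paste0(out, sub)
        }
      }
      out
    }
    pieces[ci] <- emit(root)
  }
  paste(pieces, collapse = ".")
}

# Rebuild a sr_mol after graph edits (charges / hydrogen counts changed).
sr_reparse <- function(mol) {
  smi <- sr_write_smiles(mol)
  sr_mol_from_smiles(smi)
}
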