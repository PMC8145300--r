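# Canonical atom ordering and SMILES output.
#
# Canonicalization uses iterative neighbourhood refinement (Morgan-style)
# followed by individualization of tied atoms, taking the labelling with
# the lexicographically smallest certificate. Molecules in this domain are
# small, so the worst-case branching on symmetric cells is cheap.

atom_invariants <- function(mol) {
  deg <- atom_degrees(mol)
  paste(mol$atoms$element, mol$atoms$aromatic, mol$atoms$charge,
        mol$atoms$nH, deg, sep = "|")
}

refine_ranks <- function(mol, ranks, adj, bond_of) {
  n <- n_atoms(mol)
  repeat {
    keys <- character(n)
    for (i in seq_len(n)) {
      nb <- adj[[i]]
      if (length(nb)) {
        tok <- sort(paste0(bond_of[[i]], ":", formatC(ranks[nb], width = 4, flag = "0")))
        keys[i] <- paste0(formatC(ranks[i], width = 4, flag = "0"), "|",
                          paste(tok, collapse = ","))
      } else {
        keys[i] <- formatC(ranks[i], width = 4, flag = "0")
      }
    }
    new_ranks <- match(keys, sort(unique(keys)))
    if (identical(new_ranks, ranks)) return(ranks)
    ranks <- new_ranks
  }
}

# Certificate for a total order: atom invariant sequence + sorted edge list.
order_certificate <- function(mol, perm_rank) {
  ord <- order(perm_rank)
  pos <- integer(length(ord)); pos[ord] <- seq_along(ord)
  inv <- atom_invariants(mol)
  a_part <- paste(inv[ord], collapse = ";")
  b <- mol$bonds
  if (nrow(b)) {
    p1 <- pmin(pos[b$a1], pos[b$a2]); p2 <- pmax(pos[b$a1], pos[b$a2])
    e_part <- paste(sort(sprintf("%03d-%03d-%d", p1, p2, b$order)), collapse = ";")
  } else e_part <- ""
  paste(a_part, e_part, sep = "#")
}

# Returns the canonical rank (1..n, all distinct) of each atom.
canonical_ranks <- function(mol) {
  n <- n_atoms(mol)
  if (n == 1L) return(1L)
  adj <- adjacency_list(mol)
  bond_of <- vector("list", n)
  for (i in seq_len(n)) bond_of[[i]] <- integer(0)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    bond_of[[b$a1[k]]] <- c(bond_of[[b$a1[k]]], b$order[k])
    bond_of[[b$a2[k]]] <- c(bond_of[[b$a2[k]]], b$order[k])
  }
  # bond_of[[i]] must align with adj[[i]] ordering: rebuild pairwise
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    bo <- integer(length(nb))
    for (j in seq_along(nb)) {
      hit <- which((b$a1 == i & b$a2 == nb[j]) | (b$a2 == i & b$a1 == nb[j]))[1]
      bo[j] <- b$order[hit]
    }
    bond_of[[i]] <- bo
  }

  init <- match(atom_invariants(mol), sort(unique(atom_invariants(mol))))

  search <- function(ranks) {
    ranks <- refine_ranks(mol, ranks, adj, bond_of)
    tab <- table(ranks)
    if (all(tab == 1L)) {
      return(list(cert = order_certificate(mol, ranks), ranks = ranks))
    }
    cell_rank <- as.integer(names(tab)[tab > 1L])[1]
    members <- which(ranks == cell_rank)
    best <- NULL
    for (a in members) {
      r2 <- ranks * 2L
      r2[a] <- r2[a] - 1L
      r2 <- match(r2, sort(unique(r2)))
      cand <- search(r2)
      if (is.null(best) || cand$cert < best$cert) best <- cand
    }
    best
  }
  search(init)$ranks
}

# Decide whether an atom needs a bracket expression when written.
needs_bracket <- function(mol, i, order_sum, arom_bond) {
  a <- mol$atoms[i, ]
  if (a$charge != 0L) return(TRUE)
  if (!(a$element %in% .organic_subset)) return(TRUE)
  if (a$aromatic && !(tolower(a$element) %in% .aromatic_ok)) return(TRUE)
  implied <- implicit_h_count(a$element, 0L, order_sum, aromatic = arom_bond)
  implied != a$nH
}

atom_token <- function(mol, i, order_sum, arom_bond) {
  a <- mol$atoms[i, ]
  sym <- if (a$aromatic) tolower(a$element) else a$element
  if (!needs_bracket(mol, i, order_sum, arom_bond)) return(sym)
  h <- if (a$nH == 0L) "" else if (a$nH == 1L) "H" else paste0("H", a$nH)
  ch <- if (a$charge == 0L) "" else if (a$charge == 1L) "+" else if (a$charge == -1L) "-"
        else sprintf("%+d", a$charge)
  paste0("[", sym, h, ch, "]")
}

bond_token <- function(order, arom1, arom2) {
  if (order == BOND_AROMATIC) return(if (arom1 && arom2) "" else ":")
  if (order == 1L) return(if (arom1 && arom2) "-" else "")
  if (order == 2L) return("=")
  if (order == 3L) return("#")
  stop("bad bond order")
}

#' Write a molecule as SMILES
#'
#' @param mol an `acidstab_mol`
#' @param canonical use the canonical atom ordering (default) so that equal
#'   structures yield identical text
#' @return character scalar SMILES
#' @export
write_smiles <- function(mol, canonical = TRUE) {
  comp <- mol_components(mol)
  if (max(comp) > 1L) {
    parts <- vapply(seq_len(max(comp)),
                    function(ci) write_smiles(subset_molecule(mol, which(comp == ci)),
                                              canonical = canonical), "")
    return(paste(sort(parts), collapse = "."))
  }
  n <- n_atoms(mol)
  ranks <- if (canonical) canonical_ranks(mol) else seq_len(n)
  sums <- bond_order_sums(mol)
  aromf <- has_aromatic_bond(mol)
  adj <- adjacency_list(mol)
  b <- mol$bonds
  border <- function(i, j) b$order[which((b$a1 == pmin(i, j)) & (b$a2 == pmax(i, j)))[1]]

  visited <- logical(n)
  ring_num <- 0L
  ring_marks <- vector("list", n)   # per atom: list of (digit, bond token)
  for (i in seq_len(n)) ring_marks[[i]] <- list()
  out <- character(0)

  emit_atom <- function(i) {
    tok <- atom_token(mol, i, sums[i], aromf[i])
    marks <- ring_marks[[i]]
    if (length(marks)) {
      ms <- vapply(marks, function(m) {
        d <- if (m$digit > 9L) paste0("%", m$digit) else as.character(m$digit)
        paste0(m$bond, d)
      }, "")
      tok <- paste0(tok, paste(ms, collapse = ""))
    }
    tok
  }

  # first pass: DFS assigning ring-closure digits
  parent <- rep(NA_integer_, n)
  dfs_order <- integer(0)
  tree_children <- vector("list", n)
  closure_seen <- new.env(parent = emptyenv())
  assign_digits <- function(root) {
    stack <- list(root)
    visited[root] <<- TRUE
    # iterative DFS preserving neighbor order by rank
    recurse <- function(v) {
      dfs_order <<- c(dfs_order, v)
      nb <- adj[[v]][order(ranks[adj[[v]]])]
      for (w in nb) {
        if (!is.na(parent[v]) && w == parent[v]) next
        key <- paste(pmin(v, w), pmax(v, w))
        if (visited[w]) {
          if (is.null(closure_seen[[key]])) {
            closure_seen[[key]] <- TRUE
            ring_num <<- ring_num + 1L
            ord <- border(v, w)
            btok <- bond_token(ord, mol$atoms$aromatic[v], mol$atoms$aromatic[w])
            ring_marks[[v]] <<- c(ring_marks[[v]], list(list(digit = ring_num, bond = btok)))
            ring_marks[[w]] <<- c(ring_marks[[w]], list(list(digit = ring_num, bond = "")))
          }
        } else {
          visited[w] <<- TRUE
          parent[w] <<- v
          tree_children[[v]] <<- c(tree_children[[v]], w)
          recurse(w)
        }
      }
    }
    recurse(root)
  }
  root <- which.min(ranks)
  assign_digits(root)

  write_from <- function(v) {
    s <- emit_atom(v)
    kids <- tree_children[[v]]
    if (length(kids)) {
      for (k in seq_along(kids)) {
        w <- kids[k]
        ord <- border(v, w)
        btok <- bond_token(ord, mol$atoms$aromatic[v], mol$atoms$aromatic[w])
        piece <- paste0(btok, write_from(w))
        if (k < length(kids)) piece <- paste0("(", piece, ")")
        s <- paste0(s, piece)
      }
    }
    s
  }
  write_from(root)
}
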