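# Molecular graph container used by every downstream stage.
#
# A molecule is a light list:
#   atoms: data.frame(element, charge, nH, aromatic)
#   bonds: data.frame(a1, a2, order)  with order 1, 2, 3 or 4 (= aromatic)
# Hydrogens are implicit (nH per heavy atom); only heavy atoms are vertices.

BOND_AROMATIC <- 4L

# Allowed valences per element for the chemical space handled here:
# SPONCH + halogens + Si. Charged atoms shift the allowed set by the charge.
.allowed_valences <- list(
  C = 4, N = 3, O = 2, S = c(2, 4, 6), P = c(3, 5),
  Si = 4, B = 3, F = 1, Cl = 1, Br = 1, I = 1, H = 1
)

# Elements writable without brackets in SMILES (organic subset).
.organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.aromatic_ok   <- c("b", "c", "n", "o", "p", "s")

#' Construct a molecule object
#'
#' Low-level constructor for the heavy-atom graph used throughout the
#' package. Most users will obtain molecules from [parse_molecule()] rather
#' than calling this directly.
#'
#' @param atoms data.frame with columns `element`, `charge`, `nH`,
#'   `aromatic` (one row per heavy atom).
#' @param bonds data.frame with columns `a1`, `a2`, `order`; `order` is
#'   1, 2, 3 or 4 (aromatic).
#' @return An object of class `acidstab_mol`.
#' @export
new_molecule <- function(atoms, bonds) {
  stopifnot(is.data.frame(atoms), is.data.frame(bonds))
  atoms$element  <- as.character(atoms$element)
  atoms$charge   <- as.integer(atoms$charge)
  atoms$nH       <- as.integer(atoms$nH)
  atoms$aromatic <- as.logical(atoms$aromatic)
  if (nrow(bonds)) {
    swap <- bonds$a1 > bonds$a2
    tmp <- bonds$a1[swap]; bonds$a1[swap] <- bonds$a2[swap]; bonds$a2[swap] <- tmp
  }
  bonds$a1 <- as.integer(bonds$a1); bonds$a2 <- as.integer(bonds$a2)
  bonds$order <- as.integer(bonds$order)
  structure(list(atoms = atoms, bonds = bonds), class = "acidstab_mol")
}

#' @export
print.acidstab_mol <- function(x, ...) {
  cat(sprintf("<molecule: %d heavy atoms, %d bonds> %s\n",
              n_atoms(x), nrow(x$bonds),
              tryCatch(write_smiles(x), error = function(e) "")))
  invisible(x)
}

#' Number of heavy atoms in a molecule
#' @param mol an `acidstab_mol`
#' @return integer count of non-hydrogen atoms
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

# Sum of bond orders incident to each atom. Aromatic bonds count 1 each;
# the delocalized pi system contributes at most one extra unit per atom,
# handled separately (see has_aromatic_bond / implicit_h_count).
bond_order_sums <- function(mol) {
  s <- numeric(n_atoms(mol))
  if (nrow(mol$bonds)) {
    ord <- ifelse(mol$bonds$order == BOND_AROMATIC, 1, mol$bonds$order)
    for (i in seq_len(nrow(mol$bonds))) {
      s[mol$bonds$a1[i]] <- s[mol$bonds$a1[i]] + ord[i]
      s[mol$bonds$a2[i]] <- s[mol$bonds$a2[i]] + ord[i]
    }
  }
  s
}

# TRUE per atom when at least one incident bond is aromatic.
has_aromatic_bond <- function(mol) {
  f <- logical(n_atoms(mol))
  if (nrow(mol$bonds)) {
    ar <- mol$bonds$order == BOND_AROMATIC
    f[unique(c(mol$bonds$a1[ar], mol$bonds$a2[ar]))] <- TRUE
  }
  f
}

# Heavy-atom degree of each atom.
atom_degrees <- function(mol) {
  d <- integer(n_atoms(mol))
  if (nrow(mol$bonds)) {
    t1 <- tabulate(mol$bonds$a1, nbins = n_atoms(mol))
    t2 <- tabulate(mol$bonds$a2, nbins = n_atoms(mol))
    d <- t1 + t2
  }
  d
}

allowed_valences_for <- function(element, charge = 0L) {
  base <- .allowed_valences[[element]]
  if (is.null(base)) return(NULL)
  v <- base + charge
  v[v >= 0]
}

# Implicit hydrogen count for an organic-subset atom given its bond order
# sum: fill up to the smallest allowed valence that accommodates the bonds.
# For an aromatic atom a single pi increment is added when an allowed
# valence can accommodate it (benzene CH: 2 ring bonds + pi + 1 H = 4);
# heteroatoms whose valence cannot absorb the increment (furan O,
# pyrrole-type N written [nH]) contribute the lone pair instead.
implicit_h_count <- function(element, charge, order_sum, aromatic = FALSE) {
  v <- allowed_valences_for(element, charge)
  if (is.null(v)) return(0L)
  v <- sort(v)
  for (need in unique(c(if (aromatic) order_sum + 1L, order_sum))) {
    need <- as.integer(need)
    fit <- v[v >= need]
    if (length(fit)) return(as.integer(fit[1] - need))
  }
  0L
}

# Check every atom's valence against the allowed table. Returns character(0)
# when valid, otherwise one message per offending atom.
valence_violations <- function(mol) {
  sums <- bond_order_sums(mol)
  arom <- has_aromatic_bond(mol)
  out <- character(0)
  for (i in seq_len(n_atoms(mol))) {
    a <- mol$atoms[i, ]
    v <- allowed_valences_for(a$element, a$charge)
    if (is.null(v)) {
      out <- c(out, sprintf("atom %d: element %s outside supported set", i, a$element))
      next
    }
    tot <- as.integer(sums[i]) + a$nH
    cand <- if (arom[i]) c(tot + 1L, tot) else tot
    if (!any(cand %in% v))
      out <- c(out, sprintf("atom %d (%s%+d): valence %d not in {%s}",
                            i, a$element, a$charge, tot, paste(v, collapse = ",")))
  }
  out
}

# Connected components of the heavy-atom graph (integer component id per atom).
mol_components <- function(mol) {
  n <- n_atoms(mol)
  comp <- integer(n)
  adj <- adjacency_list(mol)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cid; queue <- c(queue, w) }
    }
  }
  comp
}

adjacency_list <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(mol$bonds)) {
    for (i in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

# Subset a molecule to the given atom indices (renumbering bonds).
subset_molecule <- function(mol, keep) {
  keep <- sort(unique(as.integer(keep)))
  map <- integer(n_atoms(mol)); map[keep] <- seq_along(keep)
  b <- mol$bonds
  b <- b[b$a1 %in% keep & b$a2 %in% keep, , drop = FALSE]
  b$a1 <- map[b$a1]; b$a2 <- map[b$a2]
  new_molecule(mol$atoms[keep, , drop = FALSE], b)
}

# Shortest cycle through each bond; returns the graph girth (Inf if acyclic).
mol_girth <- function(mol) {
  n <- n_atoms(mol)
  if (!nrow(mol$bonds)) return(Inf)
  pairs <- unique(mol$bonds[, c("a1", "a2")])
  best <- Inf
  for (i in seq_len(nrow(pairs))) {
    u <- pairs$a1[i]; v <- pairs$a2[i]
    # BFS from u to v avoiding the direct edge u-v
    dist <- rep(NA_integer_, n); dist[u] <- 0L
    queue <- u
    while (length(queue)) {
      x <- queue[[1]]; queue <- queue[-1]
      nb <- c(mol$bonds$a2[mol$bonds$a1 == x], mol$bonds$a1[mol$bonds$a2 == x])
      for (w in nb) {
        if ((x == u && w == v) || (x == v && w == u)) next
        if (is.na(dist[w])) { dist[w] <- dist[x] + 1L; queue <- c(queue, w) }
      }
    }
    if (!is.na(dist[v])) best <- min(best, dist[v] + 1)
  }
  best
}

#' Molecular formula of a molecule
#'
#' Hill-order formula including implicit hydrogens.
#' @param mol an `acidstab_mol`
#' @return character scalar, e.g. `"C2H6O"`
#' @export
mol_formula <- function(mol) {
  counts <- table(mol$atoms$element)
  h <- sum(mol$atoms$nH)
  els <- names(counts)
  ord <- c("C", setdiff(sort(els), "C"))
  parts <- character(0)
  for (e in ord) {
    if (!e %in% els) next
    n <- counts[[e]]
    parts <- c(parts, paste0(e, if (n > 1) n else ""))
    if (e == "C" && h > 0) { parts <- c(parts, paste0("H", if (h > 1) h else "")); h <- 0 }
  }
  if (h > 0) parts <- c(parts, paste0("H", if (h > 1) h else ""))
  paste(parts, collapse = "")
}

#' Elements present in a molecule
#' @param mol an `acidstab_mol`
#' @param include_h include implicit hydrogen as `"H"`?
#' @return character vector of unique element symbols
#' @export
mol_elements <- function(mol, include_h = FALSE) {
  e <- unique(mol$atoms$element)
  if (include_h && sum(mol$atoms$nH) > 0) e <- union(e, "H")
  sort(e)
}
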