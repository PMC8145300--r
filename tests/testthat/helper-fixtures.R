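# Shared fixtures and independent oracles, built in code.

# Renumber the atoms of a molecule by a permutation (perm[i] = new index of
# old atom i); used to check invariance of canonical forms and counts.
permute_mol <- function(mol, perm) {
  atoms <- mol$atoms[order(perm), , drop = FALSE]
  rownames(atoms) <- NULL
  b <- mol$bonds
  b$a1 <- perm[b$a1]; b$a2 <- perm[b$a2]
  acidstab:::new_molecule(atoms, b)
}

# A two-group toy registry with known priorities.
toy_registry <- function() {
  register_groups(list(
    functional_group("diol", "1,2-diol", "[OX2H][CX4][CX4][OX2H]", 90),
    functional_group("alcohol", "alcohol", "[OX2H][CX4]", 60)
  ))
}

# Flat rate grid: constant ln k everywhere (k in s^-1).
flat_grid <- function(group_id, k,
                      wt = c(60, 80, 100), Tk = c(250, 300, 350)) {
  rate_grid(group_id, wt, Tk, matrix(log(k), length(wt), length(Tk)))
}

# Independent brute-force substructure counter: tries every injective
# assignment of pattern atoms to molecule atoms by explicit enumeration,
# then counts distinct matched atom sets. Only for tiny cases.
brute_force_match_sets <- function(pattern, mol) {
  pat <- acidstab:::parse_smarts(pattern)
  np <- length(pat$atoms); nm <- acidstab::n_atoms(mol)
  if (np > nm) return(list())
  deg <- acidstab:::atom_degrees(mol)
  arom <- acidstab:::has_aromatic_bond(mol)
  b <- mol$bonds
  order_of <- function(i, j) {
    hit <- which(b$a1 == min(i, j) & b$a2 == max(i, j))
    if (length(hit)) b$order[hit[1]] else 0L
  }
  sets <- list()
  idx <- utils::combn(nm, np, simplify = FALSE)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  for (subset in idx) for (assign in perms(subset)) {
    ok <- TRUE
    for (p in seq_len(np))
      if (!any(vapply(pat$atoms[[p]], acidstab:::patom_ok, TRUE,
                      mol = mol, i = assign[p], deg = deg, arom = arom))) {
        ok <- FALSE; break
      }
    if (!ok) next
    pb <- pat$bonds
    for (e in seq_len(nrow(pb))) {
      o <- order_of(assign[pb$a1[e]], assign[pb$a2[e]])
      if (o == 0L || !acidstab:::pbond_ok(pb$type[e], o)) { ok <- FALSE; break }
    }
    if (ok) sets[[length(sets) + 1]] <- sort(assign)
  }
  keys <- vapply(sets, paste, "", collapse = ",")
  sets[!duplicated(keys)]
}

# RDKit (via the system python) as an independent canonicalization oracle.
rdkit_canonical <- function(smiles) {
  script <- paste(
    "import sys",
    "from rdkit import Chem",
    "for s in sys.argv[1:]:",
    "    m = Chem.MolFromSmiles(s)",
    "    print('FAIL' if m is None else Chem.MolToSmiles(m))",
    sep = "\n")
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script), vapply(smiles, shQuote, "")),
            stdout = TRUE, stderr = FALSE))
  if (length(out) != length(smiles)) return(NULL)
  out
}
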