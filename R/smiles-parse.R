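# SMILES reader (Daylight dialect, stereo-agnostic).
#
# Supported: organic-subset atoms, bracket atoms with charge / explicit H /
# isotopes (isotopes accepted and discarded), aromatic lowercase atoms,
# bonds - = # : (/ and \ are read as single bonds), branches, ring-bond
# closures including %nn, and dot-separated components. Stereochemistry
# (@, @@) is accepted and discarded: the pipeline is stereo-agnostic.

.parse_fail <- function(msg) stop(msg, call. = FALSE)

# Tokenize + build graph for one SMILES string. Returns an acidstab_mol or
# stops with an informative message.
read_smiles_graph <- function(smiles) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  atoms <- list()
  bonds <- list()
  prev_stack <- list()        # branch stack
  prev <- NA_integer_        # current attachment atom
  pending_bond <- NA_integer_ # bond order queued by a bond symbol
  ring_open <- list()         # closure digit -> list(atom, order)
  i <- 1L

  add_atom <- function(element, charge, nH, aromatic, explicit_h) {
    atoms[[length(atoms) + 1L]] <<- list(element = element, charge = charge,
                                         nH = nH, aromatic = aromatic,
                                         explicit_h = explicit_h)
    idx <- length(atoms)
    if (!is.na(prev)) {
      ord <- pending_bond
      if (is.na(ord)) {
        ord <- if (aromatic && atoms[[prev]]$aromatic) BOND_AROMATIC else 1L
      }
      bonds[[length(bonds) + 1L]] <<- c(prev, idx, ord)
    }
    pending_bond <<- NA_integer_
    prev <<- idx
    invisible(idx)
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      if (is.na(prev)) .parse_fail("branch before any atom")
      prev_stack[[length(prev_stack) + 1L]] <- prev
      i <- i + 1L
    } else if (ch == ")") {
      if (!length(prev_stack)) .parse_fail("unmatched ')'")
      prev <- prev_stack[[length(prev_stack)]]
      prev_stack[[length(prev_stack)]] <- NULL
      i <- i + 1L
    } else if (ch %in% c("-", "/", "\\")) {
      pending_bond <- 1L; i <- i + 1L
    } else if (ch == "=") {
      pending_bond <- 2L; i <- i + 1L
    } else if (ch == "#") {
      pending_bond <- 3L; i <- i + 1L
    } else if (ch == ":") {
      pending_bond <- BOND_AROMATIC; i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_; pending_bond <- NA_integer_; i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > n) .parse_fail("truncated %nn ring closure")
        key <- paste0(chars[i + 1L], chars[i + 2L]); i <- i + 3L
      } else {
        key <- ch; i <- i + 1L
      }
      if (is.na(prev)) .parse_fail("ring closure before any atom")
      if (!is.null(ring_open[[key]])) {
        op <- ring_open[[key]]
        ord <- pending_bond
        if (is.na(ord)) ord <- op$order
        if (is.na(ord)) {
          ord <- if (atoms[[prev]]$aromatic && atoms[[op$atom]]$aromatic)
            BOND_AROMATIC else 1L
        }
        if (op$atom == prev) .parse_fail("ring closure to self")
        bonds[[length(bonds) + 1L]] <- c(op$atom, prev, ord)
        ring_open[[key]] <- NULL
        pending_bond <- NA_integer_
      } else {
        ring_open[[key]] <- list(atom = prev, order = pending_bond)
        pending_bond <- NA_integer_
      }
    } else if (ch == "[") {
      close <- NA_integer_
      for (j in (i + 1L):n) if (chars[j] == "]") { close <- j; break }
      if (is.na(close)) .parse_fail("unmatched '['")
      body <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      at <- parse_bracket_atom(body)
      add_atom(at$element, at$charge, at$nH, at$aromatic, explicit_h = TRUE)
      i <- close + 1L
    } else {
      # organic subset atom, possibly two-letter (Cl, Br)
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, 0L, NA_integer_, FALSE, explicit_h = FALSE)
        i <- i + 2L
      } else if (ch %in% .organic_subset) {
        add_atom(ch, 0L, NA_integer_, FALSE, explicit_h = FALSE)
        i <- i + 1L
      } else if (ch %in% .aromatic_ok) {
        add_atom(toupper(ch), 0L, NA_integer_, TRUE, explicit_h = FALSE)
        i <- i + 1L
      } else {
        .parse_fail(sprintf("unexpected character '%s' at position %d", ch, i))
      }
    }
  }
  if (length(prev_stack)) .parse_fail("unmatched '('")
  if (length(ring_open)) .parse_fail("unclosed ring bond")
  if (!length(atoms)) .parse_fail("no atoms")

  adf <- data.frame(
    element  = vapply(atoms, `[[`, "", "element"),
    charge   = vapply(atoms, `[[`, 0L, "charge"),
    nH       = vapply(atoms, `[[`, NA_integer_, "nH"),
    aromatic = vapply(atoms, `[[`, FALSE, "aromatic"),
    stringsAsFactors = FALSE
  )
  bdf <- if (length(bonds)) {
    m <- do.call(rbind, bonds)
    data.frame(a1 = m[, 1], a2 = m[, 2], order = m[, 3])
  } else data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  if (anyDuplicated(paste(pmin(bdf$a1, bdf$a2), pmax(bdf$a1, bdf$a2))))
    .parse_fail("duplicate bond between one atom pair")
  mol <- new_molecule(adf, bdf)

  # fill implicit hydrogens for organic-subset atoms written without brackets
  sums <- bond_order_sums(mol)
  arom <- has_aromatic_bond(mol)
  for (k in seq_len(n_atoms(mol))) {
    if (is.na(mol$atoms$nH[k]))
      mol$atoms$nH[k] <- implicit_h_count(mol$atoms$element[k],
                                          mol$atoms$charge[k], sums[k],
                                          aromatic = arom[k])
  }
  mol
}

# Body of a bracket atom expression, e.g. "NH4+", "13CH3", "Si", "O-", "nH".
parse_bracket_atom <- function(body) {
  rest <- sub("^[0-9]+", "", body)                    # strip isotope
  m <- regmatches(rest, regexpr("^([A-Z][a-z]?|[a-z])", rest))
  if (!length(m)) .parse_fail(sprintf("bad bracket atom [%s]", body))
  sym <- m
  rest <- substring(rest, nchar(sym) + 1L)
  aromatic <- sym %in% .aromatic_ok
  element <- if (aromatic) toupper(sym) else sym
  rest <- gsub("@", "", rest, fixed = TRUE)           # discard stereo
  nH <- 0L
  hm <- regmatches(rest, regexpr("H[0-9]*", rest))
  if (length(hm)) {
    nH <- if (nchar(hm) == 1L) 1L else as.integer(substring(hm, 2L))
    rest <- sub("H[0-9]*", "", rest)
  }
  charge <- 0L
  cm <- regmatches(rest, regexpr("(\\+[0-9]+|-[0-9]+|\\++|-+)", rest))
  if (length(cm)) {
    charge <- if (grepl("^[+-][0-9]", cm)) {
      as.integer(cm)
    } else {
      (nchar(cm)) * if (substring(cm, 1, 1) == "+") 1L else -1L
    }
    rest <- sub("(\\+[0-9]+|-[0-9]+|\\++|-+)", "", rest)
  }
  rest <- sub("^:[0-9]+", "", rest)                   # atom map, discard
  if (nchar(rest)) .parse_fail(sprintf("unsupported bracket content [%s]", body))
  list(element = element, charge = charge, nH = nH, aromatic = aromatic)
}
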