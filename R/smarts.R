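# SMARTS-subset substructure patterns and matcher.
#
# Supported atom primitives: bare element symbols (C aliphatic, c aromatic),
# *, and bracket expressions with comma-separated alternatives, each a
# conjunction of: #<atomic number-ish symbol lookup not needed — #6/#7/#8/
# #14/#15/#16 map to C/N/O/Si/P/S>, element symbol, a/A, X<d> (total
# connections incl. H), D<d> (heavy-atom degree), H<d> (total H count),
# charge (+/-/+n/-n), and !<primitive> negation of any of the above.
# Bonds: - = # : ~ and the default "single or aromatic". Branches and ring
# closures as in SMILES. No recursive SMARTS, no wildcard ranges.

.smarts_atomicnum <- c("5" = "B", "6" = "C", "7" = "N", "8" = "O",
                       "9" = "F", "14" = "Si", "15" = "P", "16" = "S",
                       "17" = "Cl", "35" = "Br", "53" = "I")

#' Parse a SMARTS pattern (supported subset)
#'
#' @param smarts pattern text
#' @return an object of class `acidstab_smarts` (pattern graph)
#' @export
parse_smarts <- function(smarts) {
  chars <- strsplit(smarts, "", fixed = TRUE)[[1]]
  n <- length(chars)
  patoms <- list()   # each: list of alternative constraint lists
  pbonds <- list()   # c(a1, a2, bondtype) bondtype: 1,2,3,4=aromatic,5=any,6=single-or-aromatic
  prev_stack <- list(); prev <- NA_integer_
  pending <- NA_integer_
  ring_open <- list()
  i <- 1L
  fail <- function(msg) stop(sprintf("SMARTS '%s': %s", smarts, msg), call. = FALSE)

  add_patom <- function(alts) {
    patoms[[length(patoms) + 1L]] <<- alts
    idx <- length(patoms)
    if (!is.na(prev)) {
      bt <- if (is.na(pending)) 6L else pending
      pbonds[[length(pbonds) + 1L]] <<- c(prev, idx, bt)
    }
    pending <<- NA_integer_
    prev <<- idx
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") { prev_stack[[length(prev_stack) + 1L]] <- prev; i <- i + 1L }
    else if (ch == ")") {
      if (!length(prev_stack)) fail("unmatched ')'")
      prev <- prev_stack[[length(prev_stack)]]
      prev_stack[[length(prev_stack)]] <- NULL; i <- i + 1L
    }
    else if (ch == "-") { pending <- 1L; i <- i + 1L }
    else if (ch == "=") { pending <- 2L; i <- i + 1L }
    else if (ch == "#" && i < n && grepl("[0-9]", chars[i + 1L])) {
      # bare #n atom outside brackets
      j <- i + 1L
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      num <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      el <- .smarts_atomicnum[[num]]
      if (is.null(el)) fail(paste("unsupported atomic number", num))
      add_patom(list(list(element = el)))
      i <- j
    }
    else if (ch == "#") { pending <- 3L; i <- i + 1L }
    else if (ch == ":") { pending <- BOND_AROMATIC; i <- i + 1L }
    else if (ch == "~") { pending <- 5L; i <- i + 1L }
    else if (grepl("[0-9]", ch)) {
      if (is.na(prev)) fail("ring closure before atom")
      key <- ch
      if (!is.null(ring_open[[key]])) {
        op <- ring_open[[key]]
        bt <- if (!is.na(pending)) pending else if (!is.na(op$bt)) op$bt else 6L
        pbonds[[length(pbonds) + 1L]] <- c(op$atom, prev, bt)
        ring_open[[key]] <- NULL
      } else ring_open[[key]] <- list(atom = prev, bt = pending)
      pending <- NA_integer_; i <- i + 1L
    }
    else if (ch == "[") {
      close <- NA_integer_
      depth <- 0L
      for (j in (i + 1L):n) {
        if (chars[j] == "[") depth <- depth + 1L
        if (chars[j] == "]") { if (depth == 0L) { close <- j; break }; depth <- depth - 1L }
      }
      if (is.na(close)) fail("unmatched '['")
      body <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      add_patom(parse_smarts_atom(body, fail))
      i <- close + 1L
    }
    else if (ch == "*") { add_patom(list(list())); i <- i + 1L }
    else {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br", "Si")) {
        add_patom(list(list(element = two, aromatic = FALSE))); i <- i + 2L
      } else if (ch %in% .organic_subset) {
        add_patom(list(list(element = ch, aromatic = FALSE))); i <- i + 1L
      } else if (ch %in% .aromatic_ok) {
        add_patom(list(list(element = toupper(ch), aromatic = TRUE))); i <- i + 1L
      } else fail(sprintf("unexpected '%s' at %d", ch, i))
    }
  }
  if (length(prev_stack)) fail("unmatched '('")
  if (length(ring_open)) fail("unclosed ring bond")
  if (!length(patoms)) fail("no atoms")
  pb <- if (length(pbonds)) do.call(rbind, pbonds) else
    matrix(integer(0), ncol = 3)
  structure(list(atoms = patoms,
                 bonds = data.frame(a1 = pb[, 1], a2 = pb[, 2], type = pb[, 3]),
                 source = smarts),
            class = "acidstab_smarts")
}

# One bracket body, e.g. "CX3H1", "OX2H", "F,Cl,Br,I", "NX3;!$(..)" (no $).
parse_smarts_atom <- function(body, fail) {
  body <- gsub(";", "&", body, fixed = TRUE)
  alts <- strsplit(body, ",", fixed = TRUE)[[1]]
  lapply(alts, function(alt) {
    con <- list()
    s <- gsub("&", "", alt, fixed = TRUE)
    while (nchar(s)) {
      neg <- FALSE
      if (startsWith(s, "!")) { neg <- TRUE; s <- substring(s, 2) }
      grab <- function(rx) {
        m <- regmatches(s, regexpr(rx, s))
        if (length(m)) { s <<- substring(s, nchar(m) + 1L); m } else NULL
      }
      set <- function(key, val) {
        if (neg) con[[paste0("not_", key)]] <<- c(con[[paste0("not_", key)]], val)
        else con[[key]] <<- val
      }
      if (!is.null(m <- grab("^#[0-9]+"))) {
        el <- .smarts_atomicnum[[substring(m, 2)]]
        if (is.null(el)) fail(paste("unsupported atomic number", m))
        set("element", el)
      } else if (!is.null(m <- grab("^(Si|Cl|Br|[BCNOPSFI])"))) {
        set("element", m); if (!neg) con$aromatic <- FALSE
      } else if (!is.null(m <- grab("^[bcnops]"))) {
        set("element", toupper(m)); if (!neg) con$aromatic <- TRUE
      } else if (!is.null(m <- grab("^A"))) { set("aromatic", FALSE)
      } else if (!is.null(m <- grab("^a"))) { set("aromatic", TRUE)
      } else if (!is.null(m <- grab("^X[0-9]+"))) { set("X", as.integer(substring(m, 2)))
      } else if (!is.null(m <- grab("^D[0-9]+"))) { set("D", as.integer(substring(m, 2)))
      } else if (!is.null(m <- grab("^H[0-9]*"))) {
        set("H", if (nchar(m) == 1L) 1L else as.integer(substring(m, 2)))
      } else if (!is.null(m <- grab("^\\+[0-9]+|^-[0-9]+"))) { set("charge", as.integer(m))
      } else if (!is.null(m <- grab("^\\++|^-+"))) {
        set("charge", nchar(m) * if (startsWith(m, "+")) 1L else -1L)
      } else if (!is.null(m <- grab("^\\*"))) { # wildcard, no constraint
      } else fail(sprintf("unsupported primitive near '%s'", s))
    }
    con
  })
}

# Does molecule atom i satisfy one alternative's constraints?
patom_ok <- function(con, mol, i, deg, arom) {
  a <- mol$atoms[i, ]
  if (!is.null(con$element) && a$element != con$element) return(FALSE)
  if (!is.null(con$not_element) && a$element %in% con$not_element) return(FALSE)
  if (!is.null(con$aromatic) && isTRUE(con$aromatic) != (a$aromatic || arom[i])) return(FALSE)
  if (!is.null(con$X) && (deg[i] + a$nH) != con$X) return(FALSE)
  if (!is.null(con$D) && deg[i] != con$D) return(FALSE)
  if (!is.null(con$H) && a$nH != con$H) return(FALSE)
  if (!is.null(con$not_H) && a$nH %in% con$not_H) return(FALSE)
  if (!is.null(con$charge) && a$charge != con$charge) return(FALSE)
  TRUE
}

pbond_ok <- function(type, order) {
  switch(type,
         `1` = order == 1L,
         `2` = order == 2L,
         `3` = order == 3L,
         `4` = order == BOND_AROMATIC,
         `5` = TRUE,
         `6` = order == 1L || order == BOND_AROMATIC)
}

#' Find substructure matches of a SMARTS pattern in a molecule
#'
#' @param pattern an `acidstab_smarts` (or pattern text, parsed on the fly)
#' @param mol an `acidstab_mol`
#' @param unique_sets collapse matches that cover the same atom set
#'   (symmetry-distinct copies)? Default TRUE.
#' @return list of integer vectors of matched molecule atom indices (in
#'   pattern-atom order for `unique_sets = FALSE`; sorted sets otherwise)
#' @export
match_smarts <- function(pattern, mol, unique_sets = TRUE) {
  if (is.character(pattern)) pattern <- parse_smarts(pattern)
  np <- length(pattern$atoms)
  nm <- n_atoms(mol)
  if (np > nm) return(list())
  deg <- atom_degrees(mol)
  arom <- has_aromatic_bond(mol)

  # pattern adjacency
  padj <- vector("list", np)
  for (i in seq_len(np)) padj[[i]] <- list()
  pb <- pattern$bonds
  for (k in seq_len(nrow(pb))) {
    padj[[pb$a1[k]]] <- c(padj[[pb$a1[k]]], list(c(pb$a2[k], pb$type[k])))
    padj[[pb$a2[k]]] <- c(padj[[pb$a2[k]]], list(c(pb$a1[k], pb$type[k])))
  }
  madj <- adjacency_list(mol)
  b <- mol$bonds
  morder <- function(i, j) b$order[which(b$a1 == min(i, j) & b$a2 == max(i, j))[1]]

  atom_matches <- function(p, i)
    any(vapply(pattern$atoms[[p]], patom_ok, TRUE, mol = mol, i = i,
               deg = deg, arom = arom))

  # order pattern atoms so each (after the first) touches an earlier one
  ord <- integer(0); seen <- logical(np)
  queue <- 1L
  while (length(ord) < np) {
    if (!length(queue)) { queue <- which(!seen)[1] }   # disconnected pattern
    v <- queue[[1]]; queue <- queue[-1]
    if (seen[v]) next
    seen[v] <- TRUE; ord <- c(ord, v)
    nb <- vapply(padj[[v]], `[`, 0L, 1L)
    queue <- c(queue, nb[!seen[nb]])
  }

  results <- list()
  map <- integer(np)  # pattern -> mol atom
  used <- logical(nm)
  extend <- function(k) {
    if (k > np) { results[[length(results) + 1L]] <<- map; return(invisible()) }
    p <- ord[k]
    anchored <- Filter(function(e) map[e[1]] != 0L, padj[[p]])
    cands <- if (length(anchored)) {
      madj[[map[anchored[[1]][1]]]]
    } else seq_len(nm)
    for (i in cands) {
      if (used[i]) next
      if (!atom_matches(p, i)) next
      ok <- TRUE
      for (e in padj[[p]]) {
        q <- e[1]
        if (map[q] == 0L) next
        j <- map[q]
        if (!(j %in% madj[[i]])) { ok <- FALSE; break }
        if (!pbond_ok(e[2], morder(i, j))) { ok <- FALSE; break }
      }
      if (!ok) next
      map[p] <<- i; used[i] <<- TRUE
      extend(k + 1L)
      map[p] <<- 0L; used[i] <<- FALSE
    }
  }
  map[] <- 0L
  extend(1L)
  if (unique_sets) {
    sets <- lapply(results, function(m) sort(m))
    keys <- vapply(sets, paste, "", collapse = ",")
    sets[!duplicated(keys)]
  } else results
}
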