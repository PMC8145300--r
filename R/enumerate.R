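# Exhaustive generation of all molecules buildable from an atom palette
# within size and ring constraints.
#
# Structures are neutral closed-shell Kekule graphs: heavy atoms from the
# palette, bond orders from a declared set, hydrogens filled implicitly to
# each element's valence. Every emitted structure is connected, satisfies
# valence, contains no ring smaller than min_ring_size, and is emitted
# once (deduplicated by canonical SMILES). A brute-force oracle over all
# labelled multigraphs, with igraph-based isomorphism classing when
# available, provides an independent check for small specs.

#' Specification for exhaustive structure enumeration
#'
#' @param palette named integer vector of element valences, e.g.
#'   `c(C = 4, N = 3, O = 2, Si = 4)`
#' @param size_min,size_max heavy-atom count range (hydrogens do not count)
#' @param min_ring_size smallest ring allowed (default 5)
#' @param bond_orders allowed bond orders, subset of 1:3
#' @return an `enumeration_spec`
#' @export
enumeration_spec <- function(palette, size_min, size_max,
                             min_ring_size = 5L, bond_orders = 1:3) {
  stopifnot(length(palette) >= 1, !is.null(names(palette)),
            size_min >= 1, size_min <= size_max, min_ring_size >= 3,
            all(bond_orders %in% 1:3))
  structure(list(palette = palette, size_min = as.integer(size_min),
                 size_max = as.integer(size_max),
                 min_ring_size = as.integer(min_ring_size),
                 bond_orders = sort(as.integer(bond_orders))),
            class = "enumeration_spec")
}

# Build a molecule from an element vector and an order assignment over the
# pair list; returns NULL if hydrogen fill is impossible.
.mol_from_assignment <- function(elements, valences, pairs, orders) {
  keep <- orders > 0L
  b <- data.frame(a1 = pairs[keep, 1], a2 = pairs[keep, 2],
                  order = orders[keep])
  deg <- numeric(length(elements))
  for (i in seq_len(nrow(b))) {
    deg[b$a1[i]] <- deg[b$a1[i]] + b$order[i]
    deg[b$a2[i]] <- deg[b$a2[i]] + b$order[i]
  }
  nH <- valences - deg
  if (any(nH < 0)) return(NULL)
  new_molecule(
    data.frame(element = elements, charge = 0L, nH = as.integer(nH),
               aromatic = FALSE, stringsAsFactors = FALSE), b)
}

.pair_list <- function(n) {
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  do.call(rbind, lapply(seq_len(n - 1L), function(i)
    cbind(i, seq.int(i + 1L, n))))
}

# Non-decreasing element index tuples (multisets) of length n over k symbols.
.element_multisets <- function(k, n) {
  out <- list()
  rec <- function(prefix, lo) {
    if (length(prefix) == n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (e in lo:k) rec(c(prefix, e), e)
  }
  rec(integer(0), 1L)
  out
}

#' Enumerate all structures satisfying a spec
#'
#' Depth-first assignment of bond orders over every atom pair with valence
#' and connectivity pruning; each complete assignment that is connected,
#' ring-legal and valence-satisfied is canonicalized and emitted once.
#' Output order is deterministic.
#'
#' @param spec an [enumeration_spec()]
#' @param callback optional function called with each new canonical SMILES;
#'   when supplied, SMILES are not accumulated (constant memory)
#' @return character vector of canonical SMILES (invisibly when
#'   `callback` given)
#' @export
enumerate_structures <- function(spec, callback = NULL) {
  seen <- new.env(parent = emptyenv())
  acc <- if (is.null(callback)) new.env(parent = emptyenv()) else NULL
  count <- 0L
  out <- character(0)
  emit <- function(mol) {
    smi <- write_smiles(mol)
    if (!is.null(seen[[smi]])) return()
    seen[[smi]] <- TRUE
    if (is.null(callback)) out[[length(out) + 1L]] <<- smi
    else callback(smi)
  }
  orders <- c(0L, spec$bond_orders)
  k <- length(spec$palette)
  for (n in spec$size_min:spec$size_max) {
    pairs <- .pair_list(n)
    npairs <- nrow(pairs)
    if (n == 1L) {
      for (e in seq_len(k)) {
        mol <- .mol_from_assignment(names(spec$palette)[e],
                                    spec$palette[[e]],
                                    pairs, integer(0))
        if (!is.null(mol)) emit(mol)
      }
      next
    }
    # last pair index touching each atom: once passed, the atom is final
    last_pair_of <- vapply(seq_len(n), function(a)
      max(which(pairs[, 1] == a | pairs[, 2] == a)), 0L)
    for (tuple in .element_multisets(k, n)) {
      elements <- names(spec$palette)[tuple]
      valences <- unname(spec$palette[tuple])
      ordvec <- integer(npairs)
      used <- numeric(n)
      nedges <- 0L
      dfs <- function(p) {
        if (p > npairs) {
          mol <- .mol_from_assignment(elements, valences, pairs, ordvec)
          if (is.null(mol)) return()
          if (max(mol_components(mol)) != 1L) return()
          if (mol_girth(mol) < spec$min_ring_size) return()
          emit(mol)
          return()
        }
        a <- pairs[p, 1]; b <- pairs[p, 2]
        for (o in orders) {
          if (o > 0L && (used[a] + o > valences[a] || used[b] + o > valences[b])) next
          ordvec[p] <<- o
          used[a] <<- used[a] + o; used[b] <<- used[b] + o
          if (o > 0L) nedges <<- nedges + 1L
          prune <- FALSE
          # connectivity lower bound
          if (nedges + (npairs - p) < n - 1L) prune <- TRUE
          # an atom whose pairs are all assigned must have a bond
          if (!prune)
            for (at in c(a, b))
              if (last_pair_of[at] == p && used[at] == 0) { prune <- TRUE; break }
          if (!prune) dfs(p + 1L)
          used[a] <<- used[a] - o; used[b] <<- used[b] - o
          if (o > 0L) nedges <<- nedges - 1L
          ordvec[p] <<- 0L
        }
      }
      dfs(1L)
    }
  }
  if (is.null(callback)) out else invisible(out)
}

#' Count structures satisfying a spec
#' @param spec an [enumeration_spec()]
#' @return integer count of distinct canonical structures
#' @export
count_structures <- function(spec) {
  n <- 0L
  enumerate_structures(spec, callback = function(smi) n <<- n + 1L)
  n
}

# igraph-based isomorphism certificate: atoms colored by element index,
# bonds represented as extra vertices colored by 4 + order.
.igraph_certificate <- function(elements, pairs, orders, palette_names) {
  keep <- which(orders > 0L)
  na <- length(elements)
  nb <- length(keep)
  col <- c(match(elements, palette_names), 4L + orders[keep])
  edges <- integer(0)
  for (j in seq_along(keep)) {
    p <- keep[j]
    bv <- na + j
    edges <- c(edges, pairs[p, 1], bv, pairs[p, 2], bv)
  }
  g <- igraph::make_graph(edges, n = na + nb, directed = FALSE)
  cp <- igraph::canonical_permutation(g, colors = col)$labeling
  g2 <- igraph::permute(g, cp)
  col2 <- integer(length(col)); col2[cp] <- col
  m <- igraph::as_edgelist(g2)
  m <- m[order(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])), , drop = FALSE]
  paste(paste(col2, collapse = ","),
        paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]),
              sep = "-", collapse = ";"), sep = "|")
}

#' Brute-force enumeration oracle for small specs
#'
#' Independent code path: iterates over every labelled element tuple and
#' every bond-order assignment (no search-tree pruning), filters on
#' valence, connectivity and ring size, and classes survivors by graph
#' isomorphism (igraph canonical permutation with vertex colors when
#' igraph is installed, canonical SMILES otherwise). One representative
#' per class is canonicalized for comparison against
#' [enumerate_structures()].
#'
#' @param spec an [enumeration_spec()] with `size_max <= 5`
#' @return character vector of canonical SMILES, sorted
#' @export
oracle_enumerate <- function(spec) {
  if (spec$size_max > 5L)
    stop("oracle refuses size_max > 5 (combinatorial explosion)")
  have_igraph <- requireNamespace("igraph", quietly = TRUE)
  k <- length(spec$palette)
  orders <- c(0L, spec$bond_orders)
  classes <- new.env(parent = emptyenv())
  smiles <- new.env(parent = emptyenv())
  for (n in spec$size_min:spec$size_max) {
    pairs <- .pair_list(n)
    npairs <- nrow(pairs)
    n_assign <- length(orders)^npairs
    if (k^n * max(n_assign, 1) > 3e7) stop("oracle spec too large")
    # all labelled element tuples (full cartesian product — no symmetry use)
    tuples <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
    # all order assignments as an integer matrix
    om <- as.matrix(expand.grid(rep(list(orders), max(npairs, 0L))))
    if (npairs == 0L) om <- matrix(integer(0), nrow = 1, ncol = 0)
    # degree sums: pair-to-atom incidence
    D <- matrix(0, nrow(om), n)
    for (p in seq_len(npairs)) {
      D[, pairs[p, 1]] <- D[, pairs[p, 1]] + om[, p]
      D[, pairs[p, 2]] <- D[, pairs[p, 2]] + om[, p]
    }
    for (ti in seq_len(nrow(tuples))) {
      tuple <- tuples[ti, ]
      val <- unname(spec$palette[tuple])
      ok <- rep(TRUE, nrow(om))
      for (a in seq_len(n)) ok <- ok & D[, a] <= val[a]
      if (n > 1L) for (a in seq_len(n)) ok <- ok & D[, a] > 0
      for (ri in which(ok)) {
        mol <- .mol_from_assignment(names(spec$palette)[tuple], val,
                                    pairs, as.integer(om[ri, ]))
        if (is.null(mol)) next
        if (max(mol_components(mol)) != 1L) next
        if (mol_girth(mol) < spec$min_ring_size) next
        key <- if (have_igraph)
          .igraph_certificate(names(spec$palette)[tuple], pairs,
                              as.integer(om[ri, ]), names(spec$palette))
        else write_smiles(mol)
        if (is.null(classes[[key]])) {
          classes[[key]] <- TRUE
          smiles[[write_smiles(mol)]] <- TRUE
        }
      }
    }
  }
  sort(ls(smiles))
}
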