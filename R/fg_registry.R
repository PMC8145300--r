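# Registry of reactive functional groups and their assignment to molecules.
#
# A group pairs a SMARTS pattern with a precedence rank and a reaction
# class (solvolysis or sulfonation). Compound groups (1,2-diol) outrank
# their constituents (alcohol); assignment is greedy in descending
# priority, and an atom consumed by a higher-priority group is unavailable
# to lower-priority ones. The copy count N of a group is the number of
# symmetry-distinct atom sets it retains, the N entering the multi-copy
# half-life correction.

#' Define one functional group
#'
#' @param group_id unique identifier
#' @param name human-readable name
#' @param smarts substructure pattern (supported SMARTS subset)
#' @param priority integer rank; higher ranks are assigned first
#' @param reaction_class `"solvolysis"` or `"sulfonation"`
#' @return a `functional_group` list
#' @export
functional_group <- function(group_id, name, smarts, priority,
                             reaction_class = c("solvolysis", "sulfonation")) {
  reaction_class <- match.arg(reaction_class)
  pat <- parse_smarts(smarts)  # errors early on invalid pattern
  structure(list(group_id = group_id, name = name, smarts = smarts,
                 pattern = pat, priority = as.integer(priority),
                 reaction_class = reaction_class),
            class = "functional_group")
}

#' Build a functional-group registry
#'
#' @param definitions list of [functional_group()] objects
#' @return a `fg_registry`, queryable by id with `[[`
#' @export
register_groups <- function(definitions) {
  ids <- vapply(definitions, `[[`, "", "group_id")
  if (anyDuplicated(ids))
    stop("duplicate group_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (d in definitions)
    if (!inherits(d, "functional_group"))
      stop("definitions must be functional_group objects")
  structure(stats::setNames(definitions, ids), class = "fg_registry")
}

#' @export
print.fg_registry <- function(x, ...) {
  cat(sprintf("<fg_registry: %d groups>\n", length(x)))
  for (g in x)
    cat(sprintf("  %-22s prio %3d  %-11s %s\n", g$group_id, g$priority,
                g$reaction_class, g$smarts))
  invisible(x)
}

#' The package's default functional-group registry
#'
#' About twenty illustrative reactive motifs covering the common
#' solvolysis chemistry of concentrated sulfuric acid plus an aromatic
#' sulfonation target. This is a documented stand-in: the full measured
#' 130-group kinetics compilation is external to this package and can be
#' loaded from a user-supplied table with [read_group_table()].
#'
#' Priorities place compound groups (1,2-diol) above their constituents
#' (alcohol) and acyl groups above the plain heteroatom motifs they
#' contain.
#'
#' @return an `fg_registry`
#' @export
default_registry <- function() {
  d <- list(
    functional_group("diol_12",      "1,2-diol",          "[OX2H][CX4][CX4][OX2H]", 90),
    functional_group("carboxylic",   "carboxylic acid",   "[CX3](=O)[OX2H]",        85),
    functional_group("ester",        "carboxylic ester",  "[CX3](=O)[OX2][#6]",     84),
    functional_group("amide",        "amide",             "[CX3](=O)[NX3]",         83),
    functional_group("anhydride",    "acid anhydride",    "[CX3](=O)[OX2][CX3]=O",  86),
    functional_group("aldehyde",     "aldehyde",          "[CX3H1]=O",              80),
    functional_group("ketone",       "ketone",            "[#6][CX3](=O)[#6]",      79),
    functional_group("phosphate_e",  "phosphate ester",   "[PX4](=O)([OX2])[OX2]",  78),
    functional_group("tms_ether",    "silyl ether",       "[Si][OX2][#6]",          77),
    functional_group("nitrile",      "nitrile",           "[CX2]#[NX1]",            70),
    functional_group("alcohol",      "alcohol",           "[OX2H][CX4]",            60),
    functional_group("thiol",        "thiol",             "[SX2H]",                 59),
    functional_group("amine",        "amine",             "[NX3]",                  58),
    functional_group("ether",        "dialkyl ether",     "[CX4][OX2][CX4]",        50),
    functional_group("thioether",    "thioether",         "[CX4][SX2][CX4]",        49),
    functional_group("alkyne",       "alkyne",            "C#C",                    41),
    functional_group("alkene",       "alkene",            "C=C",                    40),
    functional_group("alkyl_halide", "alkyl halide",      "[CX4][F,Cl,Br,I]",       39),
    functional_group("aromatic_ch",  "aromatic C-H (sulfonation)", "[cH]",          10,
                     reaction_class = "sulfonation")
  )
  register_groups(d)
}

#' Match registry groups against a molecule
#'
#' Runs every pattern, then resolves overlaps with [resolve_overlaps()].
#' Matching operates on the record's parsed graph, so counts are invariant
#' under input atom renumbering.
#'
#' @param record an ok `molecule_record` (or an `acidstab_mol`)
#' @param registry an `fg_registry`
#' @return a `match_result`: list with `molecule_id`, `assignments`
#'   (data.frame group_id, N, reaction_class plus a list-column of atom
#'   sets), `status` = `"matched"` or `"no_reactive_groups"`
#' @export
match_groups <- function(record, registry) {
  if (inherits(record, "molecule_record")) {
    if (record$parse_status != "ok") stop("record not parsed ok")
    mol <- record$mol; id <- record$id
  } else { mol <- record; id <- NA_character_ }

  raw <- list()
  for (g in registry) {
    sets <- match_smarts(g$pattern, mol)
    for (s in sets)
      raw[[length(raw) + 1L]] <- list(group_id = g$group_id,
                                      priority = g$priority,
                                      reaction_class = g$reaction_class,
                                      atoms = s)
  }
  assignments <- resolve_overlaps(raw)
  status <- if (nrow(assignments)) "matched" else "no_reactive_groups"
  structure(list(molecule_id = id, assignments = assignments, status = status),
            class = "match_result")
}

#' Resolve overlapping raw matches by priority
#'
#' Greedy assignment in descending priority: an atom consumed by a
#' higher-priority group is unavailable to lower-priority groups; matches
#' of equal priority are kept when atom-disjoint, in discovery order.
#'
#' @param raw list of raw matches (`group_id`, `priority`,
#'   `reaction_class`, `atoms`)
#' @return data.frame with one row per group: `group_id`, `N`,
#'   `reaction_class`, and list-column `atom_sets`
#' @export
resolve_overlaps <- function(raw) {
  empty <- data.frame(group_id = character(0), N = integer(0),
                      reaction_class = character(0))
  empty$atom_sets <- list()
  if (!length(raw)) return(empty)
  prio <- vapply(raw, `[[`, 0L, "priority")
  raw <- raw[order(-prio, seq_along(raw))]
  consumed <- integer(0)
  kept <- list()
  for (m in raw) {
    if (any(m$atoms %in% consumed)) next
    kept[[length(kept) + 1L]] <- m
    consumed <- c(consumed, m$atoms)
  }
  ids <- vapply(kept, `[[`, "", "group_id")
  ug <- unique(ids)
  out <- data.frame(group_id = ug,
                    N = vapply(ug, function(g) sum(ids == g), 0L),
                    reaction_class = vapply(ug, function(g)
                      kept[[which(ids == g)[1]]]$reaction_class, ""),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$atom_sets <- lapply(ug, function(g) lapply(kept[ids == g], `[[`, "atoms"))
  out
}

#' @export
print.match_result <- function(x, ...) {
  if (x$status == "no_reactive_groups") {
    cat(sprintf("<match %s: no reactive groups>\n", x$molecule_id))
  } else {
    cat(sprintf("<match %s: %s>\n", x$molecule_id,
                paste(sprintf("%s(N=%d)", x$assignments$group_id,
                              x$assignments$N), collapse = ", ")))
  }
  invisible(x)
}

#' Read group definitions from CSV
#'
#' Columns: `group_id,name,smarts,priority,reaction_class`.
#' @param path CSV file
#' @return an `fg_registry`
#' @export
read_group_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group_id", "name", "smarts", "priority", "reaction_class")
  if (!all(need %in% names(df)))
    stop("group table must have columns ", paste(need, collapse = ","))
  register_groups(lapply(seq_len(nrow(df)), function(i)
    functional_group(df$group_id[i], df$name[i], df$smarts[i],
                     df$priority[i], df$reaction_class[i])))
}

#' Write group definitions to CSV
#' @param registry an `fg_registry`
#' @param path output CSV
#' @export
write_group_table <- function(registry, path) {
  df <- data.frame(
    group_id = vapply(registry, `[[`, "", "group_id"),
    name = vapply(registry, `[[`, "", "name"),
    smarts = vapply(registry, `[[`, "", "smarts"),
    priority = vapply(registry, `[[`, 0L, "priority"),
    reaction_class = vapply(registry, `[[`, "", "reaction_class"),
    row.names = NULL, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
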