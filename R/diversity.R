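# Chemical-diversity statistics over stable subsets: bond-type diversity
# and element-wise stability fractions.

#' Set of bond types in a molecule
#'
#' A bond type is an unordered element pair plus a bond order, including
#' bonds to implicit hydrogens. Aromatic bonds are their own type
#' (`C:C`), so the count does not depend on the Kekule structure chosen
#' for an aromatic input; set `kekule_aromatic = TRUE` to type aromatic
#' bonds as alternating single/double instead.
#'
#' @param mol an `acidstab_mol` (or ok `molecule_record`)
#' @param kekule_aromatic type aromatic bonds as the pair {single, double}
#' @return character vector of bond-type labels, e.g. `c("C-C", "C-H")`
#' @export
bond_type_set <- function(mol, kekule_aromatic = FALSE) {
  if (inherits(mol, "molecule_record")) mol <- mol$mol
  types <- character(0)
  b <- mol$bonds
  sym <- c(`1` = "-", `2` = "=", `3` = "#", `4` = ":")
  for (i in seq_len(nrow(b))) {
    e1 <- mol$atoms$element[b$a1[i]]; e2 <- mol$atoms$element[b$a2[i]]
    pair <- sort(c(e1, e2))
    if (b$order[i] == BOND_AROMATIC && kekule_aromatic) {
      types <- c(types, paste0(pair[1], "-", pair[2]),
                 paste0(pair[1], "=", pair[2]))
    } else {
      types <- c(types, paste0(pair[1], sym[[as.character(b$order[i])]], pair[2]))
    }
  }
  hs <- mol$atoms$nH > 0
  if (any(hs))
    types <- c(types, vapply(unique(mol$atoms$element[hs]), function(e) {
      pair <- sort(c("H", e))
      paste0(pair[1], "-", pair[2])
    }, ""))
  sort(unique(types))
}

#' Number of bonds between non-hydrogen atoms
#'
#' Cyclohexane and benzene each have 6 countable bonds; methane has 0.
#'
#' @param mol an `acidstab_mol` (or ok `molecule_record`)
#' @return integer bond count
#' @export
countable_bonds <- function(mol) {
  if (inherits(mol, "molecule_record")) mol <- mol$mol
  nrow(mol$bonds)
}

#' Mean bond-type diversity of the stable subset, per altitude
#'
#' At each altitude, the mean of `|bond_type_set|` over molecules whose
#' half-life is at least the threshold; altitudes where no molecule
#' qualifies are reported as NA.
#'
#' @param records list of ok `molecule_record`s, ids matching `results`
#' @param results data.frame from [profile_stability()]
#' @param threshold_s stability threshold in seconds
#' @return data.frame `altitude_km`, `n_stable`, `mean_bond_types`
#' @export
mean_bond_diversity <- function(records, results, threshold_s) {
  ids <- vapply(records, function(r) as.character(r$id), "")
  nbt <- vapply(records, function(r) length(bond_type_set(r)), 0L)
  names(nbt) <- ids
  alts <- sort(unique(results$altitude_km))
  out <- lapply(alts, function(z) {
    sub <- results[results$altitude_km == z & results$status == "ok" &
                     results$half_life_s >= threshold_s, ]
    data.frame(altitude_km = z, n_stable = nrow(sub),
               mean_bond_types = if (nrow(sub))
                 mean(nbt[sub$molecule_id]) else NA_real_)
  })
  do.call(rbind, out)
}

#' Element-wise stability fractions, weighted across datasets
#'
#' For each dataset, the fraction of element-containing molecules (with a
#' prediction) that are stable at the threshold; datasets are combined as
#' a weighted mean with weights equal to dataset sizes (counts of parsed
#' molecules), which equals the pooled fraction.
#'
#' @param datasets named list; each entry a list of ok `molecule_record`s
#' @param results_list named list of [profile_stability()] data.frames,
#'   same names as `datasets`
#' @param threshold_s stability threshold in seconds
#' @param weights dataset weights for the combined fraction; default is
#'   dataset size (count of parsed molecules)
#' @return data.frame `element`, `altitude_km`, `fraction_stable`
#'   (weighted mean over datasets containing the element),
#'   `n_with_element` (pooled count); elements absent everywhere are absent
#' @export
element_stability_fractions <- function(datasets, results_list, threshold_s,
                                        weights = NULL) {
  stopifnot(identical(names(datasets), names(results_list)))
  if (is.null(weights)) weights <- vapply(datasets, length, 0L)
  rows <- list()
  for (ds in names(datasets)) {
    recs <- datasets[[ds]]
    res <- results_list[[ds]]
    els <- lapply(recs, function(r) mol_elements(r$mol))
    ids <- vapply(recs, function(r) as.character(r$id), "")
    all_el <- sort(unique(unlist(els)))
    for (z in sort(unique(res$altitude_km))) {
      sub <- res[res$altitude_km == z & res$status == "ok", ]
      stable_ids <- sub$molecule_id[sub$half_life_s >= threshold_s]
      for (e in all_el) {
        has <- ids[vapply(els, function(x) e %in% x, TRUE)]
        has <- has[has %in% sub$molecule_id]   # only molecules with predictions
        if (!length(has)) next
        rows[[length(rows) + 1L]] <- data.frame(
          dataset = ds, element = e, altitude_km = z,
          n = length(has), n_stable = sum(has %in% stable_ids),
          w = weights[[ds]], stringsAsFactors = FALSE)
      }
    }
  }
  per <- do.call(rbind, rows)
  if (is.null(per)) return(data.frame(element = character(0),
                                      altitude_km = numeric(0),
                                      fraction_stable = numeric(0),
                                      n_with_element = integer(0)))
  per$frac <- per$n_stable / per$n
  keys <- unique(per[, c("element", "altitude_km")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- per[per$element == keys$element[i] &
                 per$altitude_km == keys$altitude_km[i], ]
    data.frame(element = keys$element[i], altitude_km = keys$altitude_km[i],
               fraction_stable = sum(sub$w * sub$frac) / sum(sub$w),
               n_with_element = sum(sub$n), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$element, out$altitude_km), ]
}
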