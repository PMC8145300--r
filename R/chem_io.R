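# Dataset I/O: parse, validate, canonicalize, load and save molecule sets.

#' Parsing policy for molecule input
#'
#' @param component how to reduce multi-component (dot-separated) input:
#'   `"largest"` keeps the largest covalent component by heavy-atom count
#'   (tie broken by first occurrence); `"keep"` keeps all components;
#'   `"reject"` rejects multi-component input.
#' @param validate_valence reject molecules with disallowed valences?
#' @return a `parse_policy` list
#' @export
parse_policy <- function(component = c("largest", "keep", "reject"),
                         validate_valence = TRUE) {
  structure(list(component = match.arg(component),
                 validate_valence = validate_valence),
            class = "parse_policy")
}

#' Parse one SMILES string into a molecule record
#'
#' Invalid input never raises an error: the returned record carries
#' `parse_status = "rejected"` and a reason. Multi-component input (salts,
#' mixtures) is reduced according to the policy.
#'
#' @param smiles SMILES text
#' @param id identifier carried on the record
#' @param policy a [parse_policy()]
#' @return a `molecule_record` list with fields `id`, `source_smiles`,
#'   `mol` (an `acidstab_mol` or NULL), `canonical`, `parse_status`,
#'   `reason`
#' @export
parse_molecule <- function(smiles, id = NA_character_, policy = parse_policy()) {
  rec <- list(id = id, source_smiles = smiles, mol = NULL,
              canonical = NA_character_, parse_status = "rejected",
              reason = NA_character_)
  class(rec) <- "molecule_record"
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    rec$reason <- "empty input"
    return(rec)
  }
  smiles <- trimws(smiles)
  mol <- tryCatch(read_smiles_graph(smiles), error = function(e) conditionMessage(e))
  if (is.character(mol)) { rec$reason <- mol; return(rec) }

  comp <- mol_components(mol)
  if (max(comp) > 1L) {
    if (policy$component == "reject") {
      rec$reason <- "multi-component input"
      return(rec)
    }
    if (policy$component == "largest") {
      sizes <- tabulate(comp)
      mol <- subset_molecule(mol, which(comp == which.max(sizes)))
    }
  }
  if (policy$validate_valence) {
    bad <- valence_violations(mol)
    if (length(bad)) { rec$reason <- bad[1]; return(rec) }
  }
  rec$mol <- mol
  rec$canonical <- write_smiles(mol)
  rec$parse_status <- "ok"
  rec$reason <- NA_character_
  rec
}

#' @export
print.molecule_record <- function(x, ...) {
  if (x$parse_status == "ok")
    cat(sprintf("<record %s: %s>\n", x$id, x$canonical))
  else
    cat(sprintf("<record %s: REJECTED (%s)>\n", x$id, x$reason))
  invisible(x)
}

#' Canonical SMILES of a parsed record
#'
#' Equal structures map to equal text regardless of input atom ordering.
#'
#' @param record a `molecule_record` with `parse_status == "ok"`
#' @return character scalar
#' @export
canonical_form <- function(record) {
  if (!inherits(record, "molecule_record"))
    stop("expected a molecule_record")
  if (record$parse_status != "ok")
    stop("cannot canonicalize a rejected record: ", record$reason)
  record$canonical
}

#' Load a molecule dataset from disk
#'
#' Every input line is accounted for as either a parsed record or a logged
#' rejection. Lines starting with `#` and blank lines are skipped (and not
#' counted).
#'
#' @param path file path
#' @param format `"smiles"`: one SMILES per line with an optional
#'   tab/comma-separated id column; `"csv"`: CSV with header columns
#'   `id,smiles`
#' @param policy a [parse_policy()]
#' @param dedup drop records whose canonical form was already seen?
#' @return list with `records` (molecule_record list), `rejections`
#'   (data.frame line,id,reason), `n_input`
#' @export
load_dataset <- function(path, format = c("smiles", "csv"),
                         policy = parse_policy(), dedup = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("id", "smiles") %in% names(df)))
      stop("csv must have header columns id,smiles")
    ids <- as.character(df$id); smi <- df$smiles
    lines <- seq_len(nrow(df)) + 1L
  } else {
    raw <- readLines(path, warn = FALSE)
    keep <- !grepl("^\\s*(#|$)", raw)
    lines <- which(keep)
    raw <- raw[keep]
    parts <- strsplit(raw, "[\t,]")
    smi <- vapply(parts, `[`, "", 1L)
    ids <- vapply(parts, function(p) if (length(p) > 1L) p[2] else NA_character_, "")
    ids[is.na(ids)] <- paste0("mol", seq_along(ids))[is.na(ids)]
  }
  parse_one <- function(k) parse_molecule(smi[k], id = ids[k], policy = policy)
  records <- lapply(seq_along(smi), parse_one)
  ok <- vapply(records, function(r) r$parse_status == "ok", TRUE)
  rej <- data.frame(line = lines[!ok], id = ids[!ok],
                    reason = vapply(records[!ok], `[[`, "", "reason"),
                    stringsAsFactors = FALSE)
  records <- records[ok]
  if (dedup) records <- dedup_records(records)
  list(records = records, rejections = rej, n_input = length(smi))
}

#' Deduplicate records by canonical form
#'
#' Keeps the first record of each canonical form; idempotent.
#' @param records list of ok molecule_records
#' @return filtered list
#' @export
dedup_records <- function(records) {
  keys <- vapply(records, `[[`, "", "canonical")
  records[!duplicated(keys)]
}

#' Write a dataset to disk
#'
#' @param records list of ok molecule_records
#' @param path output file
#' @param format `"smiles"` (canonical SMILES + tab + id) or `"csv"`
#' @export
save_dataset <- function(records, path, format = c("smiles", "csv")) {
  format <- match.arg(format)
  cano <- vapply(records, `[[`, "", "canonical")
  ids <- vapply(records, function(r) as.character(r$id), "")
  if (format == "csv") {
    utils::write.csv(data.frame(id = ids, smiles = cano), path, row.names = FALSE)
  } else {
    writeLines(paste(cano, ids, sep = "\t"), path)
  }
  invisible(path)
}
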