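# Stability-constant records: ingestion, validation, exclusion filters and
# condition-priority duplicate resolution.

# required columns of the record schema, in canonical order
.record_cols <- c("cation", "charge", "smiles", "ligand_charge", "n", "beta",
                  "temp_c", "ionic_strength", "source")

.excluded_cations <- c("Am", "Cm", "Cf", "Bk", "Es", "Fm", "Md")
.excluded_ligand_elements <- c("Te", "Se", "As", "Mn", "Co", "Fe", "W", "Mo",
                               "Cr", "Re")

#' Canonicalize SMILES strings
#'
#' Converts SMILES to the OpenBabel canonical form so that notation variants
#' of the same ligand compare equal.  Unparsable strings yield `NA`.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, `NA` where parsing failed.
#' @examples
#' canonical_smiles(c("NCCN", "C(N)CN"))
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(character())
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  if (!any(ok)) return(out)
  # openbabel writes one tab-terminated canonical SMILES per input line;
  # invalid molecules come back as empty lines
  raw <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "CAN", paste(smiles[ok], collapse = "\n"))
  )
  lines <- strsplit(raw, "\n", fixed = TRUE)[[1]]
  length(lines) <- sum(ok)  # pad with NA if openbabel dropped trailing lines
  vals <- sub("\t.*$", "", lines)
  vals[is.na(vals) | !nzchar(vals)] <- NA_character_
  out[ok] <- vals
  out
}

# element symbols appearing as bracket atoms in a SMILES string, e.g.
# "[Se]", "[se]", "[Fe+2]" -> "Se", "Se", "Fe"
.bracket_elements <- function(smiles) {
  brackets <- regmatches(smiles, gregexpr("\\[[^]]*\\]", smiles))[[1]]
  if (length(brackets) == 0) return(character())
  stripped <- sub("^\\[[0-9]*", "", brackets)  # drop "[", isotope digits
  syms <- regmatches(stripped, regexpr("[A-Za-z][a-z]?", stripped))
  syms <- syms[!syms %in% c("H")]
  # aromatic lowercase forms map back to the element symbol
  paste0(toupper(substr(syms, 1, 1)), substring(syms, 2))
}

#' Parse and validate stability-constant records
#'
#' Takes a data frame (one row per measurement) with columns `cation`,
#' `charge`, `smiles`, `ligand_charge`, `n`, `beta`, `temp_c`,
#' `ionic_strength`, `source` and returns a validated tibble of records with
#' SMILES canonicalized.  `beta` is the overall stability constant on the
#' log10 scale; `n` is the coordination count of the M-L_n complex.
#'
#' Schema problems (a missing column) abort immediately naming the column;
#' row-level problems (unparsable SMILES, `n < 1`, negative ionic strength,
#' non-positive cation charge, non-finite `beta`) are collected across the
#' whole table and reported together with their row indices.
#'
#' @param data A data frame with the record schema above.
#' @return A tibble of validated records, row order preserved, `smiles`
#'   replaced by its canonical form.
#' @seealso [read_records()] to read the same schema from delimited text.
#' @examples
#' parse_records(data.frame(
#'   cation = "Cu", charge = 2, smiles = "NCCN", ligand_charge = 0,
#'   n = 1, beta = 10.5, temp_c = 25, ionic_strength = 0.1, source = "demo"
#' ))
#' @export
parse_records <- function(data) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(.record_cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("record table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "stabcast_schema_error")
  }
  rec <- as_tibble(data)[.record_cols]
  rec$cation <- as.character(rec$cation)
  rec$smiles <- as.character(rec$smiles)
  rec$source <- as.character(rec$source)
  num_cols <- c("charge", "ligand_charge", "n", "beta", "temp_c", "ionic_strength")
  rec[num_cols] <- lapply(rec[num_cols], as.numeric)
  if (nrow(rec) == 0) return(rec)

  can <- canonical_smiles(rec$smiles)
  problems <- character()
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0) {
      paste0("row ", head(idx, 10), ": ", what)
    } else character()
  }
  bad_smi <- head(which(is.na(can)), 10)
  problems <- c(
    problems,
    if (length(bad_smi) > 0) {
      paste0("row ", bad_smi, ": unparsable SMILES '", rec$smiles[bad_smi], "'")
    },
    bad(!is.finite(rec$n) | rec$n < 1 | rec$n != round(rec$n),
        "coordination count n must be an integer >= 1"),
    bad(!is.finite(rec$beta), "beta must be finite"),
    bad(!is.finite(rec$ionic_strength) | rec$ionic_strength < 0,
        "ionic_strength must be >= 0"),
    bad(!is.finite(rec$charge) | rec$charge < 1, "cation charge must be >= +1")
  )
  if (length(problems) > 0) {
    abort(c("invalid stability-constant record(s):", problems),
          class = "stabcast_record_error")
  }
  rec$smiles <- can
  rec$n <- as.integer(rec$n)
  rec
}

#' Read / write stability-constant records as delimited text
#'
#' CSV with a header row in the package's record schema (see
#' [parse_records()], which `read_records()` applies after reading).
#'
#' @param path File path.
#' @param records A tibble of records.
#' @return `read_records()` a validated tibble of records;
#'   `write_records()` the input, invisibly.
#' @export
read_records <- function(path) {
  parse_records(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' @rdname read_records
#' @export
write_records <- function(records, path) {
  readr::write_csv(records[.record_cols], path)
  invisible(records)
}

#' Apply the element-based exclusion rules
#'
#' Drops records whose cation is one of the unsupported heavy actinides
#' (Am, Cm, Cf, Bk, Es, Fm, Md) or whose ligand contains any of the elements
#' Te, Se, As, Mn, Co, Fe, W, Mo, Cr, Re, for which reliable molecular
#' descriptors cannot be generated.  The operation is a partition: every
#' input row ends up in exactly one of `kept` or `dropped`.
#'
#' @param records A tibble of validated records.
#' @return A list with tibbles `kept` and `dropped`; `dropped` carries a
#'   machine-readable `reason` column.
#' @examples
#' recs <- parse_records(data.frame(
#'   cation = c("Cu", "Am"), charge = 2, smiles = "NCCN", ligand_charge = 0,
#'   n = 1, beta = 8, temp_c = 25, ionic_strength = 0.1, source = "demo"
#' ))
#' apply_exclusions(recs)$dropped
#' @export
apply_exclusions <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) {
    return(list(kept = as_tibble(records),
                dropped = dplyr::mutate(as_tibble(records), reason = character())))
  }
  reason <- rep(NA_character_, nrow(records))
  reason[records$cation %in% .excluded_cations] <- "excluded cation"
  lig_elem <- purrr::map(records$smiles, .bracket_elements)
  for (i in which(is.na(reason))) {
    hit <- intersect(lig_elem[[i]], .excluded_ligand_elements)
    if (length(hit) > 0) {
      reason[i] <- paste0("excluded ligand element ", hit[1])
    }
  }
  keep <- is.na(reason)
  list(
    kept = as_tibble(records[keep, , drop = FALSE]),
    dropped = dplyr::mutate(as_tibble(records[!keep, , drop = FALSE]),
                            reason = reason[!keep])
  )
}

# priority tier of each record: 1 = 25 degC and I = 0.1, 2 = 25 degC any I,
# 3 = any T and I = 0.1, 4 = everything else.  Tolerances absorb rounding in
# reported conditions.
.condition_tier <- function(temp_c, ionic_strength,
                            temp_tol = 0.5, i_tol = 0.005) {
  at_t <- abs(temp_c - 25) <= temp_tol
  at_i <- abs(ionic_strength - 0.1) <= i_tol
  dplyr::case_when(at_t & at_i ~ 1L, at_t ~ 2L, at_i ~ 3L, TRUE ~ 4L)
}

#' Resolve duplicate measurements by condition priority
#'
#' For each (cation, charge, ligand, n) key exactly one record survives.
#' Records are ranked by condition tier - (1) 25 degC and ionic strength
#' 0.1 mol/L, (2) 25 degC at any ionic strength, (3) any temperature at
#' 0.1 mol/L, (4) all others - and within the winning tier the record with
#' the largest `beta` is kept (first-seen on an exact tie).  Tier membership
#' uses |T - 25| <= 0.5 degC and |I - 0.1| <= 0.005 mol/L to absorb rounding
#' of reported conditions.  SMILES are assumed canonical (as produced by
#' [parse_records()]) so notation variants deduplicate together.
#'
#' The operation is idempotent and neither invents nor loses keys.
#'
#' @param records A tibble of validated records.
#' @return A tibble with one record per key, in order of first appearance.
#' @export
resolve_duplicates <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) return(as_tibble(records))
  rec <- dplyr::mutate(
    as_tibble(records),
    .order = dplyr::row_number(),
    .tier = .condition_tier(.data$temp_c, .data$ionic_strength)
  )
  out <- rec |>
    dplyr::group_by(.data$cation, .data$charge, .data$smiles, .data$n) |>
    dplyr::arrange(.data$.tier, dplyr::desc(.data$beta), .data$.order,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.order)
  dplyr::select(out, -".order", -".tier")
}
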