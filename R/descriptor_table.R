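# DescriptorTable: numeric feature block + row identifiers + per-column
# provenance + optional standardization metadata.

new_descriptor_table <- function(features, info, provenance,
                                 center = NULL, scale = NULL) {
  stopifnot(is.data.frame(features), is.data.frame(info),
            nrow(features) == nrow(info),
            all(names(features) %in% names(provenance)))
  structure(
    list(features = as_tibble(features), info = as_tibble(info),
         provenance = provenance[names(features)],
         center = center, scale = scale),
    class = "descriptor_table"
  )
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat("<descriptor_table> ", nrow(x$features), " rows x ",
      ncol(x$features), " features\n", sep = "")
  tab <- table(x$provenance)
  cat("  provenance:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  standardized:", !is.null(x$center), "\n")
  invisible(x)
}

#' @export
as_tibble.descriptor_table <- function(x, ...) {
  dplyr::bind_cols(x$info, x$features)
}

#' @export
dim.descriptor_table <- function(x) dim(x$features)

#' Extract the numeric feature matrix of a descriptor table
#'
#' @param x A `descriptor_table`.
#' @return A numeric matrix (rows = records, columns = features).
#' @export
feature_matrix <- function(x) {
  stopifnot(inherits(x, "descriptor_table"))
  as.matrix(x$features)
}

#' Assemble the beta_1 descriptor table
#'
#' Concatenates, per record, the 12 element-level cation features, the
#' (pruned) ligand descriptor columns including the molecular charge, and
#' the two experimental conditions (temperature in degC, ionic strength in
#' mol/L).  Cation columns are prefixed `cat_` to keep the provenance of
#' every column unambiguous.
#'
#' @param records A tibble of validated records (canonical SMILES).
#' @param cation_tbl Cation feature table, default [cation_features()].
#' @param ligand_tbl Ligand descriptor table keyed by `smiles` (canonical),
#'   e.g. the output of [ligand_descriptors()] after pruning.
#' @return A `descriptor_table` whose rows parallel `records`; the `info`
#'   block carries the record keys and `beta`.
#' @export
assemble_beta1_descriptor <- function(records,
                                      cation_tbl = cation_features(),
                                      ligand_tbl) {
  stopifnot(is.data.frame(records), is.data.frame(ligand_tbl),
            "smiles" %in% names(ligand_tbl))
  cat_feats <- cation_tbl[c("symbol", .cation_feature_names)]
  names(cat_feats) <- c("symbol", paste0("cat_", .cation_feature_names))
  cat_feats$.cat_key <- paste0(cat_feats$symbol, "+", cat_feats$cat_charge)

  rec_key <- paste0(records$cation, "+", records$charge)
  unknown <- setdiff(unique(rec_key), cat_feats$.cat_key)
  if (length(unknown) > 0) {
    abort(paste0("no cation features for: ", paste(unknown, collapse = ", ")))
  }
  idx_c <- match(rec_key, cat_feats$.cat_key)
  cat_block <- cat_feats[idx_c, paste0("cat_", .cation_feature_names)]

  idx_l <- match(records$smiles, ligand_tbl$smiles)
  if (anyNA(idx_l)) {
    abort(paste0("no ligand descriptors for: ",
                 paste(unique(records$smiles[is.na(idx_l)]), collapse = ", ")))
  }
  lig_cols <- setdiff(.numeric_cols(ligand_tbl), character())
  lig_block <- ligand_tbl[idx_l, lig_cols]

  cond_block <- tibble(temp_c = records$temp_c,
                       ionic_strength = records$ionic_strength)

  features <- dplyr::bind_cols(cat_block, lig_block, cond_block)
  provenance <- c(
    setNames(rep("cation", ncol(cat_block)), names(cat_block)),
    setNames(rep("ligand", ncol(lig_block)), names(lig_block)),
    setNames(rep("condition", 2), names(cond_block))
  )
  info_cols <- intersect(c("cation", "charge", "smiles", "ligand_charge",
                           "n", "beta"), names(records))
  new_descriptor_table(features, records[info_cols], provenance)
}

#' Standardize a descriptor table
#'
#' Z-scores every feature column using the mean and population standard
#' deviation computed over `fit_rows` only, and stores the statistics so that
#' held-out rows can be transformed with the fit-set metadata
#' ([apply_standardization()]) and the transform inverted
#' ([unstandardize_descriptors()]).
#'
#' @param x A `descriptor_table` (not yet standardized).
#' @param fit_rows Integer row indices defining the fit set; defaults to all
#'   rows.
#' @return The standardized `descriptor_table` with `center` and `scale`
#'   metadata set.
#' @export
standardize_descriptors <- function(x, fit_rows = seq_len(nrow(x$features))) {
  stopifnot(inherits(x, "descriptor_table"), length(fit_rows) > 0)
  if (!is.null(x$center)) abort("descriptor table is already standardized")
  m <- as.matrix(x$features)
  fit <- m[fit_rows, , drop = FALSE]
  center <- colMeans(fit)
  # population standard deviation, so a two-point column {a, b} maps to
  # exactly {-1, +1}
  scale <- sqrt(colMeans(sweep(fit, 2, center)^2))
  if (any(scale <= 0 | !is.finite(scale))) {
    abort(paste0("zero-variance column(s) over the fit rows: ",
                 paste(names(scale)[scale <= 0 | !is.finite(scale)], collapse = ", "),
                 " (run drop_degenerate() first)"))
  }
  z <- sweep(sweep(m, 2, center), 2, scale, "/")
  out <- x
  out$features <- as_tibble(as.data.frame(z))
  out$center <- center
  out$scale <- scale
  out
}

#' @rdname standardize_descriptors
#' @param reference A standardized `descriptor_table` whose metadata is
#'   applied to `x` (the transform uses the reference's fit statistics, not
#'   statistics of `x` itself).
#' @export
apply_standardization <- function(x, reference) {
  stopifnot(inherits(x, "descriptor_table"), inherits(reference, "descriptor_table"))
  if (is.null(reference$center)) abort("reference table is not standardized")
  miss <- setdiff(names(reference$features), names(x$features))
  if (length(miss) > 0) {
    abort(paste0("columns missing from new table: ", paste(miss, collapse = ", ")))
  }
  m <- as.matrix(x$features[names(reference$features)])
  z <- sweep(sweep(m, 2, reference$center), 2, reference$scale, "/")
  out <- x
  out$features <- as_tibble(as.data.frame(z))
  out$provenance <- reference$provenance
  out$center <- reference$center
  out$scale <- reference$scale
  out
}

#' @rdname standardize_descriptors
#' @export
unstandardize_descriptors <- function(x) {
  stopifnot(inherits(x, "descriptor_table"))
  if (is.null(x$center)) abort("descriptor table is not standardized")
  m <- as.matrix(x$features)
  raw <- sweep(sweep(m, 2, x$scale, "*"), 2, x$center, "+")
  out <- x
  out$features <- as_tibble(as.data.frame(raw))
  out$center <- NULL
  out$scale <- NULL
  out
}

#' Read / write descriptor tables as delimited text
#'
#' The table body (identifier columns then feature columns) is written as
#' CSV; standardization metadata and per-column provenance go to a JSON
#' sidecar at `paste0(path, ".meta.json")`.
#'
#' @param x A `descriptor_table`.
#' @param path CSV file path.
#' @return `write_descriptors()` returns `x` invisibly; `read_descriptors()`
#'   the reconstructed `descriptor_table`.
#' @export
write_descriptors <- function(x, path) {
  stopifnot(inherits(x, "descriptor_table"))
  readr::write_csv(as_tibble(x), path)
  meta <- list(
    schema = "stabcast/descriptor_table/v1",
    info_cols = names(x$info),
    feature_cols = names(x$features),
    provenance = as.list(x$provenance),
    center = if (!is.null(x$center)) as.list(x$center),
    scale = if (!is.null(x$scale)) as.list(x$scale)
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(x)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(path) {
  body <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  feats <- body[unlist(meta$feature_cols)]
  info <- body[unlist(meta$info_cols)]
  new_descriptor_table(
    feats, info,
    provenance = unlist(meta$provenance),
    center = if (!is.null(meta$center)) unlist(meta$center),
    scale = if (!is.null(meta$scale)) unlist(meta$scale)
  )
}
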