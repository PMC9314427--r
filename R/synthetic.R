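# Synthetic stability-constant datasets with planted structure.
#
# Generative model: for each (M, L) pair the first stepwise constant is
#   log K_1 = f(active cation features, active ligand features) + noise,
# with f sparse and dominated by electronegativity- and charge-like
# columns; subsequent stepwise constants shrink geometrically,
#   log K_i = rho^(i-1) log K_1,  rho in (0, 1) per pair,
# so beta_n = sum_{i<=n} log K_i.  With log K_1 > 0 and rho strictly inside
# (0, 1) the universal inequality beta_(n-1) < beta_n < n beta_1 holds for
# every generated record by construction.

#' Specification of a synthetic dataset
#'
#' Defaults emulate the scale and structure of large curated
#' stability-constant compilations: 57 cation species, 2706 ligands, about
#' 13,600 (M, L) pairs with measured beta_1 and a long-tailed distribution
#' of maximum coordination counts up to 6, measurement noise of 0.3 log10
#' units on log K_1, conditions concentrated at 25 degC / 0.1 mol/L with a
#' minority off-condition and a small injected duplicate rate.
#'
#' @param n_cations Number of cation species (drawn from
#'   [cation_features()]; at most its row count).
#' @param n_ligands Number of distinct ligands sampled from the template
#'   grammar.
#' @param n_pairs Number of distinct (cation, ligand) pairs.
#' @param max_n Maximum coordination count.
#' @param order_probs Probabilities of a pair's maximum order 1..max_n.
#' @param effect_weights Named weights of the planted sparse effect; see
#'   Details.
#' @param nonlinear Add a mild electronegativity x donor-count interaction.
#' @param noise_sd Gaussian noise on log K_1, in log10-beta units (>= 0).
#' @param rho_range Range of the stepwise ratio rho, strictly inside (0, 1).
#' @param off_condition_rate Fraction of records at conditions other than
#'   25 degC / 0.1 mol/L.
#' @param duplicate_rate Probability of injecting an off-condition
#'   duplicate for a record (exercises [resolve_duplicates()]).
#' @param seed Integer seed; generation is fully deterministic given it.
#'
#' @details The planted effect is
#'   `log K_1 = 1.5 + w_en (EN_M - 1.5) + w_q (q_M - 2) + w_lig q_L +
#'    w_N nN + w_O nO [+ w_int (EN_M - 1.5)(nN + nO)]`, clipped below at
#'   0.1 so the geometric beta_n construction stays valid, where EN_M and
#'   q_M are the cation's Pauling electronegativity and charge, q_L the
#'   ligand's molecular charge, and nN / nO its nitrogen / oxygen donor
#'   counts.
#' @return A `synthetic_spec` object (validated named list).
#' @export
synthetic_spec <- function(n_cations = 57, n_ligands = 2706,
                           n_pairs = 13559, max_n = 6,
                           order_probs = c(0.70, 0.13, 0.09, 0.06, 0.015, 0.005),
                           effect_weights = c(en = 3.0, cat_charge = 1.2,
                                              lig_charge = -1.5,
                                              nN = 0.8, nO = 0.5,
                                              interaction = 0.4),
                           nonlinear = TRUE, noise_sd = 0.3,
                           rho_range = c(0.45, 0.85),
                           off_condition_rate = 0.15,
                           duplicate_rate = 0.05, seed = 1) {
  stopifnot(
    n_cations >= 1, n_ligands >= 1, n_pairs >= 1,
    max_n >= 1, length(order_probs) >= max_n,
    noise_sd >= 0,
    length(rho_range) == 2, rho_range[1] > 0, rho_range[2] < 1,
    rho_range[1] <= rho_range[2],
    off_condition_rate >= 0, off_condition_rate <= 1,
    duplicate_rate >= 0, duplicate_rate <= 1,
    all(c("en", "cat_charge", "lig_charge", "nN", "nO", "interaction") %in%
          names(effect_weights))
  )
  structure(
    list(n_cations = n_cations, n_ligands = n_ligands, n_pairs = n_pairs,
         max_n = max_n,
         order_probs = order_probs[seq_len(max_n)] / sum(order_probs[seq_len(max_n)]),
         effect_weights = effect_weights, nonlinear = nonlinear,
         noise_sd = noise_sd, rho_range = rho_range,
         off_condition_rate = off_condition_rate,
         duplicate_rate = duplicate_rate, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Template grammar for ligand SMILES: functionalized alkyl backbones
# (amine / hydroxyl / carboxyl / thiol end groups, optional mid-chain
# substituent) plus a set of chelator and (hetero)aromatic templates.
# Only H, C, N, O, S appear, so no ligand hits the exclusion list.
.ligand_pool <- local({
  pool <- NULL
  function() {
    if (!is.null(pool)) return(pool)
    ends1 <- c(amine = "N", hydroxyl = "O", carboxyl = "OC(=O)",
               thiol = "S", none = "")
    ends2 <- c(amine = "N", hydroxyl = "O", carboxyl = "C(=O)O",
               thiol = "S", none = "")
    branches <- c("C", "N", "O", "CC(=O)O", "CN")
    grid <- list()
    for (a in 2:9) {
      for (e1 in seq_along(ends1)) {
        for (e2 in seq_along(ends2)) {
          if (names(ends1)[e1] == "none" && names(ends2)[e2] == "none") next
          base <- paste0(ends1[e1], strrep("C", a), ends2[e2])
          grid[[length(grid) + 1]] <- base
          for (b in branches) {
            for (p in seq_len(a - 1)) {
              chain <- paste0(strrep("C", p), "C(", b, ")",
                              strrep("C", a - p - 1))
              grid[[length(grid) + 1]] <- paste0(ends1[e1], chain, ends2[e2])
            }
          }
        }
      }
    }
    specials <- c(
      # polyamines
      "NCCN", "NCCCN", "NCCNCCN", "NCCCNCCCN", "NCCNCCNCCN",
      # aminopolycarboxylates
      "OC(=O)CNCC(=O)O", "OC(=O)CN(CC(=O)O)CC(=O)O",
      "OC(=O)CN(CC(=O)O)CCN(CC(=O)O)CC(=O)O",
      "OC(=O)CN(CC(=O)O)CCCN(CC(=O)O)CC(=O)O",
      # hydroxy acids
      "OC(=O)C(O)C(O)C(=O)O", "OC(=O)CC(O)(CC(=O)O)C(=O)O", "OC(=O)C(O)C",
      # polyols
      "OCC(O)CO", "OCC(O)C(O)CO", "OCC(O)C(O)C(O)CO",
      # aromatics and heteroaromatics
      "c1ccncc1", "Cc1ccncc1", "Cc1cccnc1", "NCc1ccccn1", "Nc1ccccn1",
      "c1ccc(-c2ccccn2)nc1", "Oc1ccccc1", "Oc1ccccc1O", "Oc1ccc(O)cc1",
      "OC(=O)c1ccccc1", "OC(=O)c1ccccc1O", "Nc1ccccc1", "Nc1ccccc1N",
      "OC(=O)c1ccccn1", "Oc1cccc2cccnc12", "OC(=O)c1cc(O)ccc1",
      # thio ligands
      "OC(=O)CS", "NCCS", "SCCS"
    )
    smis <- unique(c(unlist(grid), specials))
    # aqueous charge rule: each carboxyl fully deprotonated (-1), all other
    # groups neutral; counted on the template strings, where acids are
    # written literally as head "OC(=O)" or tail "C(=O)O" groups
    charge <- -(stringr::str_count(smis, stringr::fixed("C(=O)O")) +
                  stringr::str_count(smis, stringr::fixed("OC(=O)")))
    can <- canonical_smiles(smis)
    keep <- !is.na(can) & !duplicated(can)
    pool <<- tibble(smiles = can[keep], charge = as.numeric(charge[keep]))
    pool
  }
})

# nitrogen / oxygen donor counts straight from the canonical SMILES string
.donor_counts <- function(smiles) {
  tibble(
    nN = stringr::str_count(smiles, "[Nn]"),
    nO = stringr::str_count(smiles, "[Oo]")
  )
}

#' Generate the entities of a synthetic dataset
#'
#' Draws `n_cations` cation species (with their 12-feature rows) from the
#' bundled [cation_features()] table and `n_ligands` ligand SMILES from a
#' template grammar of amines, (amino)carboxylates, polyols, thiols,
#' chelators and (hetero)aromatics, with aqueous molecular charges assigned
#' by a fixed rule (each carboxyl group deprotonated: -1; other groups
#' neutral).  Fully deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `cations` (feature tibble) and `ligands` (tibble
#'   with `smiles`, `charge`, `nN`, `nO`).
#' @export
generate_entities <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  cat_tbl <- cation_features()
  if (spec$n_cations > nrow(cat_tbl)) {
    abort(paste0("n_cations exceeds the ", nrow(cat_tbl),
                 " available cation species"))
  }
  pool <- .ligand_pool()
  if (spec$n_ligands > nrow(pool)) {
    abort(paste0("n_ligands exceeds the template-grammar pool (",
                 nrow(pool), " distinct ligands)"))
  }
  .with_seed(spec$seed, {
    cations <- cat_tbl[sort(sample(nrow(cat_tbl), spec$n_cations)), ]
    lig_idx <- sort(sample(nrow(pool), spec$n_ligands))
    ligands <- dplyr::bind_cols(pool[lig_idx, ],
                                .donor_counts(pool$smiles[lig_idx]))
    list(cations = cations, ligands = ligands)
  })
}

#' Generate synthetic stability-constant records
#'
#' Samples `n_pairs` distinct (cation, ligand) pairs, plants the sparse
#' effect on log K_1 (see [synthetic_spec()]), draws a per-pair stepwise
#' ratio rho and emits one record per order n = 1..(pair's maximum order)
#' with `beta_n = log K_1 (1 - rho^n) / (1 - rho)`.  Conditions concentrate
#' at 25 degC / 0.1 mol/L; a configurable fraction is off-condition and a
#' configurable rate of off-condition duplicates is injected, perturbed
#' downward by less than the family's minimum inequality gap so that the
#' universal inequality holds even before duplicate resolution.
#'
#' @param entities Output of [generate_entities()].
#' @param spec The same [synthetic_spec()].
#' @return A record tibble in the package schema, with the per-pair ground
#'   truth (`log_k1`, `rho`) attached as attribute `"truth"`.
#' @export
generate_beta <- function(entities, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  cats <- entities$cations
  ligs <- entities$ligands
  w <- spec$effect_weights
  .with_seed(spec$seed + 997L, {
    n_cells <- nrow(cats) * nrow(ligs)
    n_pairs <- min(spec$n_pairs, n_cells)
    cells <- sample(n_cells, n_pairs)
    ci <- ((cells - 1) %% nrow(cats)) + 1
    li <- ((cells - 1) %/% nrow(cats)) + 1

    en <- cats$electronegativity[ci]
    qm <- cats$charge[ci]
    ql <- ligs$charge[li]
    nn <- ligs$nN[li]
    no <- ligs$nO[li]
    log_k1 <- 1.5 + w["en"] * (en - 1.5) + w["cat_charge"] * (qm - 2) +
      w["lig_charge"] * ql + w["nN"] * nn + w["nO"] * no
    if (isTRUE(spec$nonlinear)) {
      log_k1 <- log_k1 + w["interaction"] * (en - 1.5) * (nn + no)
    }
    log_k1 <- log_k1 + rnorm(n_pairs, 0, spec$noise_sd)
    log_k1 <- pmax(log_k1, 0.1)
    rho <- runif(n_pairs, spec$rho_range[1], spec$rho_range[2])
    max_order <- sample(seq_len(spec$max_n), n_pairs, replace = TRUE,
                        prob = spec$order_probs)

    rec <- tibble(
      pair = rep(seq_len(n_pairs), max_order),
      n = unlist(lapply(max_order, seq_len))
    )
    rec$beta <- log_k1[rec$pair] *
      (1 - rho[rec$pair]^rec$n) / (1 - rho[rec$pair])
    off <- runif(nrow(rec)) < spec$off_condition_rate
    mode <- sample(3, nrow(rec), replace = TRUE)  # T off, I off, or both
    off_t <- off & mode != 2
    off_i <- off & mode != 1
    rec$temp_c <- ifelse(off_t,
                         sample(c(15, 20, 30, 37), nrow(rec), replace = TRUE),
                         25)
    rec$ionic_strength <- ifelse(off_i,
                                 sample(c(0.5, 1, 3), nrow(rec), replace = TRUE),
                                 0.1)

    records <- tibble(
      cation = cats$symbol[ci][rec$pair],
      charge = as.numeric(qm[rec$pair]),
      smiles = ligs$smiles[li][rec$pair],
      ligand_charge = as.numeric(ql[rec$pair]),
      n = as.integer(rec$n),
      beta = rec$beta,
      temp_c = as.numeric(rec$temp_c),
      ionic_strength = as.numeric(rec$ionic_strength),
      source = "synthetic"
    )

    # inject off-condition duplicates perturbed by less than the family's
    # minimum inequality gap
    dup_sel <- which(runif(nrow(records)) < spec$duplicate_rate)
    if (length(dup_sel) > 0) {
      p <- rec$pair[dup_sel]
      gap_lower <- records$beta[dup_sel] -
        ifelse(rec$n[dup_sel] == 1, 0,
               log_k1[p] * (1 - rho[p]^(rec$n[dup_sel] - 1)) / (1 - rho[p]))
      gap_upper <- rec$n[dup_sel] * log_k1[p] - records$beta[dup_sel]
      # lowering a beta_1 duplicate shrinks the upper bound n beta_1 of the
      # family's higher orders; the binding constraint is at n = 2
      is1 <- rec$n[dup_sel] == 1
      gap_upper[is1] <- ifelse(max_order[p[is1]] >= 2,
                               log_k1[p[is1]] * (1 - rho[p[is1]]) / 2,
                               Inf)
      u <- runif(length(dup_sel)) * 0.2 * pmin(gap_lower, gap_upper)
      dups <- records[dup_sel, ]
      dups$beta <- dups$beta - u
      dups$temp_c <- sample(c(18, 20, 30, 37), length(dup_sel), replace = TRUE)
      dups$ionic_strength <- sample(c(0.25, 0.5, 1), length(dup_sel),
                                    replace = TRUE)
      dups$source <- "synthetic-duplicate"
      records <- dplyr::bind_rows(records, dups)
    }
    attr(records, "truth") <- tibble(
      pair = seq_len(n_pairs),
      cation = cats$symbol[ci], charge = qm, smiles = ligs$smiles[li],
      log_k1 = log_k1, rho = rho, max_order = max_order
    )
    records
  })
}

#' @rdname generate_beta
#' @param spec A [synthetic_spec()].
#' @return `generate_dataset()`: the record tibble (entities are generated
#'   internally).
#' @export
generate_dataset <- function(spec) {
  generate_beta(generate_entities(spec), spec)
}
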