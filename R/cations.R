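# Element-level cation features.
#
# Eight properties per cation species are shipped as a plain-text reference
# table (approximate standard literature values: element melting point, molar
# heat capacity of the element, Shannon 6-coordinate ionic radius for the
# given charge, atomic polarizability, electron affinity, Pauling
# electronegativity, plus charge and atomic number).  The four unfilled
# s/p/d/f electron counts are derived in code from an aufbau filling of the
# ion, so the full table always carries exactly 12 features.

# Madelung filling order with subshell capacities.
.subshells <- local({
  n <- rep(1:7, each = 4)
  l <- rep(0:3, times = 7)
  keep <- l < n & !(n == 1 & l > 0)
  n <- n[keep]; l <- l[keep]
  ord <- order(n + l, n)
  data.frame(
    n = n[ord], l = l[ord],
    label = paste0(n[ord], c("s", "p", "d", "f")[l[ord] + 1]),
    cap = (2 * (0:3) + 1)[l[ord] + 1] * 2
  )
})

# Neutral ground-state configurations that deviate from plain Madelung
# filling, expressed as electron moves "from subshell -> to subshell".
.aufbau_exceptions <- list(
  `24` = c("4s", "3d"), `29` = c("4s", "3d"),               # Cr, Cu
  `41` = c("5s", "4d"), `42` = c("5s", "4d"),               # Nb, Mo
  `44` = c("5s", "4d"), `45` = c("5s", "4d"),               # Ru, Rh
  `46` = c("5s", "4d", "5s", "4d"),                         # Pd
  `47` = c("5s", "4d"),                                     # Ag
  `78` = c("6s", "5d"), `79` = c("6s", "5d"),               # Pt, Au
  `57` = c("4f", "5d"), `58` = c("4f", "5d"),               # La, Ce
  `64` = c("4f", "5d"),                                     # Gd
  `89` = c("5f", "6d"),                                     # Ac
  `90` = c("5f", "6d", "5f", "6d"),                         # Th
  `91` = c("5f", "6d"), `92` = c("5f", "6d"), `93` = c("5f", "6d")
)

# Occupancy vector (named by subshell label) for an ion with atomic number z
# and positive charge q: fill the neutral atom (Madelung + exceptions), then
# ionize by removing electrons from the highest principal quantum number
# first, higher angular momentum first within a shell (4s before 3d etc.).
.ion_configuration <- function(z, q) {
  stopifnot(z >= 1, q >= 0, q < z)
  occ <- setNames(numeric(nrow(.subshells)), .subshells$label)
  left <- z
  for (i in seq_len(nrow(.subshells))) {
    take <- min(left, .subshells$cap[i])
    occ[i] <- take
    left <- left - take
    if (left == 0) break
  }
  exc <- .aufbau_exceptions[[as.character(z)]]
  if (!is.null(exc)) {
    for (k in seq(1, length(exc), by = 2)) {
      if (occ[exc[k]] > 0) {
        occ[exc[k]] <- occ[exc[k]] - 1
        occ[exc[k + 1]] <- occ[exc[k + 1]] + 1
      }
    }
  }
  # ionization order: decreasing n, then decreasing l
  idx <- order(-.subshells$n, -.subshells$l)
  left <- q
  for (i in idx) {
    if (left == 0) break
    take <- min(left, occ[i])
    occ[i] <- occ[i] - take
    left <- left - take
  }
  occ
}

# Unfilled-electron counts per angular momentum: vacancies of the highest
# occupied subshell of that l, or the full subshell capacity if no subshell
# of that l holds electrons.
.unfilled_spdf <- function(occ) {
  caps <- c(s = 2, p = 6, d = 10, f = 14)
  out <- numeric(4)
  for (l in 0:3) {
    sel <- .subshells$l == l & occ[.subshells$label] > 0
    if (any(sel)) {
      top <- utils::tail(which(sel), 1)
      out[l + 1] <- caps[l + 1] - occ[.subshells$label[top]]
    } else {
      out[l + 1] <- caps[l + 1]
    }
  }
  setNames(out, c("unfilled_s", "unfilled_p", "unfilled_d", "unfilled_f"))
}

#' Element-level feature table for metal cations
#'
#' Returns the bundled reference table of 12 element-level features for the
#' cation species supported by the package: charge, atomic number, melting
#' point of the element (K), molar specific heat capacity of the element
#' (J/mol K), Shannon ionic radius for the given charge at 6-coordination
#' (pm), atomic polarizability (cubic Angstrom), electron affinity (eV),
#' Pauling electronegativity, and the numbers of unfilled electrons in the
#' s, p, d and f orbitals of the ion.  Property values are standard
#' literature reference values (rounded); the unfilled-orbital counts are
#' computed from an aufbau configuration of the ion (electrons removed from
#' the highest shell first, with the usual d/f filling exceptions).
#'
#' @return A tibble with one row per cation species (`symbol`, `charge`) and
#'   the 12 numeric feature columns.
#' @examples
#' cation_features()
#' @export
cation_features <- function() {
  path <- system.file("extdata", "cation_features.csv", package = "stabcast")
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  spdf <- purrr::map2(tbl$atomic_number, tbl$charge,
                      ~ .unfilled_spdf(.ion_configuration(.x, .y)))
  dplyr::bind_cols(tbl, dplyr::bind_rows(spdf))
}

# names of the 12 cation feature columns, in table order
.cation_feature_names <- c(
  "charge", "atomic_number", "melting_point_k", "heat_capacity_j_mol_k",
  "ionic_radius_pm", "polarizability_a3", "electron_affinity_ev",
  "electronegativity", "unfilled_s", "unfilled_p", "unfilled_d", "unfilled_f"
)
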