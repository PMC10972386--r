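#' @name mass
#' @title Monoisotopic mass arithmetic
#' @description Elemental-formula parsing and exact-mass computation for
#'   precursor and fragment ions. Masses are principal-isotope atomic masses;
#'   charged formulas written with a trailing `+`/`-` are corrected for the
#'   electron mass so that e.g. `"C5H15NO4P+"` is the phosphocholine head-group
#'   cation at 184.0733 Da.
NULL

# principal-isotope atomic masses (Da)
ATOMIC_MASS <- c(
  C = 12.0, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
  P = 30.97376151, S = 31.97207069, Na = 22.98976928, K = 38.9637064864
)
ELECTRON_MASS <- 0.000548579909
PROTON_MASS <- 1.00727646688

# "C42H82NO8P" -> named integer vector of element counts
parse_formula <- function(formula) {
  formula <- gsub("\\s", "", formula)
  if (formula == "") return(setNames(integer(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)
  pieces <- regmatches(formula, m)[[1]]
  m <- m[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    abort(paste0("malformed formula: ", formula))
  }
  el <- sub("[0-9]*$", "", pieces)
  cnt <- as.integer(ifelse(grepl("[0-9]+$", pieces),
                           sub("^[A-Za-z]+", "", pieces), "1"))
  unknown <- setdiff(el, names(ATOMIC_MASS))
  if (length(unknown) > 0) {
    abort(paste0("unknown element symbol(s): ", paste(unknown, collapse = ", ")))
  }
  tapply(cnt, factor(el, levels = unique(el)), sum)
}

counts_to_formula <- function(counts) {
  counts <- counts[counts != 0]
  ord <- intersect(c("C", "H", "N", "O", "P", "S", "Na", "K"), names(counts))
  paste0(ord, ifelse(counts[ord] == 1, "", counts[ord]), collapse = "")
}

# add/subtract formulas, e.g. formula_add("C3H8O3", "C16H32O2", subtract = "H2O")
formula_add <- function(..., subtract = NULL) {
  all_el <- names(ATOMIC_MASS)
  acc <- setNames(rep(0L, length(all_el)), all_el)
  for (f in list(...)) {
    cc <- parse_formula(f)
    acc[names(cc)] <- acc[names(cc)] + cc
  }
  for (f in subtract) {
    cc <- parse_formula(f)
    acc[names(cc)] <- acc[names(cc)] - cc
  }
  if (any(acc < 0)) abort("formula subtraction yields negative element count")
  counts_to_formula(acc)
}

#' Monoisotopic mass of an elemental formula
#'
#' @param formula Elemental formula string over C, H, N, O, P, S, Na, K.
#'   A trailing `+` or `-` marks a charged species and applies the electron
#'   correction (minus one electron for `+`, plus one for `-`).
#' @return Monoisotopic mass in Da (m/z for singly charged formulas).
#' @examples
#' formula_mass("C16H32O2")     # palmitic acid, 256.2402
#' formula_mass("C5H15NO4P+")   # phosphocholine head-group cation, 184.0733
#' @export
formula_mass <- function(formula) {
  stopifnot(is.character(formula))
  vapply(formula, function(f) {
    charge <- 0L
    if (grepl("\\+$", f)) { charge <- 1L; f <- sub("\\+$", "", f) }
    if (grepl("-$", f)) { charge <- -1L; f <- sub("-$", "", f) }
    counts <- parse_formula(f)
    sum(ATOMIC_MASS[names(counts)] * counts) - charge * ELECTRON_MASS
  }, numeric(1), USE.NAMES = FALSE)
}

#' Default adduct table
#'
#' Offsets are charge-carrier masses (electron-corrected); `n` is the number
#' of neutral molecules per ion and `charge` the signed charge. The defaults
#' cover the common ESI species for a formate/ammonium-formate mobile phase:
#' `[M+H]+`, `[M+NH4]+`, `[M+Na]+` in positive mode and `[M-H]-`,
#' `[M+HCOO]-` in negative mode.
#'
#' @return A tibble with columns `label`, `ion_mode`, `n`, `offset`, `charge`.
#' @export
default_adduct_table <- function() {
  tibble(
    label = c("[M+H]+", "[M+NH4]+", "[M+Na]+", "[M-H]-", "[M+HCOO]-"),
    ion_mode = c("positive", "positive", "positive", "negative", "negative"),
    n = 1L,
    offset = c(
      PROTON_MASS,
      formula_mass("NH4+"),
      ATOMIC_MASS[["Na"]] - ELECTRON_MASS,
      -PROTON_MASS,
      formula_mass("CHO2-")
    ),
    charge = c(1L, 1L, 1L, -1L, -1L)
  )
}

#' Theoretical m/z of an adduct of a neutral mass
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param adduct Adduct label present in `adduct_table`.
#' @param adduct_table An adduct table; see [default_adduct_table()].
#' @return m/z computed as `(mass * n + offset) / |charge|`.
#' @examples
#' adduct_mz(formula_mass("C16H32O2"), "[M-H]-")   # 255.2330
#' @export
adduct_mz <- function(mass, adduct, adduct_table = default_adduct_table()) {
  row <- adduct_table[adduct_table$label == adduct, ]
  if (nrow(row) != 1) abort(paste0("unknown adduct: ", adduct))
  (mass * row$n + row$offset) / abs(row$charge)
}

# inverse of adduct_mz
neutral_mass <- function(mz, adduct, adduct_table = default_adduct_table()) {
  row <- adduct_table[adduct_table$label == adduct, ]
  if (nrow(row) != 1) abort(paste0("unknown adduct: ", adduct))
  (mz * abs(row$charge) - row$offset) / row$n
}

# signed ppm error of an observed vs theoretical m/z
ppm_error <- function(observed, theoretical) {
  1e6 * (observed - theoretical) / theoretical
}
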