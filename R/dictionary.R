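#' @name dictionary
#' @title Lipid dictionary construction
#' @description The annotation dictionary is a table of lipid species with
#'   shorthand name, subclass, class, elemental formula, allowed adducts and
#'   diagnostic MS2 fragments. Formulas for diacyl/triacyl species are built
#'   from the glycerol/sphingoid backbone plus fatty-acyl chains, so every
#'   entry's monoisotopic mass is internally consistent with its name.
NULL

# subclass -> lipid class grouping used for reporting
SUBCLASS_CLASS <- c(
  Car = "fatty acid", FFA = "fatty acid",
  DG = "glycerolipid", PA = "glycerolipid", PG = "glycerolipid",
  TG = "glycerolipid",
  CL = "phospholipid", LPC = "phospholipid", LPE = "phospholipid",
  PC = "phospholipid", PE = "phospholipid", PI = "phospholipid",
  PS = "phospholipid",
  Cer = "sphingolipid", HexCer = "sphingolipid", SGL = "sphingolipid",
  SM = "sphingolipid", `sphingoid base` = "sphingolipid"
)

#' Subclass-to-class taxonomy
#' @return A tibble with columns `subclass` and `lipid_class` covering the 18
#'   supported subclasses.
#' @export
lipid_taxonomy <- function() {
  tibble(subclass = names(SUBCLASS_CLASS),
         lipid_class = unname(SUBCLASS_CLASS))
}

# combined elemental formula of k acyl chains totalling C:D (O2 per chain;
# one H2O per ester bond is subtracted where the chains are attached)
acyl_formula <- function(c, db, k = 1) {
  sprintf("C%dH%dO%d", c, 2 * c - 2 * db, 2 * k)
}

#' Elemental formula of a lipid species from its shorthand composition
#'
#' Builds the neutral formula for the supported subclasses from total acyl
#' carbons and double bonds. Ether (`O-`) chains replace one ester oxygen with
#' an ether linkage (net -O +H2 vs the diacyl species); plasmalogens (`P-`)
#' additionally carry the vinyl-ether double bond (net -O).
#'
#' @param subclass One of the 18 supported subclasses (see [lipid_taxonomy()]).
#' @param carbons,double_bonds Total acyl-chain carbons and double bonds.
#' @param ether,plasmalogen Ether / vinyl-ether linkage flags (one chain).
#' @return Elemental formula string.
#' @examples
#' lipid_formula("PC", 34, 1)   # "C42H82NO8P"
#' @export
lipid_formula <- function(subclass, carbons, double_bonds,
                          ether = FALSE, plasmalogen = FALSE) {
  c <- carbons; d <- double_bonds
  f <- switch(subclass,
    FFA = acyl_formula(c, d, 1),
    # acylcarnitine: carnitine + FA - H2O
    Car = formula_add("C7H15NO3", acyl_formula(c, d, 1), subtract = "H2O"),
    DG = formula_add("C3H8O3", acyl_formula(c, d, 2),
                     subtract = c("H2O", "H2O")),
    TG = formula_add("C3H8O3", acyl_formula(c, d, 3),
                     subtract = c("H2O", "H2O", "H2O")),
    PA = formula_add("C3H8O3", "H3PO4", acyl_formula(c, d, 2),
                     subtract = c("H2O", "H2O", "H2O")),
    PG = formula_add("C3H8O3", "C3H8O3", "H3PO4", acyl_formula(c, d, 2),
                     subtract = c("H2O", "H2O", "H2O", "H2O")),
    PC = formula_add("C3H8O3", "H3PO4", "C5H13NO", acyl_formula(c, d, 2),
                     subtract = c("H2O", "H2O", "H2O", "H2O")),
    PE = formula_add("C3H8O3", "H3PO4", "C2H7NO", acyl_formula(c, d, 2),
                     subtract = c("H2O", "H2O", "H2O", "H2O")),
    PS = formula_add("C3H8O3", "H3PO4", "C3H7NO3", acyl_formula(c, d, 2),
                     subtract = c("H2O", "H2O", "H2O", "H2O")),
    PI = formula_add("C3H8O3", "H3PO4", "C6H12O6", acyl_formula(c, d, 2),
                     subtract = c("H2O", "H2O", "H2O", "H2O")),
    LPC = formula_add("C3H8O3", "H3PO4", "C5H13NO", acyl_formula(c, d, 1),
                      subtract = c("H2O", "H2O", "H2O")),
    LPE = formula_add("C3H8O3", "H3PO4", "C2H7NO", acyl_formula(c, d, 1),
                      subtract = c("H2O", "H2O", "H2O")),
    CL = formula_add("C3H8O3", "C3H8O3", "C3H8O3", "H3PO4", "H3PO4",
                     acyl_formula(c, d, 4), subtract = rep("H2O", 8)),
    # ceramide: sphingoid d(C_b):(D_b) backbone folded into totals
    Cer = sprintf("C%dH%dNO3", c, 2 * c - 2 * d + 1),
    SM = formula_add(sprintf("C%dH%dNO3", c, 2 * c - 2 * d + 1),
                     "H3PO4", "C5H13NO", subtract = c("H2O", "H2O")),
    HexCer = formula_add(sprintf("C%dH%dNO3", c, 2 * c - 2 * d + 1),
                         "C6H12O6", subtract = "H2O"),
    SGL = formula_add(sprintf("C%dH%dNO3", c, 2 * c - 2 * d + 1),
                      "C6H12O6", "H2SO4", subtract = c("H2O", "H2O")),
    `sphingoid base` = sprintf("C%dH%dNO2", c, 2 * c - 2 * d + 3),
    abort(paste0("unsupported subclass: ", subclass))
  )
  if (ether || plasmalogen) {
    f <- if (plasmalogen) formula_add(f, subtract = "O")
         else formula_add(f, "H2", subtract = "O")
  }
  f
}

# per-subclass defaults: adducts and diagnostic fragment (charged formulas)
SUBCLASS_IONS <- list(
  Car = list(adducts = "[M+H]+", fragments = "C4H5O2+"),
  FFA = list(adducts = "[M-H]-", fragments = NA),       # acyl anion, per entry
  DG = list(adducts = "[M+NH4]+", fragments = NA),      # [M+H-H2O]+, per entry
  TG = list(adducts = "[M+NH4]+", fragments = NA),
  PA = list(adducts = "[M-H]-", fragments = "C3H6O5P-"),
  PG = list(adducts = "[M-H]-", fragments = "C3H6O5P-"),
  CL = list(adducts = "[M-H]-", fragments = "C3H6O5P-"),
  LPC = list(adducts = "[M+H]+", fragments = "C5H15NO4P+"),
  LPE = list(adducts = "[M-H]-", fragments = "C5H11NO5P-"),
  PC = list(adducts = "[M+H]+", fragments = "C5H15NO4P+"),
  PE = list(adducts = "[M-H]-", fragments = "C5H11NO5P-"),
  PI = list(adducts = "[M-H]-", fragments = "C6H10O8P-"),
  PS = list(adducts = "[M-H]-", fragments = "C3H6O5P-"),
  Cer = list(adducts = "[M+H]+", fragments = "C18H34N+"),
  HexCer = list(adducts = "[M+H]+", fragments = "C18H34N+"),
  SGL = list(adducts = "[M-H]-", fragments = "HO4S-"),
  SM = list(adducts = "[M+H]+", fragments = "C5H15NO4P+"),
  `sphingoid base` = list(adducts = "[M+H]+", fragments = "C18H34N+")
)

# build one dictionary entry from a shorthand name (or an override formula)
lipid_entry <- function(name, subclass = NULL, formula = NULL) {
  if (is.null(subclass) || is.null(formula)) {
    parsed <- parse_shorthand(name)
    subclass <- subclass %||% parsed$subclass
    formula <- formula %||% lipid_formula(
      subclass, parsed$total_c, parsed$total_db,
      ether = parsed$ether, plasmalogen = parsed$plasmalogen
    )
  }
  ions <- SUBCLASS_IONS[[subclass]]
  if (is.null(ions)) abort(paste0("unsupported subclass: ", subclass))
  frag <- ions$fragments
  if (subclass == "FFA") {
    frag <- paste0(formula_add(formula, subtract = "H"), "-")
  }
  if (subclass %in% c("DG", "TG")) {
    frag <- paste0(formula_add(formula, "H", subtract = "H2O"), "+")
  }
  tibble(
    name = name,
    subclass = subclass,
    lipid_class = SUBCLASS_CLASS[[subclass]],
    formula = formula,
    monoisotopic_mass = formula_mass(formula),
    adducts = ions$adducts,
    fragment_formulas = frag
  )
}

#' Assemble a lipid dictionary
#'
#' @param entries Tibble of entries as produced internally (columns `name`,
#'   `subclass`, `lipid_class`, `formula`, `monoisotopic_mass`, `adducts`
#'   (`;`-separated labels), `fragment_formulas` (`;`-separated charged
#'   formulas)).
#' @param tolerance_ppm_precursor,tolerance_ppm_fragment Match tolerances (ppm).
#' @param adduct_table See [default_adduct_table()].
#' @return A `lipid_dictionary` object.
#' @export
lipid_dictionary <- function(entries,
                             tolerance_ppm_precursor = 5,
                             tolerance_ppm_fragment = 10,
                             adduct_table = default_adduct_table()) {
  entries <- as_tibble(entries)
  stopifnot(tolerance_ppm_precursor > 0, tolerance_ppm_fragment > 0)
  if (anyDuplicated(entries$name)) abort("duplicate entry names in dictionary")
  bad <- abs(entries$monoisotopic_mass - formula_mass(entries$formula)) > 1e-4
  if (any(bad)) {
    abort(paste0("monoisotopic_mass inconsistent with formula for: ",
                 paste(head(entries$name[bad], 5), collapse = ", ")))
  }
  structure(
    list(entries = entries,
         tolerance_ppm_precursor = tolerance_ppm_precursor,
         tolerance_ppm_fragment = tolerance_ppm_fragment,
         adduct_table = adduct_table),
    class = "lipid_dictionary"
  )
}

#' @export
print.lipid_dictionary <- function(x, ...) {
  cat(sprintf("<lipid_dictionary> %d entries, %d subclasses, %g/%g ppm tolerances\n",
              nrow(x$entries), length(unique(x$entries$subclass)),
              x$tolerance_ppm_precursor, x$tolerance_ppm_fragment))
  invisible(x)
}

#' Built-in lipid dictionary
#'
#' About a hundred species spanning all 18 supported subclasses, including the
#' named fatty acids (myristic, palmitic, stearic, arachidic, ...) and the
#' diacyl, ether and plasmalogen phospholipids a rat-cortex lipidomics panel
#' typically reports. Formulas are built with [lipid_formula()]; the handful of
#' trivial-name entries (e.g. tetradecanedioic acid, a dicarboxylic fatty
#' acid) carry explicit formulas.
#'
#' @inheritParams lipid_dictionary
#' @return A `lipid_dictionary`.
#' @export
default_lipid_dictionary <- function(tolerance_ppm_precursor = 5,
                                     tolerance_ppm_fragment = 10) {
  names <- c(
    # fatty acid class
    "Car(16:0)", "Car(16:1)", "Car(17:0)", "Car(18:1)",
    "FFA(14:0)", "FFA(16:0)", "FFA(16:1)", "FFA(17:0)", "FFA(17:1)",
    "FFA(18:0)", "FFA(18:2)", "FFA(18:3)", "FFA(20:0)", "FFA(22:2)",
    "FFA(22:4)", "FFA(22:6)", "FFA(23:0)", "FFA(28:0)",
    # glycerolipids
    "DG(34:1)", "DG(36:1)", "DG(40:6)",
    "PA(34:1)", "PA(36:2)",
    "PG(34:1)", "PG(36:2)",
    "TG(36:2)", "TG(48:1)", "TG(52:3)", "TG(54:4)", "TG(54:5)", "TG(58:9)",
    # phospholipids
    "CL(72:6)", "CL(72:8)",
    "LPC(16:0)", "LPC(18:1)", "LPE(20:4)", "LPE(22:6)",
    "PC(30:0)", "PC(32:0)", "PC(34:1)", "PC(36:3)", "PC(37:3)", "PC(38:2)",
    "PC(40:8)", "PC(41:1)", "PC(41:7)",
    "PC(O-37:5)", "PC(O-38:4)", "PC(O-38:5)",
    # ether/plasmalogen species with one in-mode record per composition:
    # PE(O-36:4) duplicates PE(O-16:1/20:3), and PE(P-40:4) duplicates
    # PE(O-40:5) -- indistinguishable by exact mass, so one entry stands
    # for the composition
    "PE(34:1)", "PE(36:2)", "PE(36:3)", "PE(38:4)", "PE(42:10)",
    "PE(O-16:1/20:3)", "PE(O-32:1)", "PE(O-38:5)",
    "PE(O-40:1)", "PE(O-40:5)", "PE(O-40:7)", "PE(O-42:7)",
    "PI(34:1)", "PI(38:4)", "PI(40:6)",
    "PS(36:1)", "PS(38:4)", "PS(40:5)", "PS(40:6)", "PS(O-40:7)",
    # sphingolipids
    "Cer(d34:1)", "Cer(d36:1)", "Cer(d36:2)", "Cer(d38:2)", "Cer(d41:0)",
    "Cer(d42:2)",
    "HexCer(d34:1)", "HexCer(d36:1)", "HexCer(d42:2)",
    "SGL(d34:1)", "SGL(d36:1)", "SGL(d42:2)",
    "SM(d34:1)", "SM(d36:1)", "SM(d36:2)", "SM(d38:1)", "SM(d42:2)",
    "sphingosine(d18:1)", "sphingosine(d16:1)", "sphinganine(d18:0)"
  )
  entries <- list_rbind(lapply(names, function(nm) {
    sub <- parse_shorthand(nm)$subclass
    if (sub %in% c("sphingosine", "sphinganine")) {
      p <- parse_shorthand(nm)
      lipid_entry(nm, subclass = "sphingoid base",
                  formula = lipid_formula("sphingoid base", p$total_c, p$total_db))
    } else if (sub == "Cer" || sub == "SM" || sub == "HexCer" || sub == "SGL") {
      lipid_entry(nm)
    } else {
      lipid_entry(nm)
    }
  }))
  extra <- list_rbind(list(
    # dicarboxylic and trivial-name fatty acids reported by name
    lipid_entry("tetradecanedioic acid", subclass = "FFA", formula = "C14H26O4"),
    lipid_entry("DG(16:0_22:4)", subclass = "DG",
                formula = lipid_formula("DG", 38, 4))
  ))
  entries <- bind_rows(entries, extra)
  lipid_dictionary(entries,
                   tolerance_ppm_precursor = tolerance_ppm_precursor,
                   tolerance_ppm_fragment = tolerance_ppm_fragment)
}

#' Read / write a lipid dictionary CSV
#'
#' Dialect: `name,subclass,class,formula,adducts,fragment_formulas`, with
#' `;`-separated multi-valued fields.
#'
#' @param path CSV path.
#' @param ... Passed to [lipid_dictionary()] (tolerances).
#' @return A `lipid_dictionary`.
#' @export
read_lipid_dictionary <- function(path, ...) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  entries <- tibble(
    name = raw$name, subclass = raw$subclass, lipid_class = raw$class,
    formula = raw$formula,
    monoisotopic_mass = formula_mass(raw$formula),
    adducts = raw$adducts, fragment_formulas = raw$fragment_formulas
  )
  lipid_dictionary(entries, ...)
}

#' @rdname read_lipid_dictionary
#' @param dict A `lipid_dictionary`.
#' @export
write_lipid_dictionary <- function(dict, path) {
  out <- dict$entries |>
    select("name", "subclass", class = "lipid_class", "formula",
           "adducts", "fragment_formulas")
  readr::write_csv(out, path, progress = FALSE)
  invisible(dict)
}
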