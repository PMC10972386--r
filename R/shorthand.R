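#' Parse lipid shorthand nomenclature
#'
#' Understands names at species (sum-composition) level, e.g. `PC(38:2)`, at
#' fatty-acyl level, e.g. `PC(18:1_20:1)` (`_` = sn-position unknown, `/` =
#' known), and the combined form `PC(38:2) > PC(18:1_20:1)` where `>` refines a
#' sum composition. `O-` marks an ether linkage, `P-` a plasmalogen
#' (vinyl-ether), and a `d` prefix a sphingoid (dihydroxy) backbone.
#'
#' @param name A shorthand lipid name.
#' @return A list with elements `subclass`, `total_c`, `total_db`,
#'   `chains` (tibble with `prefix`, `c`, `db`), `sn_known`, `ether`,
#'   `plasmalogen`, and `refined` (whether a fatty-acyl refinement was given).
#' @examples
#' parse_shorthand("PC(38:2) > PC(18:1_20:1)")
#' parse_shorthand("PE(O-16:1/20:3)")
#' @export
parse_shorthand <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  parts <- strsplit(name, "\\s*>\\s*")[[1]]
  if (length(parts) > 2 || length(parts) < 1) {
    abort(paste0("malformed shorthand name: ", name))
  }
  sum_part <- parse_one_shorthand(parts[[1]])
  out <- list(
    subclass = sum_part$subclass,
    total_c = sum(sum_part$chains$c),
    total_db = sum(sum_part$chains$db),
    chains = sum_part$chains,
    sn_known = sum_part$sn_known,
    ether = any(sum_part$chains$prefix == "O-"),
    plasmalogen = any(sum_part$chains$prefix == "P-"),
    refined = FALSE
  )
  if (length(parts) == 2) {
    ref <- parse_one_shorthand(parts[[2]])
    if (ref$subclass != out$subclass) {
      abort("refinement subclass differs from sum-composition subclass")
    }
    if (sum(ref$chains$c) != out$total_c || sum(ref$chains$db) != out$total_db) {
      abort(paste0("refinement chains do not sum to the sum composition in: ",
                   name))
    }
    out$chains <- ref$chains
    out$sn_known <- ref$sn_known
    out$ether <- any(ref$chains$prefix == "O-")
    out$plasmalogen <- any(ref$chains$prefix == "P-")
    out$refined <- TRUE
  }
  out
}

parse_one_shorthand <- function(token) {
  m <- regexec("^([A-Za-z]+)\\(([^()]+)\\)$", token)[[1]]
  if (m[1] == -1) abort(paste0("malformed shorthand name: ", token))
  pieces <- regmatches(token, list(m))[[1]]
  subclass <- pieces[2]
  body <- pieces[3]
  sn_known <- grepl("/", body)
  if (sn_known && grepl("_", body)) {
    abort(paste0("mixed '/' and '_' separators in: ", token))
  }
  chains_raw <- strsplit(body, "[/_]")[[1]]
  chains <- lapply(chains_raw, function(ch) {
    cm <- regexec("^(O-|P-|d|t)?([0-9]+):([0-9]+)$", ch)[[1]]
    if (cm[1] == -1) abort(paste0("malformed chain '", ch, "' in: ", token))
    cp <- regmatches(ch, list(cm))[[1]]
    tibble(prefix = cp[2], c = as.integer(cp[3]), db = as.integer(cp[4]))
  })
  list(subclass = subclass, chains = list_rbind(chains), sn_known = sn_known)
}

#' Print a parsed shorthand back to its canonical string
#'
#' Inverse of [parse_shorthand()] on the supported grammar.
#'
#' @param parsed A list as returned by [parse_shorthand()].
#' @return The shorthand name.
#' @export
print_shorthand <- function(parsed) {
  sep <- if (isTRUE(parsed$sn_known)) "/" else "_"
  chain_str <- paste0(parsed$chains$prefix, parsed$chains$c, ":",
                      parsed$chains$db, collapse = sep)
  refined <- paste0(parsed$subclass, "(", chain_str, ")")
  if (!isTRUE(parsed$refined)) return(refined)
  sum_prefix <- if (parsed$plasmalogen) "P-" else if (parsed$ether) "O-" else ""
  sum_str <- paste0(parsed$subclass, "(", sum_prefix, parsed$total_c, ":",
                    parsed$total_db, ")")
  paste0(sum_str, " > ", refined)
}
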