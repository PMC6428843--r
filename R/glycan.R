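# Glycan composition grammar, mass calculus and glycan-class typing.
#
# A glycan composition is a multiset of monosaccharide residues with no
# topology or linkage information, written "HexNAc(2)Hex(9)". Compositions
# are represented as named integer vectors over the full symbol table
# (zero counts kept internally, omitted from the canonical text).

#' Create a glycan composition
#'
#' @param ... Residue counts by symbol, e.g. `glycan_composition(HexNAc = 2,
#'   Hex = 9)`, or a single named vector/list.
#' @return An object of class `glycan_composition`: a named integer vector
#'   over the full monosaccharide table.
#' @examples
#' glycan_composition(HexNAc = 2, Hex = 9)
#' @export
glycan_composition <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) &&
      (is.list(args[[1L]]) || length(args[[1L]]) != 1L || !is.null(names(args[[1L]])))) {
    args <- as.list(args[[1L]])
  }
  counts <- stats::setNames(integer(length(MONOSACCHARIDES)), names(MONOSACCHARIDES))
  if (length(args)) {
    if (is.null(names(args)) || any(!nzchar(names(args))))
      stop("glycan_composition(): counts must be named by residue symbol")
    bad <- setdiff(names(args), names(MONOSACCHARIDES))
    if (length(bad))
      stop("unknown monosaccharide symbol: ", paste(bad, collapse = ", "))
    for (s in names(args)) {
      v <- args[[s]]
      if (length(v) != 1L || is.na(v) || v < 0 || v != round(v))
        stop("count for ", s, " must be a single non-negative integer")
      counts[s] <- counts[s] + as.integer(v)
    }
  }
  structure(counts, class = "glycan_composition")
}

#' Parse a glycan composition string
#'
#' Parses the standard compositional notation `"HexNAc(2)Hex(9)"` into a
#' [glycan_composition()]. The symbol table is closed: any token outside
#' `names(MONOSACCHARIDES)` is an error. Repeated symbols accumulate.
#'
#' @param text A nonempty composition string.
#' @return A `glycan_composition`.
#' @examples
#' parse_composition("HexNAc(4)Hex(4)Fuc(1)NeuAc(1)")
#' @export
parse_composition <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("parse_composition(): text must be a single nonempty string")
  rx <- "([A-Za-z0-9]+)\\(([^)]*)\\)"
  m <- gregexpr(rx, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L)
    stop("malformed composition string: ", sQuote(text))
  toks <- regmatches(text, gregexpr(rx, text, perl = TRUE))[[1L]]
  if (sum(nchar(toks)) != nchar(text))
    stop("malformed composition string (unparsed characters): ", sQuote(text))
  counts <- stats::setNames(integer(length(MONOSACCHARIDES)), names(MONOSACCHARIDES))
  for (tok in toks) {
    sym <- sub(rx, "\\1", tok, perl = TRUE)
    num <- sub(rx, "\\2", tok, perl = TRUE)
    if (!sym %in% names(MONOSACCHARIDES))
      stop("unknown monosaccharide symbol ", sQuote(sym), " in ", sQuote(text))
    if (!grepl("^[0-9]+$", num))
      stop("count for ", sQuote(sym), " is not a non-negative integer: ", sQuote(num))
    counts[sym] <- counts[sym] + as.integer(num)
  }
  structure(counts, class = "glycan_composition")
}

#' Canonical text of a glycan composition
#'
#' Renders counts in the fixed symbol order HexNAc, Hex, Fuc, NeuAc,
#' Phospho, omitting zero counts, so that composition strings can be used
#' as table keys. `parse_composition(composition_text(x))` reproduces `x`.
#'
#' @param comp A `glycan_composition`.
#' @return A single string; `""` for the empty composition.
#' @export
composition_text <- function(comp) {
  comp <- as_glycan_composition(comp)
  nz <- comp[comp > 0L]
  if (!length(nz)) return("")
  paste0(names(nz), "(", nz, ")", collapse = "")
}

#' @export
format.glycan_composition <- function(x, ...) {
  txt <- composition_text(x)
  if (!nzchar(txt)) "<empty glycan>" else txt
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat("glycan composition:", format(x), "\n")
  invisible(x)
}

#' Coerce to a glycan composition
#'
#' Accepts a `glycan_composition`, a composition string, or a named count
#' vector.
#'
#' @param x Object to coerce.
#' @return A `glycan_composition`.
#' @export
as_glycan_composition <- function(x) {
  if (inherits(x, "glycan_composition")) return(x)
  if (is.character(x)) return(parse_composition(x))
  if (is.numeric(x) && !is.null(names(x))) return(glycan_composition(as.list(x)))
  stop("cannot coerce object of class ", class(x)[1L], " to glycan_composition")
}

#' Monoisotopic mass of a glycan composition
#'
#' Sum of residue masses over the composition; additive over multiset
#' union. The empty composition has mass 0.
#'
#' @param comp A `glycan_composition` (or anything [as_glycan_composition()]
#'   accepts).
#' @return Monoisotopic mass in Da.
#' @examples
#' composition_mass(parse_composition("HexNAc(2)Hex(9)"))
#' @export
composition_mass <- function(comp) {
  comp <- as_glycan_composition(comp)
  sum(as.numeric(comp) * MONOSACCHARIDES[names(comp)])
}

#' Total residue count of a composition
#'
#' @param comp A `glycan_composition`.
#' @return Integer number of monosaccharide residues (Phospho counts as a
#'   residue unit for ladder-depth accounting).
#' @export
composition_size <- function(comp) {
  comp <- as_glycan_composition(comp)
  sum(as.integer(comp))
}

#' Default glycan classification boundaries
#'
#' The compositional boundaries separating high-mannose, paucimannose and
#' complex/hybrid N-glycans. They are configuration, not physical
#' constants: high mannose requires exactly the two core HexNAc with five
#' or more Hex; paucimannose is the truncated core (two HexNAc, at most
#' four Hex, at most one Fuc).
#'
#' @return A list with elements `high_mannose_min_hex` (5),
#'   `paucimannose_max_hex` (4), `paucimannose_max_fuc` (1).
#' @export
glycan_class_config <- function() {
  list(high_mannose_min_hex = 5L,
       paucimannose_max_hex = 4L,
       paucimannose_max_fuc = 1L)
}

GLYCAN_CLASSES <- c("paucimannose", "high_mannose", "complex_hybrid",
                    "fucosylated", "sialylated", "M6P")

#' Classify a glycan composition
#'
#' Assigns each composition to exactly one exclusive class under the
#' precedence M6P > sialylated > fucosylated > high mannose > paucimannose
#' > complex/hybrid, and independently computes multilabel flags:
#' any glycan carrying a NeuAc is sialylated; any glycan carrying a Fuc is
#' fucosylated; high-mannose and M6P flags follow their compositional
#' definitions. Under the exclusive scheme the fucosylated class contains
#' fucosylated glycans that are not sialylated, and complex/hybrid glycans
#' are neither fucosylated nor sialylated.
#'
#' @param comp A `glycan_composition`.
#' @param config Boundary configuration, see [glycan_class_config()].
#' @return A list of class `glycan_class` with elements `exclusive_class`
#'   (single string) and `multilabel_flags` (character vector, subset of
#'   high_mannose, fucosylated, sialylated, M6P).
#' @examples
#' classify_glycan(parse_composition("HexNAc(4)Hex(4)Fuc(1)NeuAc(1)"))
#' @export
classify_glycan <- function(comp, config = glycan_class_config()) {
  comp <- as_glycan_composition(comp)
  hexnac <- comp[["HexNAc"]]; hex <- comp[["Hex"]]
  fuc <- comp[["Fuc"]]; neuac <- comp[["NeuAc"]]; phospho <- comp[["Phospho"]]

  is_m6p  <- phospho >= 1L
  is_sial <- neuac >= 1L
  is_fuc  <- fuc >= 1L
  is_hm   <- hexnac == 2L && hex >= config$high_mannose_min_hex &&
             fuc == 0L && neuac == 0L && phospho == 0L
  is_pauci <- hexnac == 2L && hex <= config$paucimannose_max_hex &&
              fuc <= config$paucimannose_max_fuc &&
              neuac == 0L && phospho == 0L

  exclusive <- if (is_m6p) "M6P"
    else if (is_sial) "sialylated"
    else if (is_fuc) "fucosylated"
    else if (is_hm) "high_mannose"
    else if (is_pauci) "paucimannose"
    else "complex_hybrid"

  flags <- character(0)
  if (is_hm)   flags <- c(flags, "high_mannose")
  if (is_fuc)  flags <- c(flags, "fucosylated")
  if (is_sial) flags <- c(flags, "sialylated")
  if (is_m6p)  flags <- c(flags, "M6P")

  structure(list(exclusive_class = exclusive, multilabel_flags = flags),
            class = "glycan_class")
}

#' Six-type membership of a glycan
#'
#' Returns the glycan-type labels used by the domain composition analytics.
#' With `scheme = "exclusive"` each glycan belongs to exactly one of the six
#' types. With `scheme = "multilabel"` a fucosylated paucimannose or
#' fucosylated sialylated glycan is additionally counted as fucosylated,
#' so one glycan can carry up to two labels.
#'
#' @param comp A `glycan_composition`.
#' @param scheme `"exclusive"` or `"multilabel"`.
#' @return Character vector of type labels (subset of the six classes).
#' @export
glycan_types <- function(comp, scheme = c("multilabel", "exclusive")) {
  scheme <- match.arg(scheme)
  cl <- classify_glycan(comp)
  types <- cl$exclusive_class
  if (scheme == "multilabel" &&
      "fucosylated" %in% cl$multilabel_flags &&
      cl$exclusive_class %in% c("paucimannose", "sialylated"))
    types <- c(types, "fucosylated")
  types
}

#' Load a glycan composition database
#'
#' Reads a TSV with columns `id` and `composition` (optional `label`),
#' parses every composition, and rejects duplicates. Row order is
#' preserved.
#'
#' @param path Path to the TSV. Defaults to the packaged database of 117
#'   mouse-brain style N-glycan compositions.
#' @return A data.frame with columns `id`, `composition` (canonical text)
#'   and, when present, `label`; attribute `"compositions"` holds the list
#'   of parsed `glycan_composition` objects.
#' @export
load_glycan_database <- function(path = system.file("extdata", "glycan_db_synthetic.tsv",
                                                    package = "glycopipe")) {
  if (!file.exists(path)) stop("glycan database not found: ", path)
  db <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("id", "composition")
  if (!all(need %in% names(db)))
    stop("glycan database must have columns 'id' and 'composition'")
  comps <- vector("list", nrow(db))
  canon <- character(nrow(db))
  for (i in seq_len(nrow(db))) {
    comps[[i]] <- tryCatch(parse_composition(db$composition[i]),
                           error = function(e)
                             stop("glycan database line ", i + 1L, ": ",
                                  conditionMessage(e), call. = FALSE))
    canon[i] <- composition_text(comps[[i]])
  }
  if (anyDuplicated(canon))
    stop("duplicate glycan composition in database: ",
         canon[duplicated(canon)][1L])
  db$composition <- canon
  attr(db, "compositions") <- comps
  db
}
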