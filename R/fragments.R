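# Theoretical fragment-ion generation for intact glycopeptides.
#
# Electron-driven dissociation of glycopeptides cleaves the peptide
# backbone (c/z-type ions, mostly retaining the intact glycan) while
# concurrent vibrational activation cleaves glycosidic bonds (Y-ion
# ladders retaining the intact peptide, and low-mass B/oxonium ions).
# Fragment tables carry one row per ion with neutral-mass bookkeeping
# resolved to m/z.

#' Construct a glycopeptide
#'
#' A peptide sequence carrying exactly one N-linked glycan at a stated
#' asparagine, plus fixed and variable modifications.
#'
#' @param sequence Amino-acid string over the 20 canonical residues.
#' @param glycosite 1-based position of the modified asparagine.
#' @param glycan A `glycan_composition` (or string); may be empty.
#' @param fixed_mods Named numeric vector residue -> mass delta applied to
#'   every occurrence (default: carbamidomethyl C).
#' @param variable_mods Optional data.frame with columns `position`,
#'   `delta` for position-specific modifications.
#' @return An object of class `glycopeptide`.
#' @examples
#' glycopeptide("TNSSFIQGFVDHVKEDCDR", 2, "HexNAc(2)Hex(9)")
#' @export
glycopeptide <- function(sequence, glycosite, glycan = glycan_composition(),
                         fixed_mods = DEFAULT_FIXED_MODS,
                         variable_mods = NULL) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a single nonempty string")
  res <- strsplit(sequence, "")[[1L]]
  bad <- setdiff(res, names(AMINO_ACIDS))
  if (length(bad))
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "))
  L <- length(res)
  glycosite <- as.integer(glycosite)
  if (is.na(glycosite) || glycosite < 1L || glycosite > L)
    stop("glycosite must lie within the peptide (1..", L, ")")
  if (res[glycosite] != "N")
    stop("residue at glycosite position ", glycosite, " is ", res[glycosite],
         ", not N")
  if (!is.null(variable_mods)) {
    if (!all(c("position", "delta") %in% names(variable_mods)))
      stop("variable_mods needs columns 'position' and 'delta'")
    if (any(variable_mods$position < 1 | variable_mods$position > L))
      stop("variable modification position out of range")
  }
  structure(list(sequence = sequence,
                 residues = res,
                 glycosite = glycosite,
                 glycan = as_glycan_composition(glycan),
                 fixed_mods = fixed_mods,
                 variable_mods = variable_mods),
            class = "glycopeptide")
}

#' @export
print.glycopeptide <- function(x, ...) {
  cat("glycopeptide: ", x$sequence, "\n  glycosite: N", x$glycosite,
      "\n  glycan: ", format(x$glycan), "\n", sep = "")
  invisible(x)
}

# Per-residue mass vector including fixed and variable modification deltas.
residue_masses <- function(gp) {
  m <- AMINO_ACIDS[gp$residues]
  fm <- gp$fixed_mods
  if (length(fm)) {
    for (r in names(fm)) m[gp$residues == r] <- m[gp$residues == r] + fm[[r]]
  }
  if (!is.null(gp$variable_mods)) {
    for (i in seq_len(nrow(gp$variable_mods)))
      m[gp$variable_mods$position[i]] <-
        m[gp$variable_mods$position[i]] + gp$variable_mods$delta[i]
  }
  unname(m)
}

#' Monoisotopic peptide mass
#'
#' Sum of residue masses plus one water, plus modification deltas. The
#' glycan is not included; see [precursor_mz()] for the glycosylated
#' precursor.
#'
#' @param sequence Amino-acid string.
#' @param fixed_mods Named numeric vector residue -> delta.
#' @param variable_mods Optional data.frame (`position`, `delta`).
#' @return Monoisotopic mass in Da.
#' @examples
#' peptide_mass("GG")  # 132.05349
#' @export
peptide_mass <- function(sequence, fixed_mods = DEFAULT_FIXED_MODS,
                         variable_mods = NULL) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a single nonempty string")
  res <- strsplit(sequence, "")[[1L]]
  bad <- setdiff(res, names(AMINO_ACIDS))
  if (length(bad))
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "))
  m <- sum(AMINO_ACIDS[res])
  if (length(fixed_mods))
    for (r in names(fixed_mods)) m <- m + fixed_mods[[r]] * sum(res == r)
  if (!is.null(variable_mods)) m <- m + sum(variable_mods$delta)
  m + MASS_CONST[["water"]]
}

# Neutral-mass offsets per backbone series relative to the summed residue
# masses of the fragment. z ions are generated as z-radical (z-dot)
# species, the direct ETD product.
series_offset <- function(series) {
  switch(series,
         b = 0,
         y = MASS_CONST[["water"]],
         c = MASS_CONST[["ammonia"]],
         z = MASS_CONST[["water"]] - MASS_CONST[["ammonia"]] + MASS_CONST[["hydrogen"]],
         stop("unknown backbone series: ", series))
}

HEXNAC_STUB_MASS <- 203.079373

empty_fragment_table <- function() {
  data.frame(series = character(0), index = integer(0),
             retention = character(0), charge = integer(0),
             mz = numeric(0), composition_retained = character(0),
             in_range = logical(0), stringsAsFactors = FALSE)
}

#' Theoretical peptide-backbone fragment ions
#'
#' Generates b/y/c/z ions for every cleavable inter-residue bond
#' (1..L-1) at charges 1..`max_charge`. Fragments whose residue span
#' contains the glycosite are emitted once per requested glycan retention
#' mode: `intact` (full glycan retained, the dominant ETD outcome),
#' `stub` (a single HexNAc retained), `none` (naked backbone fragment).
#' Fragments on the other side of the glycosite carry no glycan and are
#' emitted once with retention `"n/a"`.
#'
#' @param gp A [glycopeptide()].
#' @param series Character subset of `c("b","y","c","z")`.
#' @param retention Character subset of `c("intact","stub","none")`,
#'   applied to glycosite-containing fragments.
#' @param max_charge Maximum fragment charge (>= 1).
#' @param mz_ceiling Ions above this m/z are kept but flagged
#'   `in_range = FALSE` (default 2000 Th, a typical MS/MS scan upper
#'   bound).
#' @return A data.frame with columns `series`, `index` (cleaved-bond
#'   ordinal within the series), `retention`, `charge`, `mz`,
#'   `composition_retained`, `in_range`.
#' @export
backbone_fragments <- function(gp, series = c("c", "z"),
                               retention = c("intact", "none"),
                               max_charge = 1L, mz_ceiling = 2000) {
  stopifnot(inherits(gp, "glycopeptide"))
  series <- match.arg(series, c("b", "y", "c", "z"), several.ok = TRUE)
  retention <- match.arg(retention, c("intact", "stub", "none"),
                         several.ok = TRUE)
  max_charge <- as.integer(max_charge)
  if (is.na(max_charge) || max_charge < 1L)
    stop("max_charge must be >= 1")
  L <- length(gp$residues)
  rm <- residue_masses(gp)
  nterm_cum <- cumsum(rm)            # mass of residues 1..i
  total <- nterm_cum[L]
  glyc_mass <- composition_mass(gp$glycan)
  glyc_text <- composition_text(gp$glycan)

  rows <- vector("list", 0L)
  for (s in series) {
    nterminal <- s %in% c("b", "c")
    off <- series_offset(s)
    for (i in seq_len(L - 1L)) {
      # index i = number of residues on the fragment; bond cleaved is
      # i (N-terminal series) or L - i (C-terminal series).
      frag_res_mass <- if (nterminal) nterm_cum[i] else total - nterm_cum[L - i]
      has_site <- if (nterminal) gp$glycosite <= i else gp$glycosite > L - i
      modes <- if (has_site && composition_size(gp$glycan) > 0L) retention else "n/a"
      for (mode in modes) {
        add <- switch(mode,
                      intact = glyc_mass,
                      stub = HEXNAC_STUB_MASS,
                      none = 0, `n/a` = 0)
        ret_text <- switch(mode,
                           intact = glyc_text,
                           stub = "HexNAc(1)", none = "", `n/a` = "")
        neutral <- frag_res_mass + off + add
        for (z in seq_len(max_charge)) {
          mz <- (neutral + z * MASS_CONST[["proton"]]) / z
          rows[[length(rows) + 1L]] <- data.frame(
            series = s, index = i, retention = mode, charge = z,
            mz = mz, composition_retained = ret_text,
            in_range = mz <= mz_ceiling, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(empty_fragment_table())
  do.call(rbind, rows)
}

# All sub-compositions of a glycan that are empty or retain at least one
# HexNAc (the peptide-proximal core residue is lost last). Returns a list
# of named integer count vectors; the full composition is excluded.
y_subcompositions <- function(glycan) {
  counts <- as.integer(glycan)
  names(counts) <- names(glycan)
  grid <- expand.grid(lapply(counts, function(k) 0:k), KEEP.OUT.ATTRS = FALSE)
  keep <- apply(grid, 1L, function(g) {
    tot <- sum(g)
    if (tot == sum(counts)) return(FALSE)               # full glycan = precursor
    tot == 0L || g[["HexNAc"]] >= 1L                    # core-attachment rule
  })
  grid <- grid[keep, , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) {
    v <- as.integer(grid[i, ])
    names(v) <- names(counts)
    v
  })
}

#' Y-ion ladder of a glycopeptide
#'
#' Y ions retain the intact peptide plus a sub-portion of the glycan.
#' Because no topology is assumed, the ladder is the composition lattice:
#' every sub-composition that either is empty (Y0, the bare peptide) or
#' retains at least one HexNAc, excluding the full composition (which is
#' the precursor, not a fragment). Y1 is the peptide plus one HexNAc.
#'
#' @param gp A [glycopeptide()] with a nonempty glycan.
#' @param max_charge Maximum charge (>= 1).
#' @param require_core_hexnac If `FALSE`, drop the >=1 HexNAc constraint
#'   and enumerate the full lattice.
#' @param mz_ceiling Flag threshold as in [backbone_fragments()].
#' @return Fragment data.frame; `index` is the number of retained glycan
#'   residues, `composition_retained` the retained sub-composition.
#' @export
y_ion_ladder <- function(gp, max_charge = 1L, require_core_hexnac = TRUE,
                         mz_ceiling = 2000) {
  stopifnot(inherits(gp, "glycopeptide"))
  if (composition_size(gp$glycan) == 0L)
    stop("y_ion_ladder() needs a nonempty glycan")
  max_charge <- as.integer(max_charge)
  if (is.na(max_charge) || max_charge < 1L) stop("max_charge must be >= 1")
  pm <- peptide_mass(gp$sequence, gp$fixed_mods, gp$variable_mods)
  subs <- y_subcompositions(gp$glycan)
  if (!require_core_hexnac) {
    counts <- as.integer(gp$glycan); names(counts) <- names(gp$glycan)
    grid <- expand.grid(lapply(counts, function(k) 0:k), KEEP.OUT.ATTRS = FALSE)
    keep <- rowSums(grid) < sum(counts)
    grid <- grid[keep, , drop = FALSE]
    subs <- lapply(seq_len(nrow(grid)), function(i) {
      v <- as.integer(grid[i, ]); names(v) <- names(counts); v
    })
  }
  rows <- vector("list", 0L)
  for (s in subs) {
    smass <- sum(s * MONOSACCHARIDES[names(s)])
    stext <- {
      nz <- s[s > 0L]
      if (length(nz)) paste0(names(nz), "(", nz, ")", collapse = "") else ""
    }
    depth <- sum(s)
    for (z in seq_len(max_charge)) {
      mz <- (pm + smass + z * MASS_CONST[["proton"]]) / z
      rows[[length(rows) + 1L]] <- data.frame(
        series = "Y", index = depth, retention = "n/a", charge = z,
        mz = mz, composition_retained = stext,
        in_range = mz <= mz_ceiling, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$charge, out$index, out$mz), , drop = FALSE]
}

#' Default oxonium-ion catalog
#'
#' The shipped catalog of diagnostic B/oxonium ions: HexNAc (m/z
#' 204.0866), Hex (163.0601), NeuAc (292.1027), NeuAc minus water
#' (274.0921), HexNAcHex (366.1395) and HexNAcHexNeuAc (657.2349).
#'
#' @return data.frame with columns `name`, `composition`, `water_losses`.
#' @export
default_oxonium_catalog <- function() {
  data.frame(
    name = c("HexNAc", "Hex", "NeuAc", "NeuAc-H2O", "HexNAcHex",
             "HexNAcHexNeuAc"),
    composition = c("HexNAc(1)", "Hex(1)", "NeuAc(1)", "NeuAc(1)",
                    "HexNAc(1)Hex(1)", "HexNAc(1)Hex(1)NeuAc(1)"),
    water_losses = c(0L, 0L, 0L, 1L, 0L, 0L),
    stringsAsFactors = FALSE)
}

#' Read an oxonium catalog from TSV
#'
#' @param path TSV with columns `name`, `composition`, `water_losses`.
#' @return data.frame in the catalog layout.
#' @export
read_oxonium_catalog <- function(path) {
  cat_df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("name", "composition", "water_losses") %in% names(cat_df)))
    stop("oxonium catalog needs columns name, composition, water_losses")
  cat_df
}

#' Theoretical B/oxonium ions available from a composition
#'
#' Emits the singly protonated m/z of each catalog entry whose residues
#' are available in `comp` (the availability filter: a NeuAc-containing
#' oxonium ion cannot arise from a glycan without NeuAc).
#'
#' @param comp A `glycan_composition`.
#' @param catalog Catalog data.frame, see [default_oxonium_catalog()].
#' @return Fragment data.frame; `index` is the catalog row, `series` "B".
#' @export
oxonium_ions <- function(comp, catalog = default_oxonium_catalog()) {
  comp <- as_glycan_composition(comp)
  rows <- vector("list", 0L)
  for (i in seq_len(nrow(catalog))) {
    need <- parse_composition(catalog$composition[i])
    if (any(as.integer(need) > as.integer(comp))) next
    mz <- composition_mass(need) + MASS_CONST[["proton"]] -
      catalog$water_losses[i] * MASS_CONST[["water"]]
    rows[[length(rows) + 1L]] <- data.frame(
      series = "B", index = i, retention = "n/a", charge = 1L,
      mz = mz, composition_retained = catalog$name[i],
      in_range = TRUE, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_fragment_table())
  do.call(rbind, rows)
}

#' Precursor m/z of a glycopeptide
#'
#' @param gp A [glycopeptide()].
#' @param charge Precursor charge (>= 1).
#' @return m/z in Th.
#' @export
precursor_mz <- function(gp, charge) {
  stopifnot(inherits(gp, "glycopeptide"))
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("charge must be >= 1")
  pm <- peptide_mass(gp$sequence, gp$fixed_mods, gp$variable_mods)
  (pm + composition_mass(gp$glycan) + charge * MASS_CONST[["proton"]]) / charge
}

#' Full theoretical fragment set of a glycopeptide
#'
#' Convenience wrapper combining [backbone_fragments()], [y_ion_ladder()]
#' and [oxonium_ions()], the fragment classes expected from
#' electron-driven dissociation with concurrent vibrational activation.
#'
#' @param gp A [glycopeptide()].
#' @param max_charge Maximum fragment charge.
#' @param series Backbone series to generate.
#' @param retention Retention modes for glycosite-containing backbone
#'   fragments.
#' @param mz_ceiling Out-of-range flag threshold.
#' @return Fragment data.frame (rows from all three generators).
#' @export
glycopeptide_fragments <- function(gp, max_charge = 1L,
                                   series = c("c", "z"),
                                   retention = c("intact", "none"),
                                   mz_ceiling = 2000) {
  out <- backbone_fragments(gp, series = series, retention = retention,
                            max_charge = max_charge, mz_ceiling = mz_ceiling)
  if (composition_size(gp$glycan) > 0L) {
    out <- rbind(out,
                 y_ion_ladder(gp, max_charge = max_charge,
                              mz_ceiling = mz_ceiling),
                 oxonium_ions(gp$glycan))
  }
  out
}
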