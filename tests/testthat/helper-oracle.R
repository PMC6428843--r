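# Independent mass oracle: computes fragment m/z from elemental formulas
# and atomic monoisotopic masses, a different route than the package's
# residue-mass tables. Used to cross-check every generated fragment ion.

ATOMS <- c(H = 1.0078250319, C = 12.0, N = 14.0030740052,
           O = 15.9949146221, S = 31.97207069, P = 30.97376151)

# residue elemental formulas (amino acid minus water)
AA_FORMULA <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1))

SUGAR_FORMULA <- list(
  HexNAc  = c(C = 8, H = 13, N = 1, O = 5),
  Hex     = c(C = 6, H = 10, O = 5),
  Fuc     = c(C = 6, H = 10, O = 4),
  NeuAc   = c(C = 11, H = 17, N = 1, O = 8),
  Phospho = c(H = 1, P = 1, O = 3))

formula_mass <- function(f) sum(ATOMS[names(f)] * f)

oracle_residue_sum <- function(residues, carbamidomethyl = TRUE) {
  m <- sum(vapply(residues, function(r) formula_mass(AA_FORMULA[[r]]), 0))
  if (carbamidomethyl)   # C2H3NO adduct per cysteine
    m <- m + sum(residues == "C") * formula_mass(c(C = 2, H = 3, N = 1, O = 1))
  m
}

oracle_glycan_mass <- function(counts) {
  if (!length(counts)) return(0)
  sum(vapply(names(counts), function(s)
    counts[[s]] * formula_mass(SUGAR_FORMULA[[s]]), 0))
}

ORACLE_PROTON <- 1.00727646688
ORACLE_WATER <- formula_mass(c(H = 2, O = 1))
ORACLE_NH3 <- formula_mass(c(N = 1, H = 3))

# neutral mass of a backbone fragment with glycan_counts attached
oracle_backbone_neutral <- function(residues, series, glycan_counts = NULL) {
  base <- oracle_residue_sum(residues)
  off <- switch(series,
                b = 0, y = ORACLE_WATER, c = ORACLE_NH3,
                z = ORACLE_WATER - ORACLE_NH3 + ATOMS[["H"]])
  base + off + oracle_glycan_mass(glycan_counts)
}

oracle_mz <- function(neutral, charge) (neutral + charge * ORACLE_PROTON) / charge

oracle_peptide_mass <- function(sequence) {
  oracle_residue_sum(strsplit(sequence, "")[[1L]]) + ORACLE_WATER
}

# brute-force q-values by double loop over thresholds
oracle_qvalues <- function(score, is_decoy) {
  n <- length(score)
  q <- numeric(n)
  for (i in seq_len(n)) {
    fdrs <- vapply(unique(score[score <= score[i]]), function(t) {
      d <- sum(is_decoy & score >= t)
      tg <- sum(!is_decoy & score >= t)
      if (tg == 0) Inf else d / tg
    }, 0)
    q[i] <- min(fdrs)
  }
  q
}

# random glycan composition with at most max_per residues per symbol
random_composition <- function(max_per = 3L) {
  syms <- names(glycopipe::MONOSACCHARIDES)
  counts <- sapply(syms, function(s) sample(0:max_per, 1L))
  counts[["HexNAc"]] <- max(counts[["HexNAc"]], 1L)  # keep it N-glycan-like
  do.call(glycopipe::glycan_composition, as.list(counts))
}

# random peptide containing an N at a known position
random_glycopeptide_sequence <- function(len = 8L) {
  aa <- setdiff(names(glycopipe::AMINO_ACIDS), "N")
  pos <- sample(seq_len(len), 1L)
  res <- sample(aa, len, replace = TRUE)
  res[pos] <- "N"
  list(sequence = paste(res, collapse = ""), glycosite = pos)
}
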