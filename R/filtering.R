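# Post-search identification filtering: target-decoy q-values, the
# six-step filter cascade, glycopeptide-specific FDR estimation, sequon
# validation, and focused-database construction.
#
# PSM tables are plain data.frames with one row per candidate
# identification. Required columns mirror a search-engine export:
#   spectrum_id, peptide, protein_accession, is_decoy, glycosite_position,
#   glycan, n_glycosites, byonic_score, two_d_score, log_prob_abs,
#   delta_mod, precursor_mz, charge, dissociation

#' Filter cascade configuration
#'
#' Thresholds for the six-step post-search filter cascade. Defaults:
#' 1% PSM-level FDR on the ranking score; minimum search-engine score
#' 150; minimum peptide length 5; |log10 protein p-value| strictly above
#' 1; at most one glycosite per peptide; localization (DeltaMod) score of
#' 10 or greater; sequon check on.
#'
#' @param psm_fdr PSM q-value cutoff (fraction).
#' @param min_byonic_score Minimum search score (kept when `>=`).
#' @param min_peptide_length Minimum residue count (kept when `>=`).
#' @param min_log_prob_abs Protein-evidence threshold (kept when `>`,
#'   strict).
#' @param max_glycosites Maximum glycosites per identification.
#' @param min_delta_mod Minimum localization score (kept when `>=`).
#' @param require_sequon Apply the N-X-S/T (X != P) sequon check to
#'   glycosylated survivors.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(psm_fdr = 0.01, min_byonic_score = 150,
                          min_peptide_length = 5, min_log_prob_abs = 1,
                          max_glycosites = 1, min_delta_mod = 10,
                          require_sequon = TRUE) {
  cfg <- list(psm_fdr = psm_fdr, min_byonic_score = min_byonic_score,
              min_peptide_length = min_peptide_length,
              min_log_prob_abs = min_log_prob_abs,
              max_glycosites = max_glycosites, min_delta_mod = min_delta_mod,
              require_sequon = isTRUE(require_sequon))
  num <- vapply(cfg[setdiff(names(cfg), "require_sequon")], as.numeric, 0)
  if (any(is.na(num) | num < 0)) stop("all thresholds must be >= 0")
  class(cfg) <- "filter_config"
  cfg
}

#' Target-decoy q-values for a PSM table
#'
#' At every score threshold t, FDR(t) = (number of decoys scoring >= t) /
#' (number of targets scoring >= t); the q-value of a PSM is the minimum
#' FDR over all thresholds at or below its score (running minimum over
#' decreasing score). Tied scores share a q-value. The plain d/t
#' estimator (no +1 correction) is used.
#'
#' @param psms PSM data.frame with an `is_decoy` logical column.
#' @param score_col Ranking score column; defaults to `two_d_score`,
#'   falling back to `byonic_score` with a warning when absent.
#' @return `psms` with a `q_value` column appended (decoy rows get the
#'   q-value their score would earn). Attribute `"no_decoys"` is set
#'   `TRUE` (with a warning) when the table contains no decoys, in which
#'   case all q-values are 0.
#' @export
compute_qvalues <- function(psms, score_col = "two_d_score") {
  if (!is.data.frame(psms) || !nrow(psms)) stop("psms must be a nonempty data.frame")
  if (!"is_decoy" %in% names(psms)) stop("psms must have an 'is_decoy' column")
  if (!score_col %in% names(psms)) {
    if ("byonic_score" %in% names(psms)) {
      warning("score column ", sQuote(score_col),
              " absent; ranking on byonic_score instead")
      score_col <- "byonic_score"
    } else stop("score column ", sQuote(score_col), " not found")
  }
  s <- psms[[score_col]]
  if (anyNA(s)) stop("score column contains NA")
  dec <- as.logical(psms$is_decoy)
  if (all(dec)) stop("PSM table contains no target hits")

  o <- order(s, decreasing = TRUE)
  n_dec <- cumsum(dec[o])
  n_tgt <- cumsum(!dec[o])
  fdr <- ifelse(n_tgt > 0, n_dec / n_tgt, Inf)
  # ties share the FDR evaluated at the last row of the tie group
  ss <- s[o]
  last_of_tie <- rev(!duplicated(rev(ss)))
  idx_last <- which(last_of_tie)
  grp <- findInterval(seq_along(fdr) - 1L, idx_last) + 1L
  fdr_tie <- fdr[idx_last][grp]
  q <- rev(cummin(rev(fdr_tie)))
  psms$q_value <- numeric(nrow(psms))
  psms$q_value[o] <- q
  if (!any(dec)) {
    warning("no decoy hits present; all q-values are 0")
    attr(psms, "no_decoys") <- TRUE
  }
  psms
}

# The cascade's step predicates, in the order they are applied.
cascade_steps <- function(cfg) {
  list(
    psm_fdr       = function(d) d$q_value <= cfg$psm_fdr,
    byonic_score  = function(d) d$byonic_score >= cfg$min_byonic_score,
    peptide_length= function(d) nchar(d$peptide) >= cfg$min_peptide_length,
    log_prob      = function(d) d$log_prob_abs > cfg$min_log_prob_abs,
    single_site   = function(d) d$n_glycosites <= cfg$max_glycosites,
    delta_mod     = function(d) d$delta_mod >= cfg$min_delta_mod
  )
}

#' Apply the six-step identification filter cascade
#'
#' Steps, in order: (1) PSM q-value at or below the FDR cutoff; (2)
#' search score at or above `min_byonic_score`; (3) peptide length at or
#' above `min_peptide_length`; (4) |log10 protein p-value| strictly above
#' `min_log_prob_abs`; (5) at most `max_glycosites` glycosites; (6)
#' localization score at or above `min_delta_mod`. An optional seventh
#' step validates the N-X-S/T sequon for glycosylated survivors (needs a
#' `sequon_ok` logical column or a `protein_db` to check against).
#'
#' @param psms PSM data.frame; q-values are computed on the fly when the
#'   `q_value` column is absent.
#' @param cfg A [filter_config()].
#' @param protein_db Optional named character vector of protein sequences
#'   for the sequon check.
#' @return An object of class `filter_report`: list with `steps`
#'   (data.frame: step, n_in, n_removed, n_out), `survivors` (the
#'   filtered data.frame), `glyco_fdr_estimate` (decoy/target ratio among
#'   glycosylated survivors before the localization step, the
#'   glycopeptide-level FDR), `glyco_fdr_final` (same after all steps)
#'   and `decoys_remaining`.
#' @export
apply_filter_cascade <- function(psms, cfg = filter_config(),
                                 protein_db = NULL) {
  required <- c("spectrum_id", "peptide", "is_decoy", "n_glycosites",
                "byonic_score", "log_prob_abs", "delta_mod")
  miss <- setdiff(required, names(psms))
  if (length(miss))
    stop("PSM table lacks required column(s): ", paste(miss, collapse = ", "))
  for (col in c("byonic_score", "log_prob_abs", "delta_mod", "n_glycosites")) {
    if (anyNA(psms[[col]])) {
      row <- which(is.na(psms[[col]]))[1L]
      stop("missing value in column ", sQuote(col), " at row ", row)
    }
  }
  if (!"q_value" %in% names(psms)) psms <- compute_qvalues(psms)

  steps <- cascade_steps(cfg)
  report <- data.frame(step = character(0), n_in = integer(0),
                       n_removed = integer(0), n_out = integer(0))
  cur <- psms
  glyco_fdr_pre <- NA_real_
  for (nm in names(steps)) {
    keep <- steps[[nm]](cur)
    report <- rbind(report, data.frame(step = nm, n_in = nrow(cur),
                                       n_removed = sum(!keep),
                                       n_out = sum(keep)))
    cur <- cur[keep, , drop = FALSE]
    if (nm == "single_site")
      glyco_fdr_pre <- estimate_glyco_fdr(cur)
  }
  if (cfg$require_sequon) {
    ok <- sequon_ok_column(cur, protein_db)
    report <- rbind(report, data.frame(step = "sequon", n_in = nrow(cur),
                                       n_removed = sum(!ok),
                                       n_out = sum(ok)))
    cur <- cur[ok, , drop = FALSE]
  }
  structure(list(steps = report,
                 survivors = cur,
                 glyco_fdr_estimate = glyco_fdr_pre,
                 glyco_fdr_final = estimate_glyco_fdr(cur),
                 decoys_remaining = sum(as.logical(cur$is_decoy))),
            class = "filter_report")
}

# Sequon validity per PSM row: use an explicit sequon_ok column when
# present, otherwise validate against protein context, otherwise
# peptide-internal check. Non-glycosylated rows always pass.
sequon_ok_column <- function(psms, protein_db = NULL) {
  n <- nrow(psms)
  if (!n) return(logical(0))
  if ("sequon_ok" %in% names(psms)) {
    ok <- as.logical(psms$sequon_ok)
    ok[psms$n_glycosites == 0L] <- TRUE
    return(ok)
  }
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (is.na(psms$n_glycosites[i]) || psms$n_glycosites[i] < 1L) next
    pos <- psms$glycosite_position[i]
    if (is.null(pos) || is.na(pos)) { ok[i] <- FALSE; next }
    ctx <- NULL
    if (!is.null(protein_db) && psms$protein_accession[i] %in% names(protein_db)) {
      site <- if ("protein_site" %in% names(psms)) psms$protein_site[i] else NA
      if (!is.na(site))
        ctx <- list(sequence = protein_db[[psms$protein_accession[i]]],
                    site = site)
    }
    ok[i] <- if (is.null(ctx))
      validate_sequon(psms$peptide[i], pos)
    else
      validate_sequon(psms$peptide[i], pos,
                      protein_context = ctx$sequence,
                      protein_position = ctx$site)
  }
  ok
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter cascade report\n")
  print(x$steps, row.names = FALSE)
  cat(sprintf("glycopeptide FDR (pre-localization): %s\n",
              ifelse(is.na(x$glyco_fdr_estimate), "undefined",
                     sprintf("%.4f", x$glyco_fdr_estimate))))
  cat("decoys remaining:", x$decoys_remaining, "\n")
  invisible(x)
}

#' Glycopeptide-level FDR estimate
#'
#' Counts only glycosylated PSMs (at least one glycosite) and returns
#' decoy count over target count. Returns `NA` (undefined) when no
#' glycosylated target PSMs are present, and 0 when decoys are absent.
#'
#' @param psms PSM data.frame with `is_decoy` and `n_glycosites`.
#' @return Fraction, or `NA`.
#' @export
estimate_glyco_fdr <- function(psms) {
  glyco <- psms[psms$n_glycosites >= 1L, , drop = FALSE]
  n_tgt <- sum(!as.logical(glyco$is_decoy))
  n_dec <- sum(as.logical(glyco$is_decoy))
  if (n_tgt == 0L) return(NA_real_)
  n_dec / n_tgt
}

#' Validate the N-glycosylation sequon
#'
#' True iff the asparagine at `position` sits in an N-X-S/T sequon with
#' X any residue but proline. When the sequon spans the peptide
#' C-terminus, `protein_context` (the full protein sequence) and
#' `protein_position` (the site's protein coordinate) supply the missing
#' residues; without context a truncated sequon is invalid.
#'
#' @param peptide Peptide sequence.
#' @param position 1-based position of the N within `peptide`.
#' @param protein_context Optional protein sequence.
#' @param protein_position Optional 1-based protein coordinate of the
#'   same N.
#' @return Logical.
#' @examples
#' validate_sequon("TNSSF", 2)   # TRUE: N-S-S
#' validate_sequon("ANPTA", 2)   # FALSE: X is proline
#' @export
validate_sequon <- function(peptide, position, protein_context = NULL,
                            protein_position = NULL) {
  res <- strsplit(peptide, "")[[1L]]
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > length(res))
    stop("position out of range")
  if (res[position] != "N") return(FALSE)
  get_res <- function(offset) {
    p <- position + offset
    if (p <= length(res)) return(res[p])
    if (!is.null(protein_context) && !is.null(protein_position)) {
      pc <- strsplit(protein_context, "")[[1L]]
      pp <- as.integer(protein_position) + offset
      if (pp >= 1L && pp <= length(pc)) return(pc[pp])
    }
    NA_character_
  }
  x <- get_res(1L); st <- get_res(2L)
  if (is.na(x) || is.na(st)) return(FALSE)
  x != "P" && st %in% c("S", "T")
}

#' Build a focused protein database
#'
#' From a de-glycosylation search (asparagine deamidation marks formerly
#' glycosylated sites), retain the proteins identified with at least one
#' peptide carrying a deamidated N inside a valid N-X-S/T sequon.
#'
#' @param deglyco_psms data.frame with columns `protein_accession`,
#'   `peptide`, `deamidation_position` (1-based within the peptide; `NA`
#'   when the peptide has no deamidation). Optional `protein_site` gives
#'   the protein coordinate for C-terminal sequon completion.
#' @param fasta Named character vector of protein sequences (accession ->
#'   sequence), e.g. from [read_fasta()].
#' @return Named character vector: the retained subset of `fasta`, in
#'   `fasta` order.
#' @export
build_focused_database <- function(deglyco_psms, fasta) {
  if (!nrow(deglyco_psms)) return(fasta[0])
  keep_acc <- character(0)
  for (i in seq_len(nrow(deglyco_psms))) {
    acc <- deglyco_psms$protein_accession[i]
    pos <- deglyco_psms$deamidation_position[i]
    if (is.na(pos)) next
    if (!acc %in% names(fasta)) {
      warning("accession ", acc, " absent from FASTA; row ", i, " skipped")
      next
    }
    site <- if ("protein_site" %in% names(deglyco_psms))
      deglyco_psms$protein_site[i] else NULL
    ok <- validate_sequon(deglyco_psms$peptide[i], pos,
                          protein_context = fasta[[acc]],
                          protein_position = site)
    if (ok) keep_acc <- c(keep_acc, acc)
  }
  fasta[names(fasta) %in% keep_acc]
}
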