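# Readers and writers for the touched formats: FASTA, MGF peak lists,
# mzML (via mzR when installed), TSV tables and JSON summaries. Writers
# are atomic (temp file then rename) and emit deterministic column and
# row order so outputs diff cleanly.

# Write to a temp file in the target directory, then rename into place.
atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writer(tmp)
  file.rename(tmp, path)
  ok <- TRUE
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector accession -> sequence; the accession is
#'   the first whitespace-delimited token of the header.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- as.character(ss)
  names(out) <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  out
}

#' Write protein sequences to FASTA
#'
#' @param seqs Named character vector accession -> sequence.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  atomic_write(path, function(tmp) {
    ss <- Biostrings::AAStringSet(seqs)
    Biostrings::writeXStringSet(ss, tmp)
  })
}

#' Read spectra from an MGF peak list
#'
#' Parses BEGIN IONS/END IONS blocks honoring TITLE, PEPMASS, CHARGE and
#' peak lines. A block without PEPMASS is an error naming the spectrum
#' ordinal; a missing CHARGE is kept as `NA`.
#'
#' @param path MGF file.
#' @param scan_low,scan_high Scan range recorded on each [spectrum()].
#' @return List of [spectrum()] objects.
#' @export
read_mgf <- function(path, scan_low = 115, scan_high = 2000) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS")
  out <- vector("list", length(begins))
  for (k in seq_along(begins)) {
    block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    kv <- grepl("=", block, fixed = TRUE)
    keys <- sub("=.*$", "", block[kv])
    vals <- sub("^[^=]*=", "", block[kv])
    title <- if ("TITLE" %in% keys) vals[keys == "TITLE"][1L]
             else sprintf("spectrum_%d", k)
    if (!"PEPMASS" %in% keys)
      stop("MGF spectrum ", k, " lacks PEPMASS")
    pepmass <- as.numeric(strsplit(vals[keys == "PEPMASS"][1L], "\\s+")[[1L]][1L])
    charge <- NA_integer_
    if ("CHARGE" %in% keys) {
      cv <- vals[keys == "CHARGE"][1L]
      charge <- as.integer(sub("[+-]$", "", cv))
      if (grepl("-$", cv)) charge <- -charge
    }
    pk <- block[!kv]
    pk <- pk[nzchar(trimws(pk))]
    mz <- numeric(0); int <- numeric(0)
    if (length(pk)) {
      m <- do.call(rbind, strsplit(trimws(pk), "[ \t]+"))
      if (ncol(m) < 2L) stop("MGF spectrum ", k, ": malformed peak line")
      mz <- as.numeric(m[, 1L]); int <- as.numeric(m[, 2L])
      if (anyNA(mz) || anyNA(int))
        stop("MGF spectrum ", k, ": non-numeric peak values")
    }
    out[[k]] <- spectrum(spectrum_id = title, precursor_mz = pepmass,
                         precursor_charge = charge, mz = mz,
                         intensity = int, scan_low = scan_low,
                         scan_high = scan_high)
  }
  out
}

#' Write spectra to an MGF peak list
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output path.
#' @param digits m/z decimal places (default 6 so round trips preserve
#'   peaks to 1e-6 Th).
#' @export
write_mgf <- function(spectra, path, digits = 6) {
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    for (sp in spectra) {
      writeLines("BEGIN IONS", con)
      writeLines(paste0("TITLE=", sp$spectrum_id), con)
      writeLines(paste0("PEPMASS=", format(sp$precursor_mz, digits = 12)), con)
      if (!is.na(sp$precursor_charge))
        writeLines(sprintf("CHARGE=%d+", sp$precursor_charge), con)
      if (nrow(sp$peaks))
        writeLines(sprintf(paste0("%.", digits, "f %.4f"),
                           sp$peaks$mz, sp$peaks$intensity), con)
      writeLines("END IONS", con)
    }
  })
}

#' Read spectra from mzML
#'
#' Centroid spectra via the mzR parser (a Suggests dependency).
#'
#' @param path mzML file.
#' @param scan_low,scan_high Scan range recorded on each [spectrum()].
#' @return List of [spectrum()] objects.
#' @export
read_mzml <- function(path, scan_low = 115, scan_high = 2000) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the mzR package")
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  hdr <- mzR::header(h)
  out <- vector("list", nrow(hdr))
  for (i in seq_len(nrow(hdr))) {
    pk <- mzR::peaks(h, i)
    out[[i]] <- spectrum(
      spectrum_id = as.character(hdr$seqNum[i]),
      precursor_mz = hdr$precursorMZ[i],
      precursor_charge = as.integer(hdr$precursorCharge[i]),
      mz = pk[, 1L], intensity = pk[, 2L],
      scan_low = scan_low, scan_high = scan_high)
  }
  out
}

#' Read peak lists from MGF or mzML
#'
#' Dispatches on the file extension.
#'
#' @param path Peak-list file (`.mgf`, `.mzml`).
#' @param ... Passed to the format reader.
#' @return List of [spectrum()] objects.
#' @export
read_peaklists <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         mgf = read_mgf(path, ...),
         mzml = read_mzml(path, ...),
         stop("unsupported peak-list format: .", ext))
}

#' Write a data.frame as TSV (atomic, deterministic)
#'
#' @param df data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  atomic_write(path, function(tmp)
    utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ""))
}

#' Read a TSV into a data.frame
#'
#' @param path Input path.
#' @return data.frame (headers required; strings kept as character).
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a PSM table TSV
#'
#' Column order is free but the header must include the PSM fields used
#' by the filter cascade; `is_decoy` accepts logicals or 0/1. When the
#' column is absent, decoy status falls back to the `rev_` accession
#' prefix heuristic (with a warning).
#'
#' @param path TSV file.
#' @param decoy_prefix Accession prefix for the fallback heuristic.
#' @return PSM data.frame.
#' @export
read_psm_table <- function(path, decoy_prefix = "rev_") {
  psms <- read_tsv(path)
  if (!"is_decoy" %in% names(psms)) {
    warning("no is_decoy column; inferring decoys from the ",
            sQuote(decoy_prefix), " accession prefix")
    psms$is_decoy <- startsWith(psms$protein_accession, decoy_prefix)
  } else {
    psms$is_decoy <- as.logical(psms$is_decoy)
  }
  psms
}

#' Write a list as pretty JSON (atomic)
#'
#' @param x List to serialize.
#' @param path Output path.
#' @export
write_json_atomic <- function(x, path) {
  atomic_write(path, function(tmp)
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA))
}

#' Write a filter report as JSON plus a human-readable log
#'
#' @param report A `filter_report`.
#' @param json_path JSON output path.
#' @param log_path Optional plain-text log path.
#' @export
write_filter_report <- function(report, json_path, log_path = NULL) {
  write_json_atomic(list(steps = report$steps,
                         glyco_fdr_estimate = report$glyco_fdr_estimate,
                         glyco_fdr_final = report$glyco_fdr_final,
                         decoys_remaining = report$decoys_remaining,
                         n_survivors = nrow(report$survivors)),
                    json_path)
  if (!is.null(log_path)) {
    atomic_write(log_path, function(tmp) {
      con <- file(tmp, "w"); on.exit(close(con))
      sink(con); print(report); sink()
    })
  }
  invisible(json_path)
}

#' Summarize a glycosite table as JSON-ready counts
#'
#' @param site_table A [build_site_table()] result.
#' @return List of unique glycopeptide/glycosite/glycoprotein/glycan/PSM
#'   counts plus the glycans-per-site and sites-per-protein histograms.
#' @export
summarize_site_table <- function(site_table) {
  counts <- attr(site_table, "counts")
  list(counts = as.list(counts),
       glycans_per_site = as.list(attr(site_table, "glycans_per_site")),
       sites_per_protein = as.list(attr(site_table, "sites_per_protein")))
}
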