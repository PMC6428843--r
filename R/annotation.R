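# Spectrum annotation: matching theoretical fragments to observed peaks
# and computing spectrum-level quality metrics (backbone and glycan
# coverage, explained ion current by fragment class) and diagnostic
# oxonium-ion intensity ratios.

#' Construct a centroid MS/MS spectrum
#'
#' @param spectrum_id Identifier string.
#' @param precursor_mz Precursor m/z (Th).
#' @param precursor_charge Integer charge; `NA` when unknown.
#' @param mz,intensity Numeric peak vectors of equal length; peaks are
#'   stored sorted by m/z.
#' @param scan_low,scan_high Acquisition m/z range (Th); peaks below
#'   `scan_low` are never matched.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(spectrum_id, precursor_mz = NA_real_,
                     precursor_charge = NA_integer_,
                     mz = numeric(0), intensity = numeric(0),
                     scan_low = 115, scan_high = 2000) {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  if (scan_low >= scan_high) stop("scan_low must be < scan_high")
  o <- order(mz)
  structure(list(spectrum_id = as.character(spectrum_id),
                 precursor_mz = precursor_mz,
                 precursor_charge = precursor_charge,
                 peaks = data.frame(mz = mz[o], intensity = intensity[o]),
                 scan_low = scan_low, scan_high = scan_high),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat("spectrum ", x$spectrum_id, ": ", nrow(x$peaks), " peaks, precursor ",
      round(x$precursor_mz, 4), " Th (z=", x$precursor_charge, ")\n", sep = "")
  invisible(x)
}

PEAK_CLASSES <- c("backbone_plain", "backbone_intact_glycan", "backbone_stub",
                  "Y", "oxonium")

# Fragment class for EIC accounting, from the fragment-table row.
fragment_class <- function(series, retention) {
  ifelse(series == "B", "oxonium",
  ifelse(series == "Y", "Y",
  ifelse(retention == "intact", "backbone_intact_glycan",
  ifelse(retention == "stub", "backbone_stub", "backbone_plain"))))
}

#' Match theoretical fragments to observed peaks
#'
#' Each theoretical ion is matched to the nearest peak (smallest |ppm|
#' error) within `tol_ppm`; peaks below the spectrum's `scan_low` are
#' excluded from matching. Each observed peak then receives at most one
#' class under the priority backbone_plain > backbone_intact_glycan >
#' backbone_stub > Y > oxonium, so no peak is double-counted in the
#' explained-ion-current partition.
#'
#' @param spec A [spectrum()].
#' @param theoretical Fragment data.frame from the fragment generators.
#' @param tol_ppm Matching tolerance in ppm (default 20, the usual
#'   product-ion tolerance).
#' @return An object of class `annotation_result`: list with `matches`
#'   (data.frame: theoretical row, `peak`, `ppm_error`, `class`),
#'   `class_of_peak` (character vector, one entry per peak, `"unmatched"`
#'   when nothing matched), plus the explained-ion-current summary from
#'   [explained_ion_current()]. Coverage fields are filled by
#'   [annotate_spectrum()].
#' @export
match_peaks <- function(spec, theoretical, tol_ppm = 20) {
  stopifnot(inherits(spec, "spectrum"))
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")
  if (is.null(theoretical) || nrow(theoretical) == 0L)
    stop("theoretical fragment table must be nonempty")
  pk <- spec$peaks
  npk <- nrow(pk)
  cls <- fragment_class(theoretical$series, theoretical$retention)

  matches <- data.frame(series = character(0), index = integer(0),
                        retention = character(0), charge = integer(0),
                        theo_mz = numeric(0), peak = integer(0),
                        ppm_error = numeric(0), class = character(0),
                        composition_retained = character(0),
                        stringsAsFactors = FALSE)
  class_of_peak <- rep("unmatched", npk)

  if (npk > 0L) {
    eligible <- which(pk$mz >= spec$scan_low)
    if (length(eligible)) {
      emz <- pk$mz[eligible]
      hit_rows <- vector("list", 0L)
      for (i in seq_len(nrow(theoretical))) {
        tmz <- theoretical$mz[i]
        j <- findInterval(tmz, emz)
        cand <- unique(pmin(pmax(c(j, j + 1L), 1L), length(emz)))
        ppm <- (emz[cand] - tmz) / tmz * 1e6
        k <- which.min(abs(ppm))
        if (abs(ppm[k]) <= tol_ppm) {
          hit_rows[[length(hit_rows) + 1L]] <- data.frame(
            series = theoretical$series[i], index = theoretical$index[i],
            retention = theoretical$retention[i],
            charge = theoretical$charge[i], theo_mz = tmz,
            peak = eligible[cand[k]], ppm_error = ppm[k], class = cls[i],
            composition_retained = theoretical$composition_retained[i],
            stringsAsFactors = FALSE)
        }
      }
      if (length(hit_rows)) matches <- do.call(rbind, hit_rows)
      # one class per peak, by priority
      for (p in unique(matches$peak)) {
        pc <- matches$class[matches$peak == p]
        class_of_peak[p] <- PEAK_CLASSES[min(match(pc, PEAK_CLASSES))]
      }
    }
  }

  res <- structure(list(spectrum_id = spec$spectrum_id,
                        matches = matches,
                        class_of_peak = class_of_peak,
                        peaks = pk,
                        tol_ppm = tol_ppm,
                        backbone_coverage_pct = NA_real_,
                        glycan_coverage_pct = NA_real_,
                        eic_fractions = NULL,
                        explained_fraction_of_total = NA_real_),
                   class = "annotation_result")
  eic <- explained_ion_current(res)
  res$eic_fractions <- eic$eic_fractions
  res$explained_fraction_of_total <- eic$explained_fraction_of_total
  res
}

#' Backbone and glycan coverage of an annotated spectrum
#'
#' Backbone coverage is the percentage of the L-1 inter-residue bonds
#' evidenced by at least one matched b/y/c/z ion of any retention mode or
#' charge. Glycan coverage is the percentage of possible Y-ladder depths
#' observed: the number of distinct retained-residue counts among matched
#' Y ions (counting Y0) relative to the glycan's total residue count.
#'
#' @param res An `annotation_result` computed against `gp`'s fragments.
#' @param gp The [glycopeptide()] that was annotated.
#' @return Named numeric vector `c(backbone = %, glycan = %)`.
#' @export
coverage_metrics <- function(res, gp) {
  stopifnot(inherits(res, "annotation_result"), inherits(gp, "glycopeptide"))
  L <- length(gp$residues)
  m <- res$matches
  bb <- m[m$series %in% c("b", "y", "c", "z"), , drop = FALSE]
  bonds <- integer(0)
  if (nrow(bb)) {
    bonds <- ifelse(bb$series %in% c("b", "c"), bb$index, L - bb$index)
    bonds <- unique(bonds)
  }
  backbone <- if (L > 1L) 100 * length(bonds) / (L - 1L) else 0
  nres <- composition_size(gp$glycan)
  glycan <- 0
  if (nres > 0L) {
    ym <- m[m$series == "Y", , drop = FALSE]
    glycan <- 100 * length(unique(ym$index)) / nres
  }
  c(backbone = backbone, glycan = glycan)
}

#' Explained ion current by fragment class
#'
#' Partitions matched intensity over the five fragment classes (plain
#' backbone, backbone with intact glycan, backbone with HexNAc stub,
#' Y ions, B/oxonium ions). Fractions are relative to total matched
#' intensity and sum to 1 whenever at least one peak matched;
#' `explained_fraction_of_total` is matched intensity over all peak
#' intensity.
#'
#' @param res An `annotation_result`.
#' @return List with `eic_fractions` (named numeric over the five
#'   classes) and `explained_fraction_of_total`.
#' @export
explained_ion_current <- function(res) {
  stopifnot(inherits(res, "annotation_result"))
  int <- res$peaks$intensity
  cls <- res$class_of_peak
  matched <- cls != "unmatched"
  tot_matched <- sum(int[matched])
  tot_all <- sum(int)
  fr <- stats::setNames(numeric(length(PEAK_CLASSES)), PEAK_CLASSES)
  if (tot_matched > 0) {
    for (cl in PEAK_CLASSES) fr[cl] <- sum(int[matched & cls == cl]) / tot_matched
  }
  list(eic_fractions = fr,
       explained_fraction_of_total = if (tot_all > 0) tot_matched / tot_all else 0)
}

#' Annotate a spectrum against a glycopeptide
#'
#' End-to-end convenience: generates the theoretical fragment set, runs
#' [match_peaks()], and fills in [coverage_metrics()].
#'
#' @param spec A [spectrum()].
#' @param gp A [glycopeptide()].
#' @param tol_ppm Product-ion tolerance (ppm).
#' @param max_charge,series,retention Passed to the fragment generators.
#' @return A complete `annotation_result`.
#' @export
annotate_spectrum <- function(spec, gp, tol_ppm = 20, max_charge = 2L,
                              series = c("c", "z"),
                              retention = c("intact", "none")) {
  theo <- glycopeptide_fragments(gp, max_charge = max_charge,
                                 series = series, retention = retention)
  res <- match_peaks(spec, theo, tol_ppm = tol_ppm)
  cov <- coverage_metrics(res, gp)
  res$backbone_coverage_pct <- cov[["backbone"]]
  res$glycan_coverage_pct <- cov[["glycan"]]
  res
}

#' @export
print.annotation_result <- function(x, ...) {
  cat("annotation of ", x$spectrum_id, ": ", nrow(x$matches),
      " matched ions\n", sep = "")
  if (!is.na(x$backbone_coverage_pct))
    cat(sprintf("  backbone coverage: %.1f%%  glycan coverage: %.1f%%\n",
                x$backbone_coverage_pct, x$glycan_coverage_pct))
  cat(sprintf("  explained fraction of total ion current: %.3f\n",
              x$explained_fraction_of_total))
  invisible(x)
}

# Summed intensity of peaks matching any target m/z within tol_ppm,
# honoring the scan_low floor.
sum_ion_intensity <- function(spec, mz_set, tol_ppm) {
  pk <- spec$peaks
  keep <- pk$mz >= spec$scan_low
  tot <- 0
  for (tmz in mz_set) {
    sel <- keep & abs(pk$mz - tmz) / tmz * 1e6 <= tol_ppm
    tot <- tot + sum(pk$intensity[sel])
  }
  tot
}

#' Diagnostic intensity ratio between two ion sets
#'
#' Sums observed intensity over the numerator and denominator m/z sets
#' (within `tol_ppm`) and returns their ratio. Returns 0 when the
#' numerator is absent but the denominator present, and `NA` (undefined)
#' when the denominator sum is zero.
#'
#' @param spec A [spectrum()].
#' @param numerator_mz,denominator_mz Nonempty numeric m/z sets.
#' @param tol_ppm Tolerance in ppm.
#' @return A single numeric; `NA` flags an undefined ratio.
#' @export
intensity_ratio <- function(spec, numerator_mz, denominator_mz, tol_ppm = 20) {
  stopifnot(inherits(spec, "spectrum"))
  if (!length(numerator_mz) || !length(denominator_mz))
    stop("both ion sets must be nonempty")
  num <- sum_ion_intensity(spec, numerator_mz, tol_ppm)
  den <- sum_ion_intensity(spec, denominator_mz, tol_ppm)
  if (den == 0) return(NA_real_)
  num / den
}

#' Diagnostic ion m/z values
#'
#' Singly protonated m/z of the HexNAc oxonium ion (~204.0867 Th) and the
#' NeuAc water-loss oxonium ion (~274.0921 Th), computed from the residue
#' mass table.
#'
#' @return Named numeric vector `c(hexnac_oxonium, neuac_h2o_oxonium)`.
#' @export
diagnostic_ion_mz <- function() {
  c(hexnac_oxonium = MONOSACCHARIDES[["HexNAc"]] + MASS_CONST[["proton"]],
    neuac_h2o_oxonium = MONOSACCHARIDES[["NeuAc"]] + MASS_CONST[["proton"]] -
      MASS_CONST[["water"]])
}

#' Default GlcNAc/GalNAc diagnostic ion sets
#'
#' Shipped defaults for the HexNAc-isomer intensity ratio: numerator ions
#' at m/z 126.0550 and 138.0550, denominator ions at 144.0655 and
#' 168.0655. The ion sets are configuration (they derive from prior
#' fragmentation work on HexNAc oxonium sub-fragments), while the
#' decision thresholds live in [classify_hexnac_isomer()].
#'
#' @return List with numeric elements `numerator` and `denominator`.
#' @export
glcnac_galnac_ions <- function() {
  list(numerator = c(126.0550, 138.0550),
       denominator = c(144.0655, 168.0655))
}

#' Classify the HexNAc isomer from a GlcNAc/GalNAc ratio
#'
#' A ratio below 1 indicates GalNAc, a ratio above 2 indicates GlcNAc;
#' ratios in \[1, 2\] (or an undefined ratio) are ambiguous.
#'
#' @param ratio Numeric ratio (may be `NA`).
#' @return One of `"GalNAc"`, `"GlcNAc"`, `"ambiguous"`.
#' @export
classify_hexnac_isomer <- function(ratio) {
  if (length(ratio) != 1L) stop("ratio must be a single value")
  if (is.na(ratio)) return("ambiguous")
  if (ratio < 0) stop("ratio must be >= 0")
  if (ratio < 1) "GalNAc" else if (ratio > 2) "GlcNAc" else "ambiguous"
}

#' Flag likely sialylation from the Neu5Ac/HexNAc oxonium ratio
#'
#' Computes the intensity ratio of the NeuAc water-loss ion (~274.0921)
#' to the HexNAc oxonium ion (~204.0867) and flags the spectrum as
#' sialylated when the ratio strictly exceeds `threshold` (default 0.1).
#' An undefined ratio (no HexNAc oxonium signal) yields `FALSE`.
#'
#' @param spec A [spectrum()].
#' @param tol_ppm Tolerance in ppm.
#' @param threshold Strict decision threshold.
#' @return Logical flag.
#' @export
flag_sialylation <- function(spec, tol_ppm = 20, threshold = 0.1) {
  ions <- diagnostic_ion_mz()
  r <- intensity_ratio(spec, ions[["neuac_h2o_oxonium"]],
                       ions[["hexnac_oxonium"]], tol_ppm = tol_ppm)
  !is.na(r) && r > threshold
}
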