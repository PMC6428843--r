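# Seeded synthetic-data generators. They emit every input the pipeline
# consumes (protein FASTA, annotation tables, glycosite assignments, PSM
# tables with targets and decoys, MS/MS peak lists) together with ground
# truth, so that every downstream metric can be checked against a known
# answer. All draws come from stage-specific streams derived from the
# master seed, so each stage is reproducible on its own.

#' Simulation configuration
#'
#' Parameters of the synthetic glycoproteomics study. Defaults emulate a
#' lectin-enriched brain-tissue experiment at desk scale: tens of
#' glycoproteins, roughly 60% of glycosites carrying more than one
#' glycan (truncated-geometric microheterogeneity with continuation
#' probability 0.6), a few PSMs per site-glycan pair, well-separated
#' target and null score distributions with a 10% false-target
#' contamination, fragment detection probability 0.7 and 5 ppm m/z
#' jitter (a quarter of the 20 ppm matching tolerance).
#'
#' @param seed Master seed (integer).
#' @param n_proteins Number of synthetic proteins.
#' @param protein_length Residue count per protein.
#' @param sequons_per_protein Planted N-X-S/T sequons per protein.
#' @param domain_catalog Domain label pool.
#' @param domain_length Span length of planted domains.
#' @param domains_per_protein Domains planted per protein.
#' @param cc_catalog GO cellular-component term pool.
#' @param cc_extra_prob Probability of each additional CC term beyond the
#'   first (multi-label membership).
#' @param glycan_db Glycan database data.frame ([load_glycan_database()]).
#' @param site_occupancy Probability a planted sequon is observed
#'   glycosylated.
#' @param glycans_per_site_theta Continuation probability of the
#'   truncated geometric glycans-per-site distribution.
#' @param max_glycans_per_site Truncation point.
#' @param psm_lambda Poisson mean of extra PSMs per site-glycan pair
#'   (count is 1 + Poisson).
#' @param target_score_mean,target_score_sd Ranking-score distribution of
#'   correct identifications.
#' @param null_score_mean,null_score_sd Ranking-score distribution of
#'   decoys and false targets.
#' @param incorrect_target_fraction Fraction of target PSMs that are
#'   false (scored from the null distribution); the decoy set has the
#'   same expected size.
#' @param violators Named integer vector planting rows that each fail
#'   exactly one cascade step (names among `byonic_score`,
#'   `peptide_length`, `log_prob`, `single_site`, `delta_mod`).
#' @param detection_p Per-fragment detection probability in simulated
#'   spectra.
#' @param ppm_sigma Gaussian m/z jitter (ppm).
#' @param n_noise_peaks Uniform random noise peaks per spectrum.
#' @param scan_low,scan_high Simulated scan range (Th).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_proteins = 40L,
                              protein_length = 400L,
                              sequons_per_protein = 3L,
                              domain_catalog = c("Ig-like",
                                                 "Fibronectin type-III",
                                                 "EGF-like", "Cadherin",
                                                 "Sushi", "Lectin C-type",
                                                 "Laminin EGF-like",
                                                 "PDZ"),
                              domain_length = 60L,
                              domains_per_protein = 3L,
                              cc_catalog = default_cc_catalog(),
                              cc_extra_prob = 0.4,
                              glycan_db = load_glycan_database(),
                              site_occupancy = 0.85,
                              glycans_per_site_theta = 0.6,
                              max_glycans_per_site = 10L,
                              psm_lambda = 2.5,
                              target_score_mean = 300,
                              target_score_sd = 80,
                              null_score_mean = 150,
                              null_score_sd = 50,
                              incorrect_target_fraction = 0.1,
                              violators = c(byonic_score = 0L,
                                            peptide_length = 0L,
                                            log_prob = 0L,
                                            single_site = 0L,
                                            delta_mod = 0L),
                              detection_p = 0.7,
                              ppm_sigma = 5,
                              n_noise_peaks = 30L,
                              scan_low = 115, scan_high = 2000) {
  cfg <- as.list(environment())
  probs <- c(site_occupancy, glycans_per_site_theta, detection_p,
             cc_extra_prob, incorrect_target_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (3L * sequons_per_protein > protein_length %/% 2L)
    stop("sequon density infeasible for the protein length")
  cfg$seed <- as.integer(seed)
  class(cfg) <- "simulation_config"
  cfg
}

#' Default GO cellular-component term pool
#'
#' Term strings chosen to exercise every collapsing rule.
#'
#' @return Character vector of GO CC term names.
#' @export
default_cc_catalog <- function() {
  c("plasma membrane", "integral component of membrane", "axon",
    "neuronal cell body", "myelin sheath", "Golgi apparatus",
    "Golgi membrane", "endoplasmic reticulum",
    "endoplasmic reticulum-Golgi intermediate compartment",
    "cell surface", "lysosome", "lysosomal membrane", "synaptic vesicle",
    "synapse", "extracellular space", "extracellular exosome",
    "secreted", "cytoplasm", "nucleus", "mitochondrion")
}

# Stage-specific seed, kept below 2^31.
stage_seed <- function(cfg, stage) {
  (abs(cfg$seed) %% 2000000000L) + stage
}

#' Generate a synthetic glycoproteome
#'
#' Random protein sequences with planted N-X-S/T sequons (X != P),
#' domain spans, and GO cellular-component term lists. Deterministic
#' under the configuration seed.
#'
#' @param cfg A [simulation_config()].
#' @return List with `fasta` (named character vector accession ->
#'   sequence), `candidate_sites` (data.frame `protein_accession`,
#'   `site`), `domains` (data.frame `protein_accession`, `domain`,
#'   `start`, `end`), `cc_terms` (data.frame `protein_accession`,
#'   `go_cc_term`).
#' @export
generate_glycoproteome <- function(cfg = simulation_config()) {
  set.seed(stage_seed(cfg, 1L))
  aa <- names(AMINO_ACIDS)
  aa_bg <- setdiff(aa, "N")           # background; Ns only where planted
  L <- cfg$protein_length
  fasta <- character(cfg$n_proteins)
  acc <- sprintf("SYNP%04d", seq_len(cfg$n_proteins))
  names(fasta) <- acc
  sites <- vector("list", cfg$n_proteins)
  doms <- vector("list", cfg$n_proteins)
  ccs <- vector("list", cfg$n_proteins)
  for (i in seq_len(cfg$n_proteins)) {
    seqv <- sample(aa_bg, L, replace = TRUE)
    ns <- cfg$sequons_per_protein
    pos <- integer(0)
    if (ns > 0L) {
      # sequon anchors at least 3 residues apart and away from termini
      cand <- seq(5L, L - 5L)
      pos <- sort(sample(cand, ns))
      while (any(diff(pos) < 4L)) pos <- sort(sample(cand, ns))
      for (p in pos) {
        seqv[p] <- "N"
        seqv[p + 1L] <- sample(setdiff(aa_bg, "P"), 1L)
        seqv[p + 2L] <- sample(c("S", "T"), 1L)
      }
    }
    fasta[i] <- paste(seqv, collapse = "")
    sites[[i]] <- data.frame(protein_accession = rep(acc[i], length(pos)),
                             site = pos, stringsAsFactors = FALSE)
    nd <- cfg$domains_per_protein
    starts <- sort(sample(seq(1L, max(1L, L - cfg$domain_length)), nd))
    doms[[i]] <- data.frame(
      protein_accession = acc[i],
      domain = sample(cfg$domain_catalog, nd, replace = TRUE),
      start = starts, end = pmin(starts + cfg$domain_length - 1L, L),
      stringsAsFactors = FALSE)
    n_terms <- 1L + stats::rbinom(1L, 3L, cfg$cc_extra_prob)
    ccs[[i]] <- data.frame(
      protein_accession = acc[i],
      go_cc_term = sample(cfg$cc_catalog, min(n_terms, length(cfg$cc_catalog))),
      stringsAsFactors = FALSE)
  }
  list(fasta = fasta,
       candidate_sites = do.call(rbind, sites),
       domains = do.call(rbind, doms),
       cc_terms = do.call(rbind, ccs))
}

# k ~ truncated geometric on 1..kmax: P(k) proportional to theta^(k-1).
rtrunc_geom <- function(n, theta, kmax) {
  p <- theta^(0:(kmax - 1L))
  sample.int(kmax, n, replace = TRUE, prob = p / sum(p))
}

#' Generate site-glycan assignments with known truth
#'
#' Each candidate sequon is observed with probability `site_occupancy`;
#' occupied sites draw a glycan count from the truncated geometric
#' distribution and sample that many distinct glycans from the database.
#'
#' @param proteome Output of [generate_glycoproteome()].
#' @param cfg A [simulation_config()].
#' @return List with `assignments` (data.frame `protein_accession`,
#'   `site`, `glycan`) and `truth` (list: `k_per_site` named integer
#'   vector, `glycans_per_site_histogram`).
#' @export
generate_assignments <- function(proteome, cfg = simulation_config()) {
  set.seed(stage_seed(cfg, 2L))
  db_comps <- cfg$glycan_db$composition
  kmax <- min(cfg$max_glycans_per_site, length(db_comps))
  if (kmax < cfg$max_glycans_per_site)
    warning("glycans-per-site truncated to database size (", kmax, ")")
  cand <- proteome$candidate_sites
  rows <- vector("list", 0L)
  k_per_site <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (stats::runif(1L) > cfg$site_occupancy) next
    k <- rtrunc_geom(1L, cfg$glycans_per_site_theta, kmax)
    gl <- sample(db_comps, k)
    key <- paste(cand$protein_accession[i], cand$site[i])
    k_per_site[key] <- k
    rows[[length(rows) + 1L]] <- data.frame(
      protein_accession = cand$protein_accession[i],
      site = cand$site[i], glycan = gl, stringsAsFactors = FALSE)
  }
  assignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_accession = character(0), site = integer(0),
               glycan = character(0))
  list(assignments = assignments,
       truth = list(k_per_site = k_per_site,
                    glycans_per_site_histogram = base::table(k_per_site)))
}

# Tryptic-looking peptide window around a protein site; returns the
# peptide string and the site's 1-based position within it.
peptide_window <- function(sequence, site, min_flank = 4L, max_flank = 9L) {
  res <- strsplit(sequence, "")[[1L]]
  lflank <- sample(min_flank:max_flank, 1L)
  rflank <- sample(min_flank:max_flank, 1L)
  from <- max(1L, site - lflank)
  to <- min(length(res), site + rflank)
  list(peptide = paste(res[from:to], collapse = ""),
       position = site - from + 1L)
}

#' Generate a synthetic PSM table with targets, decoys and violators
#'
#' Target rows are drawn from the true assignments with scores from the
#' target distribution; a configurable fraction of targets are false
#' (scores from the null distribution); decoy rows (accessions prefixed
#' `rev_`, `is_decoy = TRUE`) are drawn from the same null. Optional
#' violator rows each fail exactly one cascade step while passing all
#' others.
#'
#' @param proteome Output of [generate_glycoproteome()].
#' @param assign Output of [generate_assignments()].
#' @param cfg A [simulation_config()].
#' @return List with `psms` (data.frame in the PSM layout) and `truth`
#'   (data.frame: `spectrum_id`, `is_correct`, `violates` --
#'   `NA` for ordinary rows, otherwise the step the row was planted to
#'   fail).
#' @export
generate_psm_table <- function(proteome, assign, cfg = simulation_config()) {
  set.seed(stage_seed(cfg, 3L))
  A <- assign$assignments
  rows <- vector("list", 0L)
  truth <- vector("list", 0L)
  sid <- 0L
  draw_target <- function() stats::rnorm(1L, cfg$target_score_mean,
                                         cfg$target_score_sd)
  draw_null <- function() stats::rnorm(1L, cfg$null_score_mean,
                                       cfg$null_score_sd)
  mk_row <- function(acc, peptide, pos, prot_site, glycan, decoy, correct,
                     score, byonic = NULL, log_prob = NULL,
                     delta_mod = NULL, n_sites = 1L, pep_len_ok = TRUE) {
    sid <<- sid + 1L
    id <- sprintf("scan_%05d", sid)
    gp_mass <- peptide_mass(peptide) +
      composition_mass(parse_composition(glycan))
    z <- sample(2:4, 1L)
    rows[[length(rows) + 1L]] <<- data.frame(
      spectrum_id = id, peptide = peptide, protein_accession = acc,
      is_decoy = decoy, glycosite_position = pos, protein_site = prot_site,
      glycan = glycan, n_glycosites = n_sites,
      byonic_score = byonic %||% max(0, score + stats::rnorm(1L, 50, 20)),
      two_d_score = score,
      log_prob_abs = log_prob %||% (if (correct) 1 + abs(stats::rnorm(1L, 2, 1))
                                    else abs(stats::rnorm(1L, 0.8, 0.5))),
      delta_mod = delta_mod %||% (if (correct) abs(stats::rnorm(1L, 30, 10))
                                  else abs(stats::rnorm(1L, 6, 4))),
      precursor_mz = (gp_mass + z * MASS_CONST[["proton"]]) / z,
      charge = z,
      dissociation = sample(c("AI-ETD", "HCD"), 1L),
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <<- data.frame(
      spectrum_id = id, is_correct = correct, violates = NA_character_,
      stringsAsFactors = FALSE)
    id
  }

  n_target_psms <- 0L
  for (i in seq_len(nrow(A))) {
    n_psm <- 1L + stats::rpois(1L, cfg$psm_lambda)
    acc <- A$protein_accession[i]
    for (r in seq_len(n_psm)) {
      pw <- peptide_window(proteome$fasta[[acc]], A$site[i])
      mk_row(acc, pw$peptide, pw$position, A$site[i], A$glycan[i],
             decoy = FALSE, correct = TRUE, score = draw_target())
      n_target_psms <- n_target_psms + 1L
    }
  }
  # false targets and an equally sized decoy set, both from the null
  n_false <- stats::rbinom(1L, n_target_psms, cfg$incorrect_target_fraction)
  pick_site <- function() {
    i <- sample.int(max(1L, nrow(A)), 1L)
    acc <- A$protein_accession[i]
    pw <- peptide_window(proteome$fasta[[acc]], A$site[i])
    list(acc = acc, pw = pw, site = A$site[i], glycan = A$glycan[i])
  }
  if (nrow(A)) {
    for (r in seq_len(n_false)) {
      s <- pick_site()
      mk_row(s$acc, s$pw$peptide, s$pw$position, s$site, s$glycan,
             decoy = FALSE, correct = FALSE, score = draw_null())
    }
    for (r in seq_len(n_false)) {
      s <- pick_site()
      mk_row(paste0("rev_", s$acc), s$pw$peptide, s$pw$position, s$site,
             s$glycan, decoy = TRUE, correct = FALSE, score = draw_null())
    }
    # planted violators: pass everything except one named step
    viol <- cfg$violators
    for (step in names(viol)) {
      for (r in seq_len(viol[[step]])) {
        s <- pick_site()
        args <- list(acc = s$acc, peptide = s$pw$peptide,
                     pos = s$pw$position, prot_site = s$site,
                     glycan = s$glycan, decoy = FALSE, correct = TRUE,
                     score = cfg$target_score_mean + 3 * cfg$target_score_sd)
        if (step == "byonic_score") args$byonic <- 149
        if (step == "peptide_length") {
          res <- strsplit(s$pw$peptide, "")[[1L]]
          npos <- which(res == "N")[1L]
          from <- max(1L, npos - 1L); to <- min(length(res), from + 3L)
          args$peptide <- paste(res[from:to], collapse = "")
          args$pos <- npos - from + 1L
        }
        if (step == "log_prob") args$log_prob <- 0.5
        if (step == "single_site") args$n_sites <- 2L
        if (step == "delta_mod") args$delta_mod <- 5
        id <- do.call(mk_row, args)
        truth[[length(truth)]]$violates <- step
      }
    }
  }
  psms <- do.call(rbind, rows)
  list(psms = psms, truth = do.call(rbind, truth))
}

#' Simulate an MS/MS spectrum of a glycopeptide
#'
#' Plants each theoretical fragment independently with probability
#' `detection_p`, jitters m/z with Gaussian ppm noise, draws per-class
#' log-normal intensities (backbone fragments brightest, then Y ions,
#' then oxonium ions -- arbitrary units, only ratios matter downstream),
#' and adds uniform random noise peaks across the scan range.
#'
#' @param gp A [glycopeptide()].
#' @param cfg A [simulation_config()].
#' @param fragments Theoretical fragment table; defaults to the full
#'   c/z + Y + oxonium set at charges 1..2.
#' @param seed Optional seed overriding the configuration stream (used
#'   when simulating many spectra from one configuration).
#' @return List with `spectrum` (a [spectrum()]) and `planted` (the
#'   retained theoretical rows).
#' @export
generate_spectrum <- function(gp, cfg = simulation_config(),
                              fragments = NULL, seed = NULL) {
  if (is.null(seed)) seed <- stage_seed(cfg, 4L)
  set.seed(seed)
  if (is.null(fragments))
    fragments <- glycopeptide_fragments(gp, max_charge = 2L)
  keep <- stats::runif(nrow(fragments)) <= cfg$detection_p
  planted <- fragments[keep, , drop = FALSE]
  meanlog <- c(backbone_plain = 11, backbone_intact_glycan = 11,
               backbone_stub = 10.5, Y = 10, oxonium = 11.5)
  cls <- fragment_class(planted$series, planted$retention)
  mz <- planted$mz * (1 + stats::rnorm(nrow(planted), 0, cfg$ppm_sigma) * 1e-6)
  intensity <- stats::rlnorm(nrow(planted), meanlog[cls], 0.6)
  if (cfg$n_noise_peaks > 0L) {
    mz <- c(mz, stats::runif(cfg$n_noise_peaks, cfg$scan_low, cfg$scan_high))
    intensity <- c(intensity,
                   stats::rlnorm(cfg$n_noise_peaks, 8, 0.8))
  }
  sp <- spectrum(spectrum_id = paste0("sim_", gp$sequence),
                 precursor_mz = precursor_mz(gp, 3L), precursor_charge = 3L,
                 mz = mz, intensity = intensity,
                 scan_low = cfg$scan_low, scan_high = cfg$scan_high)
  list(spectrum = sp, planted = planted)
}

#' Run the full synthetic study
#'
#' Chains [generate_glycoproteome()], [generate_assignments()] and
#' [generate_psm_table()]; optionally writes every emitted file (FASTA,
#' annotation TSVs, PSM TSV, truth JSON) to a directory in the formats
#' the pipeline reads.
#'
#' @param cfg A [simulation_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return List with `proteome`, `assignments`, `psms`, `truth`.
#' @export
simulate_dataset <- function(cfg = simulation_config(), out_dir = NULL) {
  proteome <- generate_glycoproteome(cfg)
  assign <- generate_assignments(proteome, cfg)
  psm <- generate_psm_table(proteome, assign, cfg)
  out <- list(proteome = proteome, assignments = assign$assignments,
              psms = psm$psms,
              truth = list(sites = assign$truth, psms = psm$truth))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(proteome$fasta, file.path(out_dir, "proteome.fasta"))
    write_tsv(proteome$cc_terms, file.path(out_dir, "cc_terms.tsv"))
    write_tsv(proteome$domains, file.path(out_dir, "domains.tsv"))
    write_tsv(assign$assignments, file.path(out_dir, "assignments.tsv"))
    write_tsv(psm$psms, file.path(out_dir, "psms.tsv"))
    write_json_atomic(list(glycans_per_site =
                             as.list(assign$truth$k_per_site),
                           psm_truth = psm$truth),
                      file.path(out_dir, "truth.json"))
  }
  out
}
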