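# Target-decoy q-values, the six-step filter cascade, glycopeptide FDR,
# sequon validation and focused-database construction.

psm_row <- function(id, score = 300, decoy = FALSE, peptide = "TNSSFIQGK",
                    byonic = 300, log_prob = 2, n_sites = 1L,
                    delta_mod = 25, glycan = "HexNAc(2)Hex(5)",
                    pos = 2L) {
  data.frame(spectrum_id = id, peptide = peptide,
             protein_accession = if (decoy) "rev_P1" else "P1",
             is_decoy = decoy, glycosite_position = pos,
             glycan = glycan, n_glycosites = n_sites,
             byonic_score = byonic, two_d_score = score,
             log_prob_abs = log_prob, delta_mod = delta_mod,
             precursor_mz = 1000, charge = 3L, dissociation = "AI-ETD",
             stringsAsFactors = FALSE)
}

test_that("q-values follow the decoy/target counting rule", {
  psms <- rbind(psm_row("t1", 300), psm_row("t2", 250), psm_row("t3", 200),
                psm_row("d1", 220, decoy = TRUE))
  out <- compute_qvalues(psms)
  q <- setNames(out$q_value, out$spectrum_id)
  expect_equal(unname(q["t1"]), 0)
  expect_equal(unname(q["t2"]), 0)
  expect_equal(unname(q["t3"]), 1 / 3)
})

test_that("all-decoy input is rejected; decoy-free input warns with q = 0", {
  expect_error(compute_qvalues(rbind(psm_row("d1", decoy = TRUE))),
               "no target")
  expect_warning(out <- compute_qvalues(rbind(psm_row("t1"), psm_row("t2"))),
                 "no decoy")
  expect_equal(out$q_value, c(0, 0))
})

test_that("tied target and decoy scores share a q-value", {
  psms <- rbind(psm_row("t1", 300), psm_row("t2", 250),
                psm_row("d1", 250, decoy = TRUE), psm_row("t3", 250),
                psm_row("t4", 100))
  out <- compute_qvalues(psms)
  q <- setNames(out$q_value, out$spectrum_id)
  expect_equal(unname(q["t2"]), unname(q["t3"]))
  expect_equal(unname(q["t2"]), unname(q["d1"]))
})

test_that("q-values agree with a brute-force double-loop oracle", {
  set.seed(101)
  for (rep in 1:20) {
    n <- 60
    decoy <- runif(n) < 0.3
    score <- round(ifelse(decoy, rnorm(n, 150, 50), rnorm(n, 250, 80)), 1)
    if (all(decoy)) decoy[1] <- FALSE
    psms <- do.call(rbind, lapply(seq_len(n), function(i)
      psm_row(paste0("s", i), score[i], decoy = decoy[i])))
    out <- compute_qvalues(psms)
    expect_equal(out$q_value, oracle_qvalues(score, decoy), tolerance = 1e-12)
  }
})

test_that("single threshold violations are removed at the documented step", {
  base <- rbind(psm_row("ok", 400))
  low_score <- psm_row("b149", 400, byonic = 149)
  short_pep <- psm_row("len4", 400, peptide = "GNGT", pos = 2L)
  low_prob <- psm_row("lp", 400, log_prob = 0.5)
  two_sites <- psm_row("ns2", 400, n_sites = 2L)
  low_dmod <- psm_row("dm", 400, delta_mod = 5)
  psms <- rbind(base, low_score, short_pep, low_prob, two_sites, low_dmod,
                psm_row("d", 100, decoy = TRUE))
  rep <- apply_filter_cascade(psms, filter_config(require_sequon = FALSE))
  st <- rep$steps
  expect_equal(st$n_removed[st$step == "psm_fdr"], 1L)       # the decoy
  expect_equal(st$n_removed[st$step == "byonic_score"], 1L)
  expect_equal(st$n_removed[st$step == "peptide_length"], 1L)
  expect_equal(st$n_removed[st$step == "log_prob"], 1L)
  expect_equal(st$n_removed[st$step == "single_site"], 1L)
  expect_equal(st$n_removed[st$step == "delta_mod"], 1L)
  expect_identical(rep$survivors$spectrum_id, "ok")
  # counts telescope
  expect_equal(st$n_in - st$n_removed, st$n_out)
  expect_equal(st$n_in[-1], st$n_out[-nrow(st)])
})

test_that("a seeded 1000-row table filters to the independent recount", {
  cfg <- simulation_config(seed = 77, n_proteins = 28L,
                           sequons_per_protein = 4L, psm_lambda = 2.5,
                           violators = c(byonic_score = 5L,
                                         peptide_length = 4L, log_prob = 6L,
                                         single_site = 3L, delta_mod = 7L))
  sim <- simulate_dataset(cfg)
  psms <- sim$psms
  expect_gt(nrow(psms), 800)
  fc <- filter_config(require_sequon = FALSE)
  rep <- apply_filter_cascade(psms, fc)

  # independent recount: sequentially re-apply each predicate
  cur <- compute_qvalues(psms)
  preds <- list(
    psm_fdr = function(d) d$q_value <= 0.01,
    byonic_score = function(d) d$byonic_score >= 150,
    peptide_length = function(d) nchar(d$peptide) >= 5,
    log_prob = function(d) d$log_prob_abs > 1,
    single_site = function(d) d$n_glycosites <= 1,
    delta_mod = function(d) d$delta_mod >= 10)
  for (nm in names(preds)) {
    keep <- preds[[nm]](cur)
    expect_equal(rep$steps$n_removed[rep$steps$step == nm], sum(!keep))
    cur <- cur[keep, , drop = FALSE]
  }
  expect_identical(rep$survivors$spectrum_id, cur$spectrum_id)

  # every planted violator was removed at its own step
  truth <- sim$truth$psms
  planted <- truth[!is.na(truth$violates), ]
  expect_gt(nrow(planted), 20)
  for (step in unique(planted$violates)) {
    ids <- planted$spectrum_id[planted$violates == step]
    expect_true(all(!ids %in% rep$survivors$spectrum_id))
  }

  # glyco FDR equals the decoy/target recount among pre-localization survivors
  cur2 <- compute_qvalues(psms)
  for (nm in names(preds)[1:5]) cur2 <- cur2[preds[[nm]](cur2), , drop = FALSE]
  gl <- cur2[cur2$n_glycosites >= 1, ]
  expected_fdr <- sum(gl$is_decoy) / sum(!gl$is_decoy)
  expect_equal(rep$glyco_fdr_estimate, expected_fdr)
})

test_that("raising any threshold never increases the survivor count", {
  cfg <- simulation_config(seed = 5, n_proteins = 8L)
  sim <- simulate_dataset(cfg)
  base_cfg <- filter_config(require_sequon = FALSE)
  n_base <- nrow(apply_filter_cascade(sim$psms, base_cfg)$survivors)
  tighter <- list(
    filter_config(psm_fdr = 0.005, require_sequon = FALSE),
    filter_config(min_byonic_score = 250, require_sequon = FALSE),
    filter_config(min_peptide_length = 9, require_sequon = FALSE),
    filter_config(min_log_prob_abs = 2, require_sequon = FALSE),
    filter_config(min_delta_mod = 25, require_sequon = FALSE))
  for (cfg2 in tighter)
    expect_lte(nrow(apply_filter_cascade(sim$psms, cfg2)$survivors), n_base)
})

test_that("the record-local steps commute: final survivor set is order-free", {
  cfg <- simulation_config(seed = 13, n_proteins = 8L,
                           violators = c(byonic_score = 3L, delta_mod = 3L,
                                         log_prob = 2L, peptide_length = 2L,
                                         single_site = 2L))
  psms <- simulate_dataset(cfg)$psms
  rep <- apply_filter_cascade(psms, filter_config(require_sequon = FALSE))
  # apply the same predicates in reverse order after the q-value step
  cur <- compute_qvalues(psms)
  cur <- cur[cur$q_value <= 0.01, ]
  cur <- cur[cur$delta_mod >= 10, ]
  cur <- cur[cur$n_glycosites <= 1, ]
  cur <- cur[cur$log_prob_abs > 1, ]
  cur <- cur[nchar(cur$peptide) >= 5, ]
  cur <- cur[cur$byonic_score >= 150, ]
  expect_setequal(rep$survivors$spectrum_id, cur$spectrum_id)
})

test_that("glycopeptide FDR counts only glycosylated PSMs", {
  glyco_t <- do.call(rbind, lapply(1:300, function(i) psm_row(paste0("t", i))))
  glyco_d <- psm_row("d1", decoy = TRUE)
  nonglyco <- psm_row("n1", n_sites = 0L, glycan = "")
  psms <- rbind(glyco_t, glyco_d, nonglyco)
  expect_equal(estimate_glyco_fdr(psms), 1 / 300)
  expect_equal(estimate_glyco_fdr(rbind(glyco_t, nonglyco)), 0)
  # non-glyco-only table: undefined
  expect_true(is.na(estimate_glyco_fdr(nonglyco)))
  # non-glyco rows are ignored in both numerator and denominator
  many_nonglyco <- do.call(rbind, lapply(1:50, function(i)
    psm_row(paste0("ng", i), n_sites = 0L, decoy = i <= 25)))
  expect_equal(estimate_glyco_fdr(rbind(glyco_t, glyco_d, many_nonglyco)),
               1 / 300)
})

test_that("realized false-discovery proportion is controlled at the q cutoff", {
  fdps <- vapply(1:30, function(s) {
    cfg <- simulation_config(seed = 3000 + s, n_proteins = 10L,
                             psm_lambda = 1.5)
    sim <- simulate_dataset(cfg)
    scored <- compute_qvalues(sim$psms)
    acc <- scored[scored$q_value <= 0.01 & !scored$is_decoy, ]
    if (!nrow(acc)) return(0)
    truth <- sim$truth$psms
    mean(!truth$is_correct[match(acc$spectrum_id, truth$spectrum_id)])
  }, 0)
  expect_lte(mean(fdps), 0.02)
})

test_that("sequon validation implements N-X-S/T with X != P", {
  expect_true(validate_sequon("TNSSF", 2))
  expect_true(validate_sequon("TNVTF", 2))
  expect_false(validate_sequon("TNPTF", 2))       # X is proline
  expect_false(validate_sequon("TNSAF", 2))       # no S/T at +2
  expect_false(validate_sequon("GGN", 3))         # truncated, no context
  # protein context completes a C-terminal sequon
  expect_true(validate_sequon("GGN", 3, protein_context = "AAGGNGT",
                              protein_position = 5))
  expect_false(validate_sequon("GGN", 3, protein_context = "AAGGNGG",
                               protein_position = 5))
  expect_error(validate_sequon("GGN", 9), "out of range")
  # position must hold an N
  expect_false(validate_sequon("TASSF", 2))
})

test_that("focused database keeps proteins with deamidated N in a sequon", {
  fasta <- c(P1 = "MKTNSSFIQGK", P2 = "MKTNPSFIQGK", P3 = "MKTAASFIQGK")
  psms <- data.frame(
    protein_accession = c("P1", "P2", "P4"),
    peptide = c("TNSSFIQGK", "TNPSFIQGK", "TNSSFIQGK"),
    deamidation_position = c(2L, 2L, 2L),
    stringsAsFactors = FALSE)
  expect_warning(db <- build_focused_database(psms, fasta), "P4")
  expect_identical(names(db), "P1")
  # no deamidation evidence: empty database
  none <- data.frame(protein_accession = "P1", peptide = "TNSSFIQGK",
                     deamidation_position = NA_integer_)
  expect_length(build_focused_database(none, fasta), 0L)
  expect_length(build_focused_database(psms[0, ], fasta), 0L)
})
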