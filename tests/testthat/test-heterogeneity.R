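# Site tables, co-occurrence, networks, subcellular profiles and domain
# statistics.

mk_sites <- function(...) {
  # mk_sites("P1", 10, "A", "B") builds rows for one site carrying A and B
  args <- list(...)
  rows <- list()
  i <- 1L
  while (i <= length(args)) {
    acc <- args[[i]]; site <- args[[i + 1L]]
    gl <- unlist(args[i + 2L])
    rows[[length(rows) + 1L]] <- data.frame(
      protein_accession = acc, protein_site = site, glycan = gl,
      stringsAsFactors = FALSE)
    i <- i + 3L
  }
  do.call(rbind, rows)
}

random_site_table <- function(n_sites = 12L, glycans = LETTERS[1:6]) {
  rows <- lapply(seq_len(n_sites), function(i) {
    k <- sample(1:4, 1L)
    data.frame(protein_accession = paste0("P", sample(1:4, 1L)),
               protein_site = i * 10L,
               glycan = sample(glycans, k), stringsAsFactors = FALSE)
  })
  build_site_table(do.call(rbind, rows))
}

test_that("site table deduplicates triples and tallies PSMs", {
  psms <- mk_sites("P1", 10, c("A", "A", "A"),   # 3 PSMs, one triple
                   "P1", 10, "B",
                   "P1", 20, "A",
                   "P2", 5, "C")
  tab <- build_site_table(psms)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$psm_count[tab$protein_accession == "P1" &
                               tab$site == 10 & tab$glycan == "A"], 3L)
  counts <- attr(tab, "counts")
  expect_equal(unname(counts["glycosites"]), 3L)
  expect_equal(unname(counts["glycoproteins"]), 2L)
  # glycans-per-site histogram: one site with 2 glycans, two with 1
  hist <- attr(tab, "glycans_per_site")
  expect_equal(as.integer(hist[c("1", "2")]), c(2L, 1L))
})

test_that("rows without site position are rejected with a warning", {
  psms <- data.frame(protein_accession = c("P1", "P1"),
                     protein_site = c(10L, NA), glycan = c("A", "B"))
  expect_warning(tab <- build_site_table(psms), "dropped")
  expect_equal(nrow(tab), 1L)
})

test_that("site-table recovery reproduces the generator's truth exactly", {
  cfg <- simulation_config(seed = 19, n_proteins = 15L)
  sim <- simulate_dataset(cfg)
  surv <- apply_filter_cascade(sim$psms,
                               filter_config(require_sequon = FALSE))$survivors
  # use the assignments directly (no-noise path): distribution must match
  tab <- build_site_table(
    data.frame(protein_accession = sim$assignments$protein_accession,
               protein_site = sim$assignments$site,
               glycan = sim$assignments$glycan))
  truth_k <- sim$truth$sites$k_per_site
  site_key <- paste(tab$protein_accession, tab$site)
  observed_k <- table(site_key)
  expect_equal(length(observed_k), length(truth_k))
  expect_equal(as.integer(observed_k[names(truth_k)]),
               unname(as.integer(truth_k)))
})

test_that("co-occurrence counts unordered glycan pairs per site", {
  one_site <- build_site_table(mk_sites("P1", 10, c("A", "B", "C")))
  m <- cooccurrence_matrix(one_site)
  expect_equal(m["A", "B"], 1L)
  expect_equal(m["A", "C"], 1L)
  expect_equal(m["B", "C"], 1L)
  expect_true(all(diag(m) == 0))
  two_sites <- build_site_table(mk_sites("P1", 10, c("A", "B"),
                                         "P2", 20, c("A", "B")))
  expect_equal(cooccurrence_matrix(two_sites)["A", "B"], 2L)
})

test_that("upper-triangle total equals the pairs identity on random tables", {
  set.seed(55)
  for (rep in 1:20) {
    tab <- random_site_table()
    m <- cooccurrence_matrix(tab)
    expect_true(isSymmetric(m))
    k <- table(paste(tab$protein_accession, tab$site))
    expect_equal(sum(m[upper.tri(m)]), sum(choose(k, 2)))
  }
})

test_that("network exports match their defining reductions", {
  tab <- build_site_table(mk_sites("P1", 10, c("A", "B"),
                                   "P1", 20, "A",
                                   "P2", 5, c("A", "C")))
  bip <- export_network(tab, "bipartite")
  # two sites of P1 share glycan A: single deduplicated edge
  expect_equal(sum(bip$from == "A" & bip$to == "P1"), 1L)
  # proteins ordered by glycosite count (P1 first with 2 sites)
  expect_equal(bip$to[1L], "P1")

  m <- cooccurrence_matrix(tab)
  co <- export_network(tab, "cooccurrence")
  for (i in seq_len(nrow(co)))
    expect_equal(co$weight[i], m[co$from[i], co$to[i]])

  star <- export_network(tab, "source_glycan", source = "A")
  row <- m["A", ]; row <- row[row > 0]
  expect_setequal(star$to, names(row))
  expect_equal(star$weight[match(names(row), star$to)], unname(as.numeric(row)))
  expect_error(export_network(tab, "source_glycan", source = "Z"),
               "source glycan")
  empty <- build_site_table(mk_sites("P1", 10, "A")[0, ])
  expect_equal(nrow(export_network(empty, "bipartite")), 0L)
})

test_that("GO term collapsing follows the rule order", {
  expect_identical(collapse_cc_terms("plasma membrane"), "plasma_membrane")
  expect_identical(collapse_cc_terms("integral component of membrane"),
                   "other_membrane")
  expect_identical(collapse_cc_terms("axon terminal"), "neural")
  expect_identical(collapse_cc_terms("myelin sheath"), "neural")
  expect_identical(collapse_cc_terms("Golgi apparatus"), "Golgi")
  expect_identical(collapse_cc_terms(
    "endoplasmic reticulum-Golgi intermediate compartment"), "ER")
  expect_identical(collapse_cc_terms("cell surface"), "cell_surface")
  expect_identical(collapse_cc_terms("nucleus"), "other_cellular_component")
  expect_identical(collapse_cc_terms(character(0)), "none_listed")
  # one protein, several groups
  expect_setequal(collapse_cc_terms(c("plasma membrane", "axon")),
                  c("plasma_membrane", "neural"))
})

test_that("profiles count site-glycan occurrences per group with multi-membership", {
  tab <- build_site_table(mk_sites("P1", 10, c("A", "B"), "P2", 5, "A"))
  groups <- list(P1 = c("plasma_membrane", "neural"), P2 = "ER")
  prof <- subcellular_profiles(tab, groups, glycans = c("A", "B", "C"))
  expect_equal(prof["plasma_membrane", "A"], 1)
  expect_equal(prof["neural", "A"], 1)       # P1 counted in both groups
  expect_equal(prof["ER", "A"], 1)
  expect_equal(sum(prof), 5)                 # 3 pairs, P1 doubled
  # conservation bound: total >= observations, equality iff single groups
  single <- subcellular_profiles(tab, list(P1 = "ER", P2 = "ER"),
                                 glycans = c("A", "B", "C"))
  expect_equal(sum(single), nrow(tab))
})

test_that("profile distances are a Euclidean metric", {
  prof <- rbind(a = c(1, 0, 0), b = c(0, 1, 0), c = c(1, 0, 0))
  d <- profile_distance_matrix(prof)
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d["a", "b"], sqrt(2))
  expect_equal(d["a", "c"], 0)
  set.seed(66)
  p <- matrix(rpois(30, 5), nrow = 6)
  dm <- profile_distance_matrix(p)
  for (rep in 1:20) {
    ijk <- sample(6, 3)
    expect_lte(dm[ijk[1], ijk[3]],
               dm[ijk[1], ijk[2]] + dm[ijk[2], ijk[3]] + 1e-12)
  }
})

test_that("domain statistics compute ratios and zero-sum composition differences", {
  # 3 sites inside the domain carrying 1, 2, 3 distinct glycan types
  tab <- build_site_table(mk_sites(
    "P1", 10, "HexNAc(2)Hex(9)",                                  # HM
    "P1", 20, c("HexNAc(2)Hex(9)", "HexNAc(4)Hex(5)"),            # HM+CH
    "P1", 30, c("HexNAc(2)Hex(9)", "HexNAc(4)Hex(5)",
                "HexNAc(4)Hex(4)NeuAc(1)"),                       # HM+CH+S
    "P2", 10, "HexNAc(2)Hex(5)"))                                 # outside
  domains <- data.frame(protein_accession = "P1", domain = "Ig-like C2-type 1",
                        start = 1L, end = 40L)
  ds <- domain_stats(tab, domains, min_sites = 1L)
  expect_equal(nrow(ds$stats), 1L)
  expect_identical(ds$stats$domain, "Ig-like")    # label collapsed
  expect_equal(ds$stats$n_glycosites, 3L)
  expect_equal(ds$stats$heterogeneity_ratio, (1 + 2 + 3) / 3)
  diffs <- as.numeric(ds$stats[, grep("^diff_", names(ds$stats))])
  expect_equal(sum(diffs), 0, tolerance = 1e-9)
  # overall ratio >= 1 whenever every site has a glycan
  expect_gte(ds$overall_ratio, 1)
})

test_that("small domains pool into 'other domains' and proteome counts give percentages", {
  tab <- build_site_table(mk_sites(
    "P1", 10, "HexNAc(2)Hex(9)", "P1", 20, "HexNAc(2)Hex(9)",
    "P2", 10, "HexNAc(4)Hex(5)"))
  domains <- data.frame(
    protein_accession = c("P1", "P1", "P2"),
    domain = c("Ig-like", "Ig-like", "Sushi"),
    start = c(1L, 15L, 1L), end = c(12L, 25L, 15L))
  counts <- data.frame(domain = c("Ig-like", "Sushi"), count = c(10L, 5L))
  ds <- domain_stats(tab, domains, proteome_domain_counts = counts,
                     min_sites = 2L)
  expect_setequal(ds$stats$domain, c("Ig-like", "other domains"))
  ig <- ds$stats[ds$stats$domain == "Ig-like", ]
  expect_equal(ig$n_glycosites, 2L)
  expect_equal(ig$pct_domains_with_glycosite, 100 * 2 / 10)
})

test_that("composition differences vanish when a domain matches the global mix", {
  # both domains see the same glycan mix, so every difference is ~0
  tab <- build_site_table(mk_sites(
    "P1", 10, c("HexNAc(2)Hex(9)", "HexNAc(4)Hex(5)"),
    "P2", 10, c("HexNAc(2)Hex(9)", "HexNAc(4)Hex(5)")))
  domains <- data.frame(protein_accession = c("P1", "P2"),
                        domain = c("Ig-like", "Sushi"),
                        start = 1L, end = 20L)
  ds <- domain_stats(tab, domains, min_sites = 1L)
  diffs <- as.matrix(ds$stats[, grep("^diff_", names(ds$stats))])
  expect_true(all(abs(diffs) < 1e-9))
})

test_that("hierarchical domain clustering is deterministic and outlier-aware", {
  st <- data.frame(domain = c("A", "B", "C"), n_glycosites = 5L,
                   heterogeneity_ratio = 1.5,
                   pct_domains_with_glycosite = NA_real_)
  for (g in c("paucimannose", "high_mannose", "complex_hybrid",
              "fucosylated", "sialylated", "M6P"))
    st[[paste0("diff_", g)]] <- 0
  st[st$domain == "C", "diff_high_mannose"] <- 50
  st[st$domain == "C", "diff_sialylated"] <- -50
  cl <- cluster_domains(st)
  # identical A and B merge first at height zero; outlier C joins last
  expect_equal(cl$hclust$height[1], 0)
  expect_identical(cl$order[3] == "C" || cl$order[1] == "C", TRUE)
  # permutation invariance of merge heights
  cl2 <- cluster_domains(st[c(3, 1, 2), ])
  expect_equal(cl$hclust$height, cl2$hclust$height)
  expect_identical(cl$order, cl2$order)
  # single-domain edge case
  expect_identical(cluster_domains(st[1, , drop = FALSE])$order, "A")
})
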