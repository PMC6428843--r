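# Systems-level glycan microheterogeneity analytics over filtered
# identifications: site tables, co-occurrence, networks, subcellular
# glycosylation profiles, and protein-domain glyco-type statistics.

#' Build a glycosite table from filtered PSMs
#'
#' Aggregates filter-cascade survivors to unique (protein, site, glycan)
#' triples with PSM tallies. The unique-glycopeptide key is (peptide
#' sequence including modifications, glycan composition); the
#' unique-glycosite key is (protein accession, protein-coordinate
#' position).
#'
#' @param psms data.frame with columns `protein_accession`,
#'   `protein_site` (1-based protein coordinate), `glycan` (canonical
#'   composition string), and optionally `peptide`.
#' @return An object of class `glycosite_table`: data.frame with columns
#'   `protein_accession`, `site`, `glycan`, `psm_count`, plus summary
#'   attributes `glycans_per_site` and `sites_per_protein` (tables) and
#'   `counts` (unique glycopeptide/site/protein/glycan totals).
#' @export
build_site_table <- function(psms) {
  need <- c("protein_accession", "protein_site", "glycan")
  miss <- setdiff(need, names(psms))
  if (length(miss))
    stop("PSM table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- is.na(psms$protein_site) | is.na(psms$glycan) | !nzchar(psms$glycan)
  if (any(bad)) {
    warning(sum(bad), " row(s) without a site position or glycan dropped")
    psms <- psms[!bad, , drop = FALSE]
  }
  if (!nrow(psms)) {
    tab <- data.frame(protein_accession = character(0), site = integer(0),
                      glycan = character(0), psm_count = integer(0))
  } else {
    key <- paste(psms$protein_accession, psms$protein_site, psms$glycan,
                 sep = "\r")
    agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
    parts <- strsplit(agg$key, "\r", fixed = TRUE)
    tab <- data.frame(
      protein_accession = vapply(parts, `[`, "", 1L),
      site = as.integer(vapply(parts, `[`, "", 2L)),
      glycan = vapply(parts, `[`, "", 3L),
      psm_count = agg$Freq, stringsAsFactors = FALSE)
    tab <- tab[order(tab$protein_accession, tab$site, tab$glycan), ,
               drop = FALSE]
    rownames(tab) <- NULL
  }
  site_key <- paste(tab$protein_accession, tab$site)
  glycans_per_site <- table(table(site_key))
  sites_per_protein <- table(vapply(
    split(tab$site, tab$protein_accession),
    function(s) length(unique(s)), 0L))
  counts <- c(
    glycopeptides = if ("peptide" %in% names(psms))
      length(unique(paste(psms$peptide, psms$glycan))) else NA_integer_,
    glycosites = length(unique(site_key)),
    glycoproteins = length(unique(tab$protein_accession)),
    glycans = length(unique(tab$glycan)),
    psms = sum(tab$psm_count))
  structure(tab, class = c("glycosite_table", "data.frame"),
            glycans_per_site = glycans_per_site,
            sites_per_protein = sites_per_protein,
            counts = counts)
}

#' Glycan co-occurrence matrix
#'
#' Square symmetric matrix over glycans: cell (a, b) counts the
#' glycosites where both a and b were observed. Diagonal is zero, and
#' the upper-triangle total equals the sum over sites of C(k, 2) where k
#' is the site's glycan count.
#'
#' @param table A [build_site_table()] result (or any data.frame with
#'   `protein_accession`, `site`, `glycan`).
#' @param glycans Optional character vector fixing matrix dimensions and
#'   order (e.g. the database's composition column); defaults to the
#'   glycans observed.
#' @return Integer matrix with dimnames = glycan composition strings.
#' @export
cooccurrence_matrix <- function(table, glycans = NULL) {
  if (!nrow(table)) {
    glycans <- glycans %||% character(0)
    return(matrix(0L, length(glycans), length(glycans),
                  dimnames = list(glycans, glycans)))
  }
  if (is.null(glycans)) glycans <- sort(unique(table$glycan))
  unknown <- setdiff(table$glycan, glycans)
  if (length(unknown))
    stop("glycan(s) not in the supplied index: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  m <- matrix(0L, length(glycans), length(glycans),
              dimnames = list(glycans, glycans))
  site_key <- paste(table$protein_accession, table$site)
  for (gs in split(table$glycan, site_key)) {
    gs <- unique(gs)
    if (length(gs) < 2L) next
    for (pair in utils::combn(gs, 2L, simplify = FALSE)) {
      m[pair[1L], pair[2L]] <- m[pair[1L], pair[2L]] + 1L
      m[pair[2L], pair[1L]] <- m[pair[2L], pair[1L]] + 1L
    }
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a glycosylation network as an edge list
#'
#' Three modes. `bipartite`: one edge (glycan, protein) per glycan
#' observed on at least one site of the protein, proteins ordered by
#' their glycosite count. `cooccurrence`: weighted glycan-glycan edges
#' from the co-occurrence matrix. `source_glycan`: the star of edges from
#' one source glycan to every glycan it co-occurs with, weighted by
#' co-occurrence count (the source's matrix row).
#'
#' @param table A glycosite table.
#' @param mode One of `"bipartite"`, `"cooccurrence"`, `"source_glycan"`.
#' @param source Source glycan composition string (source_glycan mode).
#' @return data.frame with columns `from`, `to`, `weight`, sorted by
#'   (`from`, `to`) for diff-stable output.
#' @export
export_network <- function(table, mode = c("bipartite", "cooccurrence",
                                           "source_glycan"),
                           source = NULL) {
  mode <- match.arg(mode)
  if (!nrow(table))
    return(data.frame(from = character(0), to = character(0),
                      weight = numeric(0)))
  if (mode == "bipartite") {
    key <- unique(data.frame(from = table$glycan,
                             to = table$protein_accession,
                             stringsAsFactors = FALSE))
    nsites <- vapply(split(table$site, table$protein_accession),
                     function(s) length(unique(s)), 0L)
    key$weight <- 1
    key <- key[order(-nsites[key$to], key$to, key$from), , drop = FALSE]
    rownames(key) <- NULL
    return(key)
  }
  m <- cooccurrence_matrix(table)
  if (mode == "cooccurrence") {
    idx <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
    out <- data.frame(from = rownames(m)[idx[, 1L]],
                      to = colnames(m)[idx[, 2L]],
                      weight = m[idx], stringsAsFactors = FALSE)
    out <- out[order(out$from, out$to), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  if (is.null(source) || !source %in% rownames(m))
    stop("source glycan not present in the table: ", source)
  w <- m[source, ]
  w <- w[w > 0]
  out <- data.frame(from = source, to = names(w), weight = as.numeric(w),
                    stringsAsFactors = FALSE)
  out <- out[order(out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an edge list as GraphML
#'
#' @param edges Edge data.frame (`from`, `to`, `weight`).
#' @param path Output path.
#' @param directed Logical; glycosylation networks are undirected.
#' @return Invisibly, the igraph object written.
#' @export
write_graphml <- function(edges, path, directed = FALSE) {
  g <- igraph::graph_from_data_frame(edges, directed = directed)
  igraph::write_graph(g, path, format = "graphml")
  invisible(g)
}

#' Default subcellular collapsing rules
#'
#' Ordered rule table mapping GO cellular-component term text to one of
#' 12 subcellular groups. A term is assigned to the first matching rule;
#' `exact` rules require full-string identity, `substring` rules a
#' case-insensitive substring (with an optional exclusion substring, used
#' to keep Golgi terms mentioning the endoplasmic reticulum out of the
#' Golgi group). Terms matching no rule fall into
#' `other_cellular_component`; proteins with no terms at all map to
#' `none_listed`.
#'
#' @return data.frame with columns `group`, `pattern`, `type`, `exclude`.
#' @export
default_cc_rules <- function() {
  data.frame(
    group = c("plasma_membrane", "synapse", "vesicle", "lysosome",
              "neural", "neural", "neural", "Golgi", "ER", "cell_surface",
              "secreted", "secreted", "other_membrane"),
    pattern = c("plasma membrane", "synap", "vesicle", "lysosom",
                "axon", "neuro", "myelin", "golgi", "endoplasmic",
                "surface", "secreted", "extracellular", "membrane"),
    type = c("exact", rep("substring", 12L)),
    exclude = c(NA, NA, NA, NA, NA, NA, NA, "endoplasmic", NA, NA, NA, NA,
                NA),
    stringsAsFactors = FALSE)
}

SUBCELLULAR_GROUPS <- c("plasma_membrane", "other_membrane", "synapse",
                        "vesicle", "cell_surface", "neural", "lysosome",
                        "secreted", "Golgi", "ER",
                        "other_cellular_component", "none_listed")

#' Collapse GO cellular-component terms to subcellular groups
#'
#' @param terms Character vector of GO CC term names for one protein
#'   (may be empty).
#' @param rules Rule table, see [default_cc_rules()].
#' @return Character vector of distinct group labels; `"none_listed"`
#'   for an empty term list. A protein may map to several groups.
#' @examples
#' collapse_cc_terms(c("plasma membrane", "axon terminal"))
#' @export
collapse_cc_terms <- function(terms, rules = default_cc_rules()) {
  terms <- terms[!is.na(terms) & nzchar(terms)]
  if (!length(terms)) return("none_listed")
  groups <- vapply(terms, function(term) {
    tl <- tolower(term)
    for (i in seq_len(nrow(rules))) {
      hit <- if (rules$type[i] == "exact") tl == tolower(rules$pattern[i])
             else grepl(tolower(rules$pattern[i]), tl, fixed = TRUE)
      if (hit && !is.na(rules$exclude[i]) &&
          grepl(tolower(rules$exclude[i]), tl, fixed = TRUE)) hit <- FALSE
      if (hit) return(rules$group[i])
    }
    "other_cellular_component"
  }, "")
  sort(unique(unname(groups)))
}

#' Subcellular glycosylation profiles
#'
#' For each subcellular group, a vector over the glycan database counting
#' that group's glycan occurrences. A protein belonging to k groups
#' contributes its sites to all k profiles. Occurrences are unique
#' (site, glycan) pairs by default; set `weight = "psm"` to weight by PSM
#' count instead.
#'
#' @param table A glycosite table.
#' @param protein_groups Named list: accession -> character vector of
#'   group labels (from [collapse_cc_terms()]); proteins absent from the
#'   list count under `"none_listed"`.
#' @param glycans Character vector fixing the profile dimension and order
#'   (typically the glycan database's composition column).
#' @param weight `"site_glycan"` (default) or `"psm"`.
#' @return Numeric matrix, rows = groups, columns = glycans.
#' @export
subcellular_profiles <- function(table, protein_groups, glycans,
                                 weight = c("site_glycan", "psm")) {
  weight <- match.arg(weight)
  groups_present <- sort(unique(c(unlist(protein_groups), "none_listed")))
  prof <- matrix(0, length(groups_present), length(glycans),
                 dimnames = list(groups_present, glycans))
  if (!nrow(table)) return(prof)
  unknown <- setdiff(table$glycan, glycans)
  if (length(unknown))
    stop("glycan(s) absent from the profile index: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  for (i in seq_len(nrow(table))) {
    gs <- protein_groups[[table$protein_accession[i]]] %||% "none_listed"
    w <- if (weight == "psm") table$psm_count[i] else 1
    prof[gs, table$glycan[i]] <- prof[gs, table$glycan[i]] + w
  }
  prof
}

#' Euclidean distances between subcellular profiles
#'
#' Treats each group as a vector over the glycan database (each glycan a
#' direction, occurrence counts as magnitudes) and returns the pairwise
#' Euclidean distance matrix.
#'
#' @param profiles Matrix from [subcellular_profiles()].
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
profile_distance_matrix <- function(profiles) {
  as.matrix(stats::dist(profiles, method = "euclidean"))
}

#' Collapse a domain label to its broadest common term
#'
#' Strips subtype qualifiers ("C1-type", "V-type", ...) and trailing copy
#' numbers so that, e.g., "Ig-like C2-type 3" collapses to "Ig-like".
#' An explicit `mapping` (named vector label -> collapsed label) takes
#' precedence.
#'
#' @param label Character vector of domain labels.
#' @param mapping Optional named character vector of overrides.
#' @return Character vector of collapsed labels.
#' @export
collapse_domain_label <- function(label, mapping = NULL) {
  out <- label
  if (!is.null(mapping)) {
    hit <- out %in% names(mapping)
    out[hit] <- mapping[out[hit]]
  }
  out <- sub("\\s+\\d+$", "", out)                    # trailing copy number
  out <- sub("\\s+(C[12]|V|I)-type$", "", out)        # Ig-like subtype tags
  sub("\\s+type-?[IVX0-9]+$", "", out)                # "type-III" style tags
}

#' Per-domain glyco-type statistics
#'
#' Maps glycosites into annotated domain spans (1-based closed
#' intervals), then per collapsed domain label computes: the number of
#' glycosites; the glycan heterogeneity ratio (glycan-type-glycosite
#' combinations divided by glycosites, where a site contributes one
#' combination per distinct glycan type observed there); the percentage
#' of the proteome's domain instances carrying a glycosite; and the
#' difference in percent composition per glycan type, i.e. the domain's
#' share of combinations of each type minus the overall share across all
#' sites (a mean-normalized comparison whose six entries sum to zero).
#' Domains with fewer than `min_sites` glycosites are pooled into
#' `"other domains"`.
#'
#' @param table A glycosite table.
#' @param domains data.frame with columns `protein_accession`, `domain`,
#'   `start`, `end` (labels are collapsed with
#'   [collapse_domain_label()]).
#' @param proteome_domain_counts Optional data.frame (`domain`, `count`)
#'   with proteome-wide domain instance totals; enables
#'   `pct_domains_with_glycosite`.
#' @param min_sites Pooling threshold (default 7).
#' @param scheme Glycan typing scheme for [glycan_types()]; the default
#'   multilabel scheme also counts fucosylated paucimannose/sialylated
#'   glycans as fucosylated.
#' @return List with `stats` (data.frame: domain, n_glycosites,
#'   heterogeneity_ratio, pct_domains_with_glycosite, one
#'   `diff_<type>` column per glycan type), `overall_ratio` (the
#'   all-sites heterogeneity ratio) and `overall_pct` (named vector of
#'   overall type shares, in percent).
#' @export
domain_stats <- function(table, domains, proteome_domain_counts = NULL,
                         min_sites = 7L,
                         scheme = c("multilabel", "exclusive")) {
  scheme <- match.arg(scheme)
  stopifnot(all(c("protein_accession", "domain", "start", "end") %in%
                names(domains)))
  domains$domain <- collapse_domain_label(domains$domain)

  # distinct glycan types observed at each site
  site_key <- paste(table$protein_accession, table$site)
  types_by_site <- lapply(split(table$glycan, site_key), function(gs) {
    sort(unique(unlist(lapply(unique(gs), function(g)
      glycan_types(g, scheme = scheme)))))
  })
  all_combos <- unlist(types_by_site, use.names = FALSE)
  overall_ratio <- length(all_combos) / length(types_by_site)
  overall_pct <- stats::setNames(numeric(length(GLYCAN_CLASSES)),
                                 GLYCAN_CLASSES)
  tt <- base::table(factor(all_combos, levels = GLYCAN_CLASSES))
  overall_pct[] <- 100 * as.numeric(tt) / length(all_combos)

  # site -> domain assignment (a site may fall in several domains)
  sites <- unique(data.frame(protein_accession = table$protein_accession,
                             site = table$site, stringsAsFactors = FALSE))
  assign_rows <- vector("list", 0L)
  for (i in seq_len(nrow(sites))) {
    dd <- domains[domains$protein_accession == sites$protein_accession[i] &
                  domains$start <= sites$site[i] &
                  domains$end >= sites$site[i], , drop = FALSE]
    if (!nrow(dd)) next
    for (lab in unique(dd$domain))
      assign_rows[[length(assign_rows) + 1L]] <- data.frame(
        domain = lab, protein_accession = sites$protein_accession[i],
        site = sites$site[i], stringsAsFactors = FALSE)
  }
  if (!length(assign_rows)) {
    return(list(stats = data.frame(), overall_ratio = overall_ratio,
                overall_pct = overall_pct))
  }
  assign_df <- do.call(rbind, assign_rows)
  assign_df$site_key <- paste(assign_df$protein_accession, assign_df$site)

  n_sites_by_domain <- vapply(split(assign_df$site_key, assign_df$domain),
                              function(x) length(unique(x)), 0L)
  small <- names(n_sites_by_domain)[n_sites_by_domain < min_sites]
  assign_df$domain[assign_df$domain %in% small] <- "other domains"

  one_domain <- function(df) {
    keys <- unique(df$site_key)
    combos <- unlist(types_by_site[keys], use.names = FALSE)
    pct <- 100 * as.numeric(base::table(factor(combos,
                                               levels = GLYCAN_CLASSES))) /
      length(combos)
    list(n = length(keys),
         ratio = length(combos) / length(keys),
         diff = pct - overall_pct)
  }
  labs <- sort(unique(assign_df$domain))
  rows <- lapply(labs, function(lab) {
    st <- one_domain(assign_df[assign_df$domain == lab, , drop = FALSE])
    pct_dom <- NA_real_
    if (!is.null(proteome_domain_counts)) {
      hit <- proteome_domain_counts$domain == lab
      if (any(hit)) {
        denom <- proteome_domain_counts$count[hit][1L]
        pct_dom <- if (denom > 0) 100 * n_domain_instances(assign_df, domains, lab) / denom
                   else NA_real_
      }
    }
    out <- data.frame(domain = lab, n_glycosites = st$n,
                      heterogeneity_ratio = st$ratio,
                      pct_domains_with_glycosite = pct_dom,
                      stringsAsFactors = FALSE)
    for (g in GLYCAN_CLASSES) out[[paste0("diff_", g)]] <- st$diff[[g]]
    out
  })
  list(stats = do.call(rbind, rows), overall_ratio = overall_ratio,
       overall_pct = overall_pct)
}

# Number of distinct annotated domain instances of a label that carry at
# least one observed glycosite.
n_domain_instances <- function(assign_df, domains, lab) {
  sub <- assign_df[assign_df$domain == lab, , drop = FALSE]
  dd <- domains
  n <- 0L
  seen <- character(0)
  for (i in seq_len(nrow(sub))) {
    hits <- which(dd$protein_accession == sub$protein_accession[i] &
                  dd$start <= sub$site[i] & dd$end >= sub$site[i])
    for (h in hits) {
      key <- paste(dd$protein_accession[h], dd$domain[h], dd$start[h],
                   dd$end[h])
      if (!key %in% seen) { seen <- c(seen, key); n <- n + 1L }
    }
  }
  n
}

#' Hierarchically cluster domains on composition differences
#'
#' Treats each domain as a six-dimensional vector of glycan-type percent
#' composition differences and clusters with agglomerative hierarchical
#' clustering (Euclidean metric; average linkage by default). Input rows
#' are sorted by domain label first, so the ordering is deterministic
#' under ties.
#'
#' @param stats The `stats` data.frame from [domain_stats()].
#' @param method Linkage passed to [stats::hclust()].
#' @return List with `order` (domain labels in leaf order) and `hclust`
#'   (the tree). A single domain returns itself.
#' @export
cluster_domains <- function(stats, method = "average") {
  if (!nrow(stats)) stop("no domain statistics to cluster")
  stats <- stats[order(stats$domain), , drop = FALSE]
  if (nrow(stats) == 1L)
    return(list(order = stats$domain, hclust = NULL))
  v <- as.matrix(stats[, grep("^diff_", names(stats)), drop = FALSE])
  rownames(v) <- stats$domain
  hc <- stats::hclust(stats::dist(v, method = "euclidean"), method = method)
  list(order = stats$domain[hc$order], hclust = hc)
}
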