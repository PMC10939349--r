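# Synthetic input bundles with planted ground truth. The generator emulates
# the statistical structure of the real MAG catalogs (multi-environment
# provenance, cross-domain KO overlap, evidence-confidence distributions
# spanning every tier, planted flank-gene motifs) without attempting
# clustering-realistic sequences. Every truth-manifest entry is re-derived
# by straight-line code here, independently of the pipeline modules it is
# later compared against.

GUT_ENV <- "human gut"

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

FUNCTION_VOCAB <- c(
  "site-specific DNA recombinase",
  "type IV pilus assembly ATPase",
  "polypeptide N-acetylgalactosaminyltransferase",
  "dolichyl-phosphate-mannose mannosyltransferase",
  "stage V sporulation factor AD",
  "stage V sporulation factor AE",
  "type II restriction endonuclease",
  "cold-shock nucleic-acid-binding regulator",
  "aminoethylphosphonate aminotransferase",
  "transthyretin-like periplasmic carrier",
  "propanediol utilization microcompartment shell",
  "hydroxyethylthiazole kinase",
  "phytol kinase",
  "nucleoside salvage kinase",
  "thiamine-phosphate pyrophosphorylase",
  "glucose-regulated chaperone GRP78",
  "arabinose glycosyltransferase",
  "intimin invasin adhesion domain",
  "restriction modification specificity subunit",
  "methanogenesis marker oxidoreductase"
)

# DF terms guaranteed to share no >=4-char token with FUNCTION_VOCAB
DF_UNRELATED_TERMS <- c(
  "metal cation homeostasis", "ribosome biogenesis cofactor",
  "membrane lipid remodeling", "small molecule catabolism"
)

# open intervals strictly inside each tier band, so boundary ambiguity is
# impossible by construction
PF_TIER_BANDS <- list(
  certain = c(1e-12, 1e-7),
  probable = c(2e-6, 9e-3),
  possible = c(0.02, 0.09),
  long_shot = c(0.2, 9)
)
TR_TIER_BANDS <- list(
  very_high = c(0.705, 0.995),
  high = c(0.505, 0.695),
  medium = c(0.405, 0.495),
  low = c(0.305, 0.395)
)

#' Build and validate a generator configuration
#'
#' The defaults describe a small but structurally faithful study: a
#' gut-dominated multi-environment MAG collection of both domains, archaeal
#' clusters of 1-8 members against a 2-member gate, bacterial clusters of
#' 8-16 members against a 10-member gate, partial KO-annotation coverage,
#' evidence whose confidence values span every PF/TR tier, and flank-gene
#' motifs planted inside and outside the 10-kb synteny window.
#'
#' @param seed integer master seed; one named RNG stream per generated file
#'   type is derived from it.
#' @param n_archaeal_mags,n_bacterial_mags MAG counts per domain.
#' @param environments named probability vector over environment labels;
#'   must contain `"human gut"` and sum to 1.
#' @param n_archaeal_clusters,n_bacterial_clusters level-1 cluster counts.
#' @param archaeal_cluster_size,bacterial_cluster_size named `c(min=, max=)`
#'   member-count ranges.
#' @param ko_universe_size size of the KO identifier universe.
#' @param shared_ko_fraction fraction of the archaeal KO pool drawn from
#'   the bacterial pool (cross-domain overlap).
#' @param fraction_gut_exclusive fraction of clusters planted with members
#'   exclusively from gut MAGs.
#' @param fraction_unannotated fraction of clusters left without complete
#'   KO annotation (half fully unannotated, half with one missing member).
#' @param pf_tier_mix probabilities over PF tiers
#'   (certain/probable/possible/long_shot/none); must sum to 1.
#' @param tr_tier_mix probabilities over TR tiers
#'   (very_high/high/medium/low/none); must sum to 1.
#' @param agreement_probability probability that PF and TR carry the same
#'   function label when both are present.
#' @param df_support_probability probability that an annotated subject gets
#'   a supporting DF prediction (score > 0.7, token-matching term).
#' @param flank_plants data.frame (`ko`, `side`, `distance`) of motif genes
#'   planted around each synteny target; distances beyond 10 kb produce
#'   genes a correct extractor must exclude.
#' @param n_samples number of metatranscriptomic samples for coverage.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(seed = 1,
                             n_archaeal_mags = 24,
                             n_bacterial_mags = 30,
                             environments = c(
                               "human gut" = 0.7, "soil" = 0.15,
                               "marine" = 0.15
                             ),
                             n_archaeal_clusters = 40,
                             n_bacterial_clusters = 25,
                             archaeal_cluster_size = c(min = 1, max = 8),
                             bacterial_cluster_size = c(min = 8, max = 16),
                             ko_universe_size = 240,
                             shared_ko_fraction = 0.4,
                             fraction_gut_exclusive = 0.5,
                             fraction_unannotated = 0.1,
                             pf_tier_mix = c(
                               certain = 0.35, probable = 0.15,
                               possible = 0.1, long_shot = 0.1, none = 0.3
                             ),
                             tr_tier_mix = c(
                               very_high = 0.35, high = 0.2, medium = 0.1,
                               low = 0.05, none = 0.3
                             ),
                             agreement_probability = 0.5,
                             df_support_probability = 0.5,
                             flank_plants = data.frame(
                               ko = c("K06400", "K02662", "K02664"),
                               side = c("upstream", "downstream", "downstream"),
                               distance = c(4000, 2000, 12000)
                             ),
                             n_samples = 6) {
  check_mix <- function(x, what, expected_names) {
    if (!setequal(names(x), expected_names)) {
      config_error(what, " must be named over: ",
        paste(expected_names, collapse = ", "))
    }
    if (any(x < 0 | x > 1)) config_error(what, " entries must lie in [0, 1]")
    if (abs(sum(x) - 1) > 1e-9) config_error(what, " must sum to 1")
    x[expected_names]
  }
  environments <- stats::setNames(
    as.numeric(environments),
    normalize_environment(names(environments))
  )
  if (!GUT_ENV %in% names(environments)) {
    config_error("environments must include '", GUT_ENV, "'")
  }
  if (abs(sum(environments) - 1) > 1e-9) {
    config_error("environment probabilities must sum to 1")
  }
  for (p in c(
    shared_ko_fraction, fraction_gut_exclusive, fraction_unannotated,
    agreement_probability, df_support_probability
  )) {
    if (p < 0 || p > 1) config_error("probabilities must lie in [0, 1]")
  }
  non_gut_mass <- sum(environments[names(environments) != GUT_ENV])
  if (fraction_gut_exclusive < 1 && non_gut_mass == 0) {
    config_error(
      "fraction_gut_exclusive < 1 requires a non-gut environment with",
      " positive probability"
    )
  }
  if (!all(c("ko", "side", "distance") %in% names(flank_plants))) {
    config_error("flank_plants needs columns ko, side, distance")
  }
  if (!all(flank_plants$side %in% c("upstream", "downstream"))) {
    config_error("flank_plants side must be 'upstream' or 'downstream'")
  }
  structure(
    list(
      seed = as.integer(seed),
      n_archaeal_mags = n_archaeal_mags,
      n_bacterial_mags = n_bacterial_mags,
      environments = environments,
      n_archaeal_clusters = n_archaeal_clusters,
      n_bacterial_clusters = n_bacterial_clusters,
      archaeal_cluster_size = archaeal_cluster_size,
      bacterial_cluster_size = bacterial_cluster_size,
      ko_universe_size = ko_universe_size,
      shared_ko_fraction = shared_ko_fraction,
      fraction_gut_exclusive = fraction_gut_exclusive,
      fraction_unannotated = fraction_unannotated,
      pf_tier_mix = check_mix(
        pf_tier_mix, "pf_tier_mix",
        c("certain", "probable", "possible", "long_shot", "none")
      ),
      tr_tier_mix = check_mix(
        tr_tier_mix, "tr_tier_mix",
        c("very_high", "high", "medium", "low", "none")
      ),
      agreement_probability = agreement_probability,
      df_support_probability = df_support_probability,
      flank_plants = flank_plants,
      n_samples = n_samples
    ),
    class = "generator_config"
  )
}

gen_mags <- function(config) {
  n_a <- config$n_archaeal_mags
  n_b <- config$n_bacterial_mags
  envs <- names(config$environments)
  probs <- unname(config$environments)
  env_a <- sample(envs, n_a, replace = TRUE, prob = probs)
  env_b <- sample(envs, n_b, replace = TRUE, prob = probs)
  non_gut <- envs[envs != GUT_ENV]
  force_mix <- function(env, n) {
    # guarantee both a usable gut pool and (when planted non-exclusive
    # clusters need one) a non-gut pool
    k <- max(2, ceiling(n / 3))
    env[seq_len(min(k, n))] <- GUT_ENV
    if (config$fraction_gut_exclusive < 1 && !any(env != GUT_ENV)) {
      env[n] <- non_gut[1]
    }
    env
  }
  env_a <- force_mix(env_a, n_a)
  env_b <- force_mix(env_b, n_b)
  arch_tax <- paste0(
    "d__Archaea;p__Methanobacteriota;c__Methanobacteria;",
    "o__Methanobacteriales;f__Methanobacteriaceae;",
    "g__Methanobrevibacter;s__Methanobrevibacter smithii"
  )
  bact_lineages <- c(
    paste0(
      "d__Bacteria;p__Firmicutes_A;c__Clostridia;o__Oscillospirales;",
      "f__CAG-272;g__Clostridium;s__Clostridium sp CAG-302"
    ),
    paste0(
      "d__Bacteria;p__Firmicutes_A;c__Clostridia;o__Lachnospirales;",
      "f__Lachnospiraceae;g__Blautia;s__Blautia obeum"
    ),
    paste0(
      "d__Bacteria;p__Bacteroidota;c__Bacteroidia;o__Bacteroidales;",
      "f__Bacteroidaceae;g__Bacteroides;s__Bacteroides uniformis"
    )
  )
  as_mag_table(data.frame(
    mag_id = sprintf("MAG%04d", seq_len(n_a + n_b)),
    domain = c(rep("archaea", n_a), rep("bacteria", n_b)),
    taxonomy = c(
      rep(arch_tax, n_a),
      sample(bact_lineages, n_b, replace = TRUE)
    ),
    environment = c(env_a, env_b),
    catalog = c(
      sample(c("GEM", "UHGG"), n_a, replace = TRUE),
      rep("UHGG", n_b)
    )
  ))
}

random_protein <- function(n) {
  lens <- sample(80:600, n, replace = TRUE)
  vapply(lens, function(l) {
    paste(sample(AA_LETTERS, l, replace = TRUE), collapse = "")
  }, character(1))
}

gen_domain_clusters <- function(config, mags, domain, prefix, id_offset) {
  n_cl <- if (domain == "archaea") {
    config$n_archaeal_clusters
  } else {
    config$n_bacterial_clusters
  }
  size_rng <- if (domain == "archaea") {
    config$archaeal_cluster_size
  } else {
    config$bacterial_cluster_size
  }
  pool <- mags$mag_id[mags$domain == domain]
  gut_pool <- mags$mag_id[mags$domain == domain &
    mags$environment == GUT_ENV]
  other_pool <- setdiff(pool, gut_pool)
  n_excl <- round(config$fraction_gut_exclusive * n_cl)
  excl <- seq_len(n_cl) %in% sample(seq_len(n_cl), n_excl)
  rows <- vector("list", n_cl)
  pid <- id_offset
  for (i in seq_len(n_cl)) {
    size <- sample(size_rng[["min"]]:size_rng[["max"]], 1)
    mag_ids <- if (excl[i]) {
      sample(gut_pool, size, replace = TRUE)
    } else {
      # plant at least one member from a non-gut MAG
      m <- sample(pool, size, replace = TRUE)
      m[sample(size, 1)] <- sample(other_pool, 1)
      m
    }
    rows[[i]] <- data.frame(
      cluster_id = sprintf("%s%04d", prefix, i),
      protein_id = sprintf("p%06d", pid + seq_len(size)),
      mag_id = mag_ids
    )
    pid <- pid + size
  }
  do.call(rbind, rows)
}

gen_clusters <- function(config, mags) {
  arch <- gen_domain_clusters(config, mags, "archaea", "AC", 0L)
  bact <- gen_domain_clusters(config, mags, "bacteria", "BC", nrow(arch))
  both <- rbind(arch, bact)
  proteins <- data.frame(
    protein_id = both$protein_id,
    mag_id = both$mag_id,
    sequence = random_protein(nrow(both))
  )
  proteins$length <- nchar(proteins$sequence)
  clusters <- as_cluster_table(
    data.frame(cluster_id = both$cluster_id, member_id = both$protein_id),
    level = "mm2"
  )
  list(proteins = proteins, clusters = clusters)
}

gen_ko <- function(config, clusters) {
  universe <- sprintf("K%05d", seq_len(config$ko_universe_size))
  # leave part of the universe outside the bacterial pool so archaea-only
  # KOs always exist
  n_bact_pool <- min(120, max(1, round(0.6 * length(universe))))
  bact_pool <- sample(universe, n_bact_pool)
  n_arch_pool <- min(60, length(universe))
  n_shared <- round(config$shared_ko_fraction * n_arch_pool)
  shared <- sample(bact_pool, min(n_shared, length(bact_pool)))
  outside <- setdiff(universe, bact_pool)
  arch_pool <- c(shared, sample(outside, min(
    n_arch_pool - length(shared),
    length(outside)
  )))
  if (length(arch_pool) == 0) arch_pool <- bact_pool
  ids <- unique(clusters$cluster_id)
  is_arch <- startsWith(ids, "AC")
  n_unann <- round(config$fraction_unannotated * length(ids))
  unann <- if (n_unann > 0) sample(ids, n_unann) else character(0)
  partial <- unann[seq_along(unann) %% 2 == 0]
  fully_unann <- setdiff(unann, partial)
  members <- split(clusters$member_id, clusters$cluster_id)
  rows <- lapply(seq_along(ids), function(i) {
    cid <- ids[i]
    if (cid %in% fully_unann) {
      return(NULL)
    }
    pool <- if (is_arch[i]) arch_pool else bact_pool
    kos <- sample(pool, sample(if (is_arch[i]) 1:2 else 1:3, 1))
    mem <- members[[cid]]
    if (cid %in% partial && length(mem) > 1) {
      mem <- mem[-sample(length(mem), 1)]
    }
    data.frame(
      subject_id = rep(mem, each = length(kos)),
      ko_id = rep(kos, times = length(mem))
    )
  })
  ko <- do.call(rbind, rows)
  rownames(ko) <- NULL
  ko
}

# straight-line re-derivation of the selection funnel (kept deliberately
# independent of the gut_selection module)
derive_selected <- function(config, mags, proteins, clusters, ko) {
  env_of_mag <- stats::setNames(mags$environment, mags$mag_id)
  dom_of_mag <- stats::setNames(mags$domain, mags$mag_id)
  mag_of_prot <- stats::setNames(proteins$mag_id, proteins$protein_id)
  annotated <- unique(ko$subject_id)
  ids <- unique(clusters$cluster_id)
  members <- split(clusters$member_id, clusters$cluster_id)[ids]
  gut_excl <- vapply(members, function(m) {
    all(env_of_mag[mag_of_prot[m]] == GUT_ENV)
  }, logical(1))
  domain <- vapply(members, function(m) {
    dom_of_mag[[mag_of_prot[[m[1]]]]]
  }, character(1))
  min_size <- ifelse(domain == "archaea", 2, 10)
  big_enough <- lengths(members) >= min_size
  fully_ann <- vapply(members, function(m) all(m %in% annotated), logical(1))
  list(
    gut_exclusive = ids[gut_excl],
    selected = ids[gut_excl & big_enough & fully_ann],
    domain = stats::setNames(domain, ids)
  )
}

gen_superclusters <- function(selected_arch, selected_bact) {
  group_ids <- function(ids, offset) {
    if (length(ids) == 0) {
      return(data.frame(cluster_id = character(), member_id = character()))
    }
    ids <- sample(ids)
    sizes <- integer(0)
    left <- length(ids)
    while (left > 0) {
      s <- min(left, sample(1:3, 1))
      sizes <- c(sizes, s)
      left <- left - s
    }
    data.frame(
      cluster_id = sprintf("SC%04d", offset + rep(
        seq_along(sizes),
        times = sizes
      )),
      member_id = ids
    )
  }
  arch <- group_ids(selected_arch, 0L)
  n_arch_sc <- length(unique(arch$cluster_id))
  bact <- group_ids(selected_bact, n_arch_sc)
  as_cluster_table(rbind(arch, bact), level = "sourmash")
}

ko_label <- function(ko_id) {
  idx <- (as.integer(sub("^K", "", ko_id)) %% length(FUNCTION_VOCAB)) + 1
  FUNCTION_VOCAB[idx]
}

draw_in <- function(band) stats::runif(1, band[1], band[2])

gen_evidence_one <- function(config, subject, sc_kos) {
  pf_tier <- sample(names(config$pf_tier_mix), 1,
    prob = unname(config$pf_tier_mix)
  )
  tr_tier <- sample(names(config$tr_tier_mix), 1,
    prob = unname(config$tr_tier_mix)
  )
  pf_label <- sample(FUNCTION_VOCAB, 1)
  tr_label <- if (stats::runif(1) < config$agreement_probability) {
    pf_label
  } else {
    sample(setdiff(FUNCTION_VOCAB, pf_label), 1)
  }
  pf <- NULL
  pf_is_3d <- NA
  pf_cov <- NA_real_
  pf_ident <- NA_real_
  if (pf_tier != "none") {
    qlen <- sample(80:600, 1)
    cov_frac <- stats::runif(1, 0.3, 0.95)
    seg <- max(1, round(cov_frac * qlen))
    pf_is_3d <- stats::runif(1) < 0.8
    pf_ident <- stats::runif(1, 20, 95)
    pf <- data.frame(
      kind = if (pf_is_3d) "template_3d" else "sequence_vs_pdb",
      e_value = draw_in(PF_TIER_BANDS[[pf_tier]]),
      percent_identity = pf_ident,
      longest_fitted_segment = seg,
      query_length = qlen,
      function_label = pf_label
    )
    pf_cov <- seg / qlen
  }
  tr <- NULL
  tr_cov <- NA_real_
  tr_ident <- NA_real_
  if (tr_tier != "none") {
    tr_cov <- stats::runif(1, 0.35, 0.95)
    tr_ident <- stats::runif(1, 0.2, 0.9)
    tr <- data.frame(
      template_id = sprintf("%s_%04d", "pdb", sample(1:9999, 1)),
      confidence = stats::runif(1, 0.65, 0.95),
      e_value = stats::runif(1, 1e-6, 5e-4),
      coverage = tr_cov,
      identity = tr_ident,
      tm_score = draw_in(TR_TIER_BANDS[[tr_tier]]),
      function_label = tr_label
    )
  } else if (stats::runif(1) < 0.5) {
    # inadmissible template (confidence below 0.6): must be ignored
    tr <- data.frame(
      template_id = sprintf("%s_%04d", "pdb", sample(1:9999, 1)),
      confidence = stats::runif(1, 0.2, 0.55),
      e_value = stats::runif(1, 1e-6, 5e-4),
      coverage = stats::runif(1, 0.35, 0.95),
      identity = stats::runif(1, 0.2, 0.9),
      tm_score = stats::runif(1, 0.4, 0.9),
      function_label = tr_label
    )
  }

  # independent straight-line re-derivation of the ladder outcome
  rank_of <- c(
    certain = 4, probable = 3, possible = 2, long_shot = 1,
    very_high = 4, high = 3, medium = 2, low = 1, none = 0
  )
  expected <- if (pf_tier == "none" && tr_tier == "none") {
    "unannotated"
  } else if (tr_tier == "none") {
    if (pf_tier == "certain") pf_label else "unannotated"
  } else if (pf_tier == "none") {
    tr_label
  } else if (pf_label == tr_label) {
    pf_label
  } else if (pf_tier != "certain") {
    tr_label
  } else if (!pf_is_3d) {
    tr_label
  } else if (rank_of[[tr_tier]] < 4) {
    pf_label
  } else if (tr_cov > pf_cov) {
    tr_label
  } else if (pf_cov > tr_cov) {
    pf_label
  } else if (tr_ident >= pf_ident / 100) {
    tr_label
  } else {
    pf_label
  }

  dfp <- NULL
  if (expected != "unannotated" &&
    stats::runif(1) < config$df_support_probability) {
    tokens <- label_tokens(expected)[[1]]
    dfp <- data.frame(
      term_id = sprintf("GO:%07d", sample(1:9999999, 1)),
      score = stats::runif(1, 0.75, 0.95),
      term_name = paste(tokens[1], "activity")
    )
  } else if (stats::runif(1) < 0.3) {
    dfp <- data.frame(
      term_id = sprintf("GO:%07d", sample(1:9999999, 1)),
      score = stats::runif(1, 0.2, 0.65),
      term_name = sample(DF_UNRELATED_TERMS, 1)
    )
  }

  bundle <- evidence_bundle(
    subject_id = subject,
    sequence_ko = if (length(sc_kos) > 0) {
      list(ko_ids = sc_kos, label = ko_label(sc_kos[1]), source = "mantis")
    },
    pf_matches = pf, tr_hits = tr, df_predictions = dfp
  )
  list(bundle = bundle, expected = expected)
}

#' Generate evidence bundles with planted expected outcomes
#'
#' For each subject a PF tier and a TR tier are sampled from the configured
#' mixtures, confidence values are drawn strictly inside the corresponding
#' tier bands, and the expected final label is re-derived by a straight-line
#' application of the reconciliation ladder (independent of the consensus
#' module).
#'
#' @param config a `generator_config`.
#' @param subjects character vector of subject ids.
#' @param subject_kos named list subject_id -> KO set (sequence annotation).
#' @return list with `bundles` (named list of `evidence_bundle`) and
#'   `expected_final_label` (named character vector).
#' @export
generate_evidence <- function(config, subjects, subject_kos = list()) {
  with_stream(config$seed, "evidence", {
    out <- lapply(subjects, function(s) {
      kos <- subject_kos[[s]]
      gen_evidence_one(config, s, if (is.null(kos)) character(0) else kos)
    })
    list(
      bundles = stats::setNames(lapply(out, `[[`, "bundle"), subjects),
      expected_final_label = stats::setNames(
        vapply(out, `[[`, character(1), "expected"), subjects
      )
    )
  })
}

#' Generate a synteny fixture with planted flank motifs
#'
#' Each synteny target sits on its own contig with background genes tiled
#' around it; each configured motif gene is placed at its signed distance
#' from the target (upstream: gene end = target start - distance;
#' downstream: gene start = target end + distance). Distances beyond 10 kb
#' yield genes a correct window extractor must exclude. Background genes
#' never carry motif KOs.
#'
#' @param config a `generator_config`.
#' @param n_targets number of target genes (default 2).
#' @return list with `features` (gene-feature data.frame), `targets`
#'   (character vector), and `planted_flank_hits` (named list target ->
#'   `upstream_recombinase`/`downstream_pilus` flags, derived straight from
#'   the plant list).
#' @export
generate_synteny_fixture <- function(config, n_targets = 2) {
  with_stream(config$seed, "synteny", {
    plants <- config$flank_plants
    motif_kos <- unique(plants$ko)
    bg_pool <- setdiff(sprintf("K%05d", seq_len(config$ko_universe_size)),
      c(motif_kos, "K06400", "K02662", "K02664")
    )
    all_rows <- list()
    flags <- list()
    for (i in seq_len(n_targets)) {
      contig <- sprintf("contig%02d", i)
      t_start <- 50001
      t_end <- 51200
      tid <- sprintf("target_%02d", i)
      rows <- list(data.frame(
        contig_id = contig, gene_id = tid, start = t_start, end = t_end,
        strand = "+", ko = NA_character_
      ))
      if (nrow(plants) > 0) {
        for (j in seq_len(nrow(plants))) {
          d <- plants$distance[j]
          if (plants$side[j] == "upstream") {
            g_end <- t_start - d
            g_start <- g_end - 899
          } else {
            g_start <- t_end + d
            g_end <- g_start + 899
          }
          if (g_start < 1) {
            config_error(
              "planted motif ", plants$ko[j], " at distance ", d,
              " would start at a negative coordinate"
            )
          }
          rows[[length(rows) + 1]] <- data.frame(
            contig_id = contig,
            gene_id = sprintf("plant_%02d_%02d", i, j),
            start = g_start, end = g_end,
            strand = sample(c("+", "-"), 1),
            ko = plants$ko[j]
          )
        }
      }
      occupied <- do.call(rbind, rows)
      for (s in seq(2001, 95001, by = 3000)) {
        e <- s + 899
        if (any(s <= occupied$end & e >= occupied$start)) next
        rows[[length(rows) + 1]] <- data.frame(
          contig_id = contig,
          gene_id = sprintf("bg_%02d_%05d", i, s),
          start = s, end = e,
          strand = sample(c("+", "-"), 1),
          ko = if (stats::runif(1) < 0.7) sample(bg_pool, 1) else NA_character_
        )
      }
      all_rows <- c(all_rows, rows)
      # flags derived straight from the plant list and the 10-kb window rule
      flags[[tid]] <- list(
        upstream_recombinase = any(
          plants$side == "upstream" & plants$distance <= 10000 &
            plants$ko %in% "K06400"
        ),
        downstream_pilus = any(
          plants$side == "downstream" & plants$distance <= 10000 &
            plants$ko %in% c("K02662", "K02664")
        )
      )
    }
    feat <- do.call(rbind, all_rows)
    features <- data.frame(
      contig_id = feat$contig_id, gene_id = feat$gene_id,
      start = feat$start, end = feat$end, strand = feat$strand
    )
    features$ko_ids <- unname(lapply(feat$ko, function(k) {
      if (is.na(k)) character(0) else k
    }))
    features <- features[
      order(features$contig_id, features$start, features$gene_id), ,
      drop = FALSE
    ]
    rownames(features) <- NULL
    list(
      features = features,
      targets = sprintf("target_%02d", seq_len(n_targets)),
      planted_flank_hits = flags
    )
  })
}

gen_coverage <- function(config, gene_ids, cluster_of_gene) {
  samples <- sprintf("S%02d", seq_len(config$n_samples))
  if (length(gene_ids) == 0) {
    return(data.frame(
      gene_id = character(), sample_id = character(),
      mean_coverage = numeric()
    ))
  }
  clusters <- unique(cluster_of_gene)
  n_high <- max(1, round(0.25 * length(clusters)))
  high <- sample(clusters, n_high)
  meanlog <- stats::setNames(
    stats::rnorm(length(clusters), mean = 1, sd = 0.3) +
      ifelse(clusters %in% high, 2, 0),
    clusters
  )
  grid <- expand.grid(
    gene_id = gene_ids, sample_id = samples,
    stringsAsFactors = FALSE
  )
  grid$mean_coverage <- round(stats::rlnorm(
    nrow(grid),
    meanlog = meanlog[cluster_of_gene[grid$gene_id]], sdlog = 0.4
  ), 3)
  grid[order(grid$gene_id, grid$sample_id), , drop = FALSE]
}

#' Generate a complete synthetic input bundle with ground truth
#'
#' Produces every file consumed by the pipeline plus a truth manifest:
#' the set of gut-exclusive clusters, the unique/homologous group of each
#' archaeal supercluster (KO-overlap definition applied by straight-line
#' set operations), the expected final label of every evidence subject
#' (independent ladder re-derivation), and the planted flank-motif flags.
#' Deterministic given the seed; superclusters are built over the clusters
#' that survive the selection funnel, mirroring the study design in which
#' MinHash superclustering follows selection.
#'
#' @param config a `generator_config`.
#' @param out_dir output directory; `NULL` keeps the bundle in memory only.
#' @return (invisibly) a list with `bundle` (see [load_input_bundle()]),
#'   `manifest`, and `paths` (when written).
#' @export
generate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  mags <- with_stream(config$seed, "mags", gen_mags(config))
  cp <- with_stream(config$seed, "clusters", gen_clusters(config, mags))
  ko <- with_stream(config$seed, "ko", gen_ko(config, cp$clusters))
  sel <- derive_selected(config, mags, cp$proteins, cp$clusters, ko)
  superclusters <- with_stream(
    config$seed, "superclusters",
    gen_superclusters(
      sel$selected[sel$domain[sel$selected] == "archaea"],
      sel$selected[sel$domain[sel$selected] == "bacteria"]
    )
  )
  # KO sets and groups, by plain set operations on the generated tables
  ko_of_protein <- split(ko$ko_id, ko$subject_id)
  members_l1 <- split(cp$clusters$member_id, cp$clusters$cluster_id)
  ko_of_cluster <- lapply(members_l1, function(m) {
    sort(unique(unlist(ko_of_protein[m], use.names = FALSE)))
  })
  sc_members <- split(superclusters$member_id, superclusters$cluster_id)
  arch_sc <- names(sc_members)[vapply(sc_members, function(m) {
    sel$domain[[m[1]]] == "archaea"
  }, logical(1))]
  bact_selected <- sel$selected[sel$domain[sel$selected] == "bacteria"]
  bact_universe <- sort(unique(unlist(ko_of_cluster[bact_selected],
    use.names = FALSE
  )))
  sc_kos <- lapply(sc_members, function(m) {
    sort(unique(unlist(ko_of_cluster[m], use.names = FALSE)))
  })
  groups <- vapply(arch_sc, function(sc) {
    if (any(sc_kos[[sc]] %in% bact_universe)) "homologous" else "unique"
  }, character(1))

  ev <- generate_evidence(config, sort(arch_sc), sc_kos)
  syn <- generate_synteny_fixture(config)

  arch_selected <- sel$selected[sel$domain[sel$selected] == "archaea"]
  genes <- unlist(members_l1[arch_selected], use.names = FALSE)
  cluster_of_gene <- stats::setNames(
    rep(arch_selected, lengths(members_l1[arch_selected])), genes
  )
  coverage <- with_stream(
    config$seed, "coverage",
    gen_coverage(config, genes, cluster_of_gene)
  )

  bundle <- list(
    mags = mags, proteins = cp$proteins, clusters = cp$clusters,
    superclusters = superclusters, ko = ko, evidence = ev$bundles,
    features = syn$features, coverage = coverage, targets = syn$targets
  )
  manifest <- list(
    gut_exclusive_cluster_ids = sort(sel$gut_exclusive),
    group_by_supercluster = as.list(groups[sort(names(groups))]),
    expected_final_label = as.list(ev$expected_final_label),
    planted_flank_hits = syn$planted_flank_hits
  )
  paths <- NULL
  if (!is.null(out_dir)) {
    paths <- write_bundle(bundle, manifest, config, out_dir)
  }
  invisible(list(bundle = bundle, manifest = manifest, paths = paths))
}

write_bundle <- function(bundle, manifest, config, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) {
      ann_stop(paste0("cannot create ", out_dir), "archannot_io_error")
    }
  }
  p <- function(f) file.path(out_dir, f)
  write_tsv_deterministic(bundle$mags, p("mag_metadata.tsv"))
  write_protein_fasta(bundle$proteins, p("proteins.fasta"))
  utils::write.table(bundle$clusters, p("clusters_mm2.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  utils::write.table(bundle$superclusters, p("superclusters.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  write_tsv_deterministic(bundle$ko, p("ko_annotations.tsv"))
  write_evidence_bundles(bundle$evidence, p("evidence.json"))
  write_gene_features(bundle$features, p("genes.gff3"),
    ko_path = p("gene_ko.tsv")
  )
  write_tsv_deterministic(bundle$coverage, p("coverage.tsv"))
  writeLines(bundle$targets, p("targets.txt"))
  writeLines(
    jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA, null = "null"),
    p("truth_manifest.json")
  )
  cfg <- unclass(config)
  cfg$flank_plants <- as.list(as.data.frame(cfg$flank_plants))
  cfg$environments <- as.list(cfg$environments)
  cfg$pf_tier_mix <- as.list(cfg$pf_tier_mix)
  cfg$tr_tier_mix <- as.list(cfg$tr_tier_mix)
  cfg$archaeal_cluster_size <- as.list(cfg$archaeal_cluster_size)
  cfg$bacterial_cluster_size <- as.list(cfg$bacterial_cluster_size)
  yaml::write_yaml(cfg, p("config.yaml"))
  invisible(stats::setNames(
    p(c(
      "mag_metadata.tsv", "proteins.fasta", "clusters_mm2.tsv",
      "superclusters.tsv", "ko_annotations.tsv", "evidence.json",
      "genes.gff3", "gene_ko.tsv", "coverage.tsv", "targets.txt",
      "truth_manifest.json", "config.yaml"
    )),
    c(
      "mags", "proteins", "clusters", "superclusters", "ko", "evidence",
      "genes", "gene_ko", "coverage", "targets", "manifest", "config"
    )
  ))
}

#' Read a truth manifest
#'
#' @param path path to `truth_manifest.json`.
#' @return the manifest as a list.
#' @export
read_truth_manifest <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}
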