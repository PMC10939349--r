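# Small in-code fixtures shared across test files.

tiny_mags <- function() {
  as_mag_table(data.frame(
    mag_id = c("M1", "M2", "M3", "M4"),
    domain = c("archaea", "archaea", "archaea", "bacteria"),
    taxonomy = "d__Archaea",
    environment = c("human gut", "human gut", "soil", "human gut"),
    catalog = "TEST"
  ))
}

tiny_proteins <- function() {
  data.frame(
    protein_id = c("p1", "p2", "p3", "p4", "p5", "p6"),
    mag_id = c("M1", "M2", "M3", "M1", "M4", "M4"),
    sequence = c("MKL", "MKLV", "MK", "MKLVA", "MMMM", "MM"),
    length = c(3L, 4L, 2L, 5L, 4L, 2L)
  )
}

tiny_clusters <- function() {
  # c1: gut archaea only; c2: one soil member; c3: gut bacteria
  as_cluster_table(data.frame(
    cluster_id = c("c1", "c1", "c2", "c2", "c3", "c3"),
    member_id = c("p1", "p2", "p3", "p4", "p5", "p6")
  ))
}

# configuration small enough for property loops
small_config <- function(seed = 1, ...) {
  generator_config(
    seed = seed,
    n_archaeal_mags = 12, n_bacterial_mags = 16,
    n_archaeal_clusters = 16, n_bacterial_clusters = 10,
    ko_universe_size = 120,
    n_samples = 3,
    ...
  )
}

# independent brute-force oracle: environment-exclusivity filter as a plain
# scan over (cluster, member, environment) triples
oracle_env_filter <- function(clusters, proteins, mags, target_env) {
  target <- normalize_environment(target_env)
  retained <- character(0)
  for (cid in unique(clusters$cluster_id)) {
    members <- clusters$member_id[clusters$cluster_id == cid]
    ok <- length(members) > 0
    for (m in members) {
      mag <- proteins$mag_id[proteins$protein_id == m]
      env <- mags$environment[mags$mag_id == mag]
      if (length(env) != 1 || env != target) ok <- FALSE
    }
    if (ok) retained <- c(retained, cid)
  }
  sort(retained)
}

# independent brute-force oracle: all-genes overlap scan for flank windows
oracle_flank_ids <- function(features, target_id, window) {
  t <- features[features$gene_id == target_id, , drop = FALSE]
  ws <- max(1, t$start - window)
  we <- t$end + window
  keep <- character(0)
  for (i in seq_len(nrow(features))) {
    g <- features[i, , drop = FALSE]
    if (g$contig_id == t$contig_id && g$start <= we && g$end >= ws) {
      keep <- c(keep, g$gene_id)
    }
  }
  sort(keep)
}

random_gene_features <- function(n_genes, n_contigs = 2, span = 120000) {
  starts <- sort(sample(seq_len(span), n_genes))
  data.frame(
    contig_id = sample(sprintf("ctg%02d", seq_len(n_contigs)), n_genes,
      replace = TRUE
    ),
    gene_id = sprintf("g%04d", seq_len(n_genes)),
    start = starts,
    end = starts + sample(200:1500, n_genes, replace = TRUE),
    strand = sample(c("+", "-"), n_genes, replace = TRUE)
  )
}

# wiring shared by partition-stage tests: selection, KO sets, partition
run_partition_stage <- function(bundle) {
  sel <- run_selection(bundle)
  doms <- cluster_domains(bundle$clusters, bundle$proteins, bundle$mags)
  ckos <- cluster_ko_sets(bundle$clusters, bundle$ko, mode = "union")
  sckos <- supercluster_ko_sets(bundle$superclusters, ckos)
  sc_dom <- vapply(
    split(bundle$superclusters$member_id, bundle$superclusters$cluster_id),
    function(m) doms[[m[1]]], character(1)
  )
  arch_sc <- names(sc_dom)[sc_dom == "archaea"]
  part <- partition_by_ko(
    sckos[arch_sc],
    collect_ko_universe(sel$retained$bacteria, ckos)
  )
  list(selection = sel, partition = part, arch_sc = arch_sc)
}
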