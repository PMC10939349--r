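# Readers and writers for every external format the pipeline touches.
# Downstream modules consume only the plain data frames / lists built here.

#' Read a MAG metadata table
#'
#' Expects a TSV with header columns `mag_id`, `domain`, `taxonomy`,
#' `environment`, `catalog`. Environments are normalized (lowercased,
#' trimmed); `domain` must be `archaea` or `bacteria`.
#'
#' @param path path to a tab-separated metadata file.
#' @return a `data.frame` with one row per MAG.
#' @export
read_mag_metadata <- function(path) {
  df <- utils::read.delim(path,
    sep = "\t", header = TRUE, colClasses = "character",
    check.names = FALSE, quote = ""
  )
  required <- c("mag_id", "domain", "taxonomy", "environment", "catalog")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    format_error(
      "MAG metadata is missing required column(s): ",
      paste(missing, collapse = ", ")
    )
  }
  df <- df[required]
  as_mag_table(df)
}

#' Validate an in-memory MAG metadata table
#'
#' @param df data.frame with columns `mag_id`, `domain`, `taxonomy`,
#'   `environment`, `catalog`.
#' @return the validated data.frame (environments normalized).
#' @export
as_mag_table <- function(df) {
  df$domain <- normalize_environment(df$domain)
  bad_domain <- !df$domain %in% c("archaea", "bacteria")
  if (any(bad_domain)) {
    validation_error(
      "unknown domain for MAG(s): ",
      paste(df$mag_id[bad_domain], collapse = ", ")
    )
  }
  df$environment <- normalize_environment(df$environment)
  if (any(df$environment == "" | is.na(df$environment))) {
    validation_error(
      "empty environment after normalization for MAG(s): ",
      paste(df$mag_id[df$environment == "" | is.na(df$environment)],
        collapse = ", "
      )
    )
  }
  dup <- df$mag_id[duplicated(df$mag_id)]
  if (length(dup) > 0) {
    validation_error("duplicate mag_id: ", paste(unique(dup), collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Read a cluster membership table
#'
#' Two-column TSV (`cluster_id`, `member_id`), headerless as emitted by
#' greedy sequence clustering (level `mm2`, members are protein ids) or
#' MinHash superclustering (level `sourmash`, members are level-1 cluster
#' ids). A header line naming the two columns is tolerated. Duplicate
#' memberships within a cluster are collapsed with a warning; a member
#' appearing in two clusters at the same level is an error, since a
#' clustering is a partition.
#'
#' @param path path to the TSV file.
#' @param level `"mm2"` or `"sourmash"`; recorded as an attribute.
#' @return a `data.frame` with columns `cluster_id`, `member_id`.
#' @export
read_cluster_table <- function(path, level = c("mm2", "sourmash")) {
  level <- match.arg(level)
  if (file.size(path) == 0) {
    df <- data.frame(cluster_id = character(), member_id = character())
    attr(df, "level") <- level
    return(df)
  }
  df <- utils::read.delim(path,
    sep = "\t", header = FALSE, colClasses = "character",
    col.names = c("cluster_id", "member_id"), quote = ""
  )
  if (nrow(df) > 0 && df$cluster_id[1] == "cluster_id" &&
    df$member_id[1] == "member_id") {
    df <- df[-1, , drop = FALSE]
  }
  as_cluster_table(df, level = level)
}

#' Validate an in-memory cluster membership table
#'
#' @param df data.frame with columns `cluster_id`, `member_id`.
#' @param level `"mm2"` or `"sourmash"`.
#' @return validated data.frame (duplicates collapsed).
#' @export
as_cluster_table <- function(df, level = "mm2") {
  dup_pair <- duplicated(df[c("cluster_id", "member_id")])
  if (any(dup_pair)) {
    warning(
      "collapsed ", sum(dup_pair), " duplicate membership row(s) in ",
      level, " cluster table"
    )
    df <- df[!dup_pair, , drop = FALSE]
  }
  multi <- unique(df$member_id[duplicated(df$member_id)])
  if (length(multi) > 0) {
    validation_error(
      "member(s) assigned to more than one ", level, " cluster: ",
      paste(utils::head(multi, 5), collapse = ", ")
    )
  }
  rownames(df) <- NULL
  attr(df, "level") <- level
  df
}

#' Read protein sequences with MAG provenance from FASTA
#'
#' Headers are of the form `>protein_id mag=MAG0001`; the `mag=` tag records
#' which MAG encodes the protein.
#'
#' @param path path to a protein FASTA file.
#' @return data.frame with columns `protein_id`, `mag_id`, `length`,
#'   `sequence`.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  protein_id <- sub("[[:space:]].*$", "", headers)
  mag_id <- ifelse(grepl("mag=", headers),
    sub("^.*mag=([^[:space:]]+).*$", "\\1", headers),
    NA_character_
  )
  dup <- protein_id[duplicated(protein_id)]
  if (length(dup) > 0) {
    validation_error(
      "duplicate protein_id in FASTA: ",
      paste(unique(dup), collapse = ", ")
    )
  }
  data.frame(
    protein_id = protein_id, mag_id = mag_id,
    length = Biostrings::width(aa),
    sequence = as.character(aa)
  )
}

#' Write protein sequences with MAG provenance to FASTA
#'
#' @param proteins data.frame with columns `protein_id`, `mag_id`,
#'   `sequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- paste0(proteins$protein_id, " mag=", proteins$mag_id)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read a KEGG ortholog annotation table
#'
#' TSV with header columns `subject_id`, `ko_id`; one row per (subject, KO)
#' pair. Subjects may be proteins or clusters. Every KO id must match the
#' `K#####` pattern.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `subject_id`, `ko_id`.
#' @export
read_ko_table <- function(path) {
  df <- utils::read.delim(path,
    sep = "\t", header = TRUE, colClasses = "character",
    check.names = FALSE, quote = ""
  )
  missing <- setdiff(c("subject_id", "ko_id"), names(df))
  if (length(missing) > 0) {
    format_error(
      "KO table is missing required column(s): ",
      paste(missing, collapse = ", ")
    )
  }
  bad <- !grepl("^K[0-9]{5}$", df$ko_id)
  if (any(bad)) {
    validation_error(
      "malformed KO id(s): ",
      paste(utils::head(unique(df$ko_id[bad]), 5), collapse = ", ")
    )
  }
  df <- unique(df[c("subject_id", "ko_id")])
  rownames(df) <- NULL
  df
}

# ---- evidence bundles ------------------------------------------------------

check_range <- function(x, lo, hi, what, subject) {
  x <- as.numeric(x)
  if (length(x) == 0 || is.na(x) || x < lo || x > hi) {
    validation_error(
      "evidence for subject ", subject, ": ", what, " (", x,
      ") outside [", lo, ", ", hi, "]"
    )
  }
  x
}

validate_pf_match <- function(m, subject) {
  if (is.null(m$kind) || !m$kind %in% c("sequence_vs_pdb", "template_3d")) {
    validation_error(
      "evidence for subject ", subject, ": PF match kind must be ",
      "'sequence_vs_pdb' or 'template_3d'"
    )
  }
  e <- as.numeric(m$e_value)
  if (is.na(e) || e < 0) {
    validation_error(
      "evidence for subject ", subject, ": PF e_value (", m$e_value,
      ") must be non-negative"
    )
  }
  pid <- check_range(m$percent_identity, 0, 100, "PF percent_identity", subject)
  seg <- as.numeric(m$longest_fitted_segment)
  qlen <- as.numeric(m$query_length)
  if (is.na(qlen) || qlen <= 0 || is.na(seg) || seg < 0 || seg > qlen) {
    validation_error(
      "evidence for subject ", subject,
      ": longest_fitted_segment must satisfy 0 <= segment <= query_length"
    )
  }
  data.frame(
    kind = m$kind, e_value = e, percent_identity = pid,
    longest_fitted_segment = seg, query_length = qlen,
    function_label = as.character(m$function_label)
  )
}

validate_tr_hit <- function(h, subject) {
  data.frame(
    template_id = as.character(h$template_id),
    confidence = check_range(h$confidence, 0, 1, "TR confidence", subject),
    e_value = {
      e <- as.numeric(h$e_value)
      if (is.na(e) || e < 0) {
        validation_error(
          "evidence for subject ", subject, ": TR e_value must be non-negative"
        )
      }
      e
    },
    coverage = check_range(h$coverage, 0, 1, "TR coverage", subject),
    identity = check_range(h$identity, 0, 1, "TR identity", subject),
    tm_score = check_range(h$tm_score, 0, 1, "TR tm_score", subject),
    function_label = as.character(h$function_label)
  )
}

validate_df_prediction <- function(p, subject) {
  data.frame(
    term_id = as.character(p$term_id),
    score = check_range(p$score, 0, 1, "DF score", subject),
    term_name = as.character(p$term_name)
  )
}

empty_pf <- function() {
  data.frame(
    kind = character(), e_value = numeric(), percent_identity = numeric(),
    longest_fitted_segment = numeric(), query_length = numeric(),
    function_label = character()
  )
}

empty_tr <- function() {
  data.frame(
    template_id = character(), confidence = numeric(), e_value = numeric(),
    coverage = numeric(), identity = numeric(), tm_score = numeric(),
    function_label = character()
  )
}

empty_df_pred <- function() {
  data.frame(term_id = character(), score = numeric(), term_name = character())
}

#' Construct a validated evidence bundle
#'
#' An evidence bundle collects, for one annotation subject (typically a
#' supercluster representative), the sequence-based KEGG annotation and the
#' parsed structure-based evidence: ProFunc-style structure matches
#' (`pf_matches`), trRosetta-style template hits (`tr_hits`), and
#' DeepFRI-style term predictions (`df_predictions`). Any slot may be empty.
#'
#' @param subject_id subject identifier.
#' @param sequence_ko `NULL`, or a list with `ko_ids` (character vector of
#'   `K#####` ids), optional `label` (human-readable function), and optional
#'   `source`.
#' @param pf_matches data.frame (or list of records) with columns `kind`,
#'   `e_value`, `percent_identity`, `longest_fitted_segment`,
#'   `query_length`, `function_label`.
#' @param tr_hits data.frame (or list of records) with columns
#'   `template_id`, `confidence`, `e_value`, `coverage`, `identity`,
#'   `tm_score`, `function_label`.
#' @param df_predictions data.frame (or list of records) with columns
#'   `term_id`, `score`, `term_name`.
#' @return an object of class `evidence_bundle`.
#' @export
evidence_bundle <- function(subject_id, sequence_ko = NULL,
                            pf_matches = NULL, tr_hits = NULL,
                            df_predictions = NULL) {
  as_rows <- function(x) {
    if (is.null(x)) {
      list()
    } else if (is.data.frame(x)) {
      lapply(seq_len(nrow(x)), function(i) as.list(x[i, , drop = FALSE]))
    } else {
      x
    }
  }
  pf <- lapply(as_rows(pf_matches), validate_pf_match, subject = subject_id)
  tr <- lapply(as_rows(tr_hits), validate_tr_hit, subject = subject_id)
  dfp <- lapply(as_rows(df_predictions), validate_df_prediction,
    subject = subject_id
  )
  if (!is.null(sequence_ko)) {
    ko_ids <- as.character(unlist(sequence_ko$ko_ids))
    bad <- !grepl("^K[0-9]{5}$", ko_ids)
    if (any(bad)) {
      validation_error(
        "evidence for subject ", subject_id, ": malformed KO id(s): ",
        paste(ko_ids[bad], collapse = ", ")
      )
    }
    sequence_ko <- list(
      ko_ids = ko_ids,
      label = if (is.null(sequence_ko$label)) {
        NA_character_
      } else {
        as.character(sequence_ko$label)
      },
      source = if (is.null(sequence_ko$source)) {
        NA_character_
      } else {
        as.character(sequence_ko$source)
      }
    )
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      sequence_ko = sequence_ko,
      pf_matches = if (length(pf) > 0) do.call(rbind, pf) else empty_pf(),
      tr_hits = if (length(tr) > 0) do.call(rbind, tr) else empty_tr(),
      df_predictions = if (length(dfp) > 0) {
        do.call(rbind, dfp)
      } else {
        empty_df_pred()
      }
    ),
    class = "evidence_bundle"
  )
}

#' Read evidence bundles from JSON
#'
#' The file is a JSON array; each element carries `subject_id` plus the four
#' evidence slots described in [evidence_bundle()]. All numeric fields are
#' range-checked; a violation is reported with the offending `subject_id`.
#'
#' @param path path to the JSON file.
#' @return a named list of `evidence_bundle` objects.
#' @export
read_evidence_bundles <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  bundles <- lapply(raw, function(el) {
    if (is.null(el$subject_id)) {
      format_error("evidence bundle without subject_id")
    }
    evidence_bundle(
      subject_id = el$subject_id,
      sequence_ko = el$sequence_ko,
      pf_matches = el$pf_matches,
      tr_hits = el$tr_hits,
      df_predictions = el$df_predictions
    )
  })
  names(bundles) <- vapply(bundles, function(b) b$subject_id, character(1))
  bundles
}

#' Write evidence bundles to JSON
#'
#' @param bundles list of `evidence_bundle` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_evidence_bundles <- function(bundles, path) {
  payload <- lapply(unname(bundles), function(b) {
    list(
      subject_id = b$subject_id,
      sequence_ko = b$sequence_ko,
      pf_matches = b$pf_matches,
      tr_hits = b$tr_hits,
      df_predictions = b$df_predictions
    )
  })
  json <- jsonlite::toJSON(payload,
    auto_unbox = TRUE, digits = NA, null = "null", dataframe = "rows"
  )
  writeLines(json, path)
  invisible(path)
}

# ---- gene features and coverage -------------------------------------------

#' Read gene features from GFF3 (Prodigal dialect)
#'
#' Coordinates are 1-based inclusive throughout; the `ID` attribute is taken
#' as the gene id. KEGG orthologs are attached from an optional sidecar TSV
#' (`gene_id`, `ko_id`).
#'
#' @param path path to a GFF3 file.
#' @param ko_path optional path to the gene-to-KO sidecar TSV.
#' @return data.frame with columns `contig_id`, `gene_id`, `start`, `end`,
#'   `strand`, and a list-column `ko_ids`.
#' @export
read_gene_features <- function(path, ko_path = NULL) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) {
      validation_error("malformed GFF3 (", conditionMessage(e), ")")
    }
  )
  ids <- S4Vectors::mcols(gr)$ID
  if (is.null(ids) || any(is.na(ids))) {
    format_error("GFF3 features must carry an ID attribute (gene_id)")
  }
  df <- data.frame(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    gene_id = as.character(ids),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  if (any(df$end < df$start)) {
    validation_error(
      "gene feature(s) with end < start: ",
      paste(df$gene_id[df$end < df$start], collapse = ", ")
    )
  }
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup) > 0) {
    validation_error(
      "duplicate gene id(s) in GFF3: ", paste(unique(dup), collapse = ", ")
    )
  }
  ko_map <- list()
  if (!is.null(ko_path)) {
    ko <- read_ko_table_generic(ko_path, id_col = "gene_id")
    ko_map <- split(ko$ko_id, ko$gene_id)
  }
  df$ko_ids <- unname(lapply(df$gene_id, function(g) {
    v <- ko_map[[g]]
    if (is.null(v)) character(0) else sort(unique(v))
  }))
  df[order(df$contig_id, df$start, df$gene_id), , drop = FALSE] -> df
  rownames(df) <- NULL
  df
}

read_ko_table_generic <- function(path, id_col) {
  df <- utils::read.delim(path,
    sep = "\t", header = TRUE, colClasses = "character",
    check.names = FALSE, quote = ""
  )
  missing <- setdiff(c(id_col, "ko_id"), names(df))
  if (length(missing) > 0) {
    format_error(
      "KO sidecar is missing required column(s): ",
      paste(missing, collapse = ", ")
    )
  }
  bad <- !grepl("^K[0-9]{5}$", df$ko_id)
  if (any(bad)) {
    validation_error(
      "malformed KO id(s): ",
      paste(utils::head(unique(df$ko_id[bad]), 5), collapse = ", ")
    )
  }
  df
}

#' Write gene features to GFF3
#'
#' @param features data.frame as returned by [read_gene_features()] (the
#'   `ko_ids` column, if present, is written to the sidecar only).
#' @param path output GFF3 path.
#' @param ko_path optional output path for the gene-to-KO sidecar TSV.
#' @return `path`, invisibly.
#' @export
write_gene_features <- function(features, path, ko_path = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = features$contig_id,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = features$strand
  )
  S4Vectors::mcols(gr)$source <- "Prodigal_v2.6.3"
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$ID <- features$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  if (!is.null(ko_path)) {
    ko <- features[c("gene_id", "ko_ids")]
    long <- data.frame(
      gene_id = rep(ko$gene_id, lengths(ko$ko_ids)),
      ko_id = unlist(ko$ko_ids, use.names = FALSE)
    )
    write_tsv_deterministic(long, ko_path)
  }
  invisible(path)
}

#' Read per-gene mean coverage records
#'
#' TSV with header columns `gene_id`, `sample_id`, `mean_coverage`
#' (mosdepth-style per-gene summaries, one row per gene and sample).
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `gene_id`, `sample_id`, `mean_coverage`.
#' @export
read_coverage <- function(path) {
  df <- utils::read.delim(path,
    sep = "\t", header = TRUE, check.names = FALSE, quote = ""
  )
  missing <- setdiff(c("gene_id", "sample_id", "mean_coverage"), names(df))
  if (length(missing) > 0) {
    format_error(
      "coverage table is missing required column(s): ",
      paste(missing, collapse = ", ")
    )
  }
  df$mean_coverage <- as.numeric(df$mean_coverage)
  bad <- is.na(df$mean_coverage) | df$mean_coverage < 0
  if (any(bad)) {
    validation_error(
      "negative or non-numeric mean_coverage for gene(s): ",
      paste(utils::head(df$gene_id[bad], 5), collapse = ", ")
    )
  }
  df[c("gene_id", "sample_id", "mean_coverage")]
}

# ---- deterministic result writing -----------------------------------------

format_sig6 <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

#' Write a result table deterministically
#'
#' Fixed column order (as given), tab separation, floats formatted at six
#' significant digits: the same input always yields byte-identical output.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_deterministic <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.list(out[[col]])) {
      out[[col]] <- vapply(
        out[[col]],
        function(v) paste(v, collapse = ","), character(1)
      )
    } else if (is.double(out[[col]])) {
      out[[col]] <- format_sig6(out[[col]])
    }
  }
  utils::write.table(out, path,
    sep = "\t", quote = FALSE, row.names = FALSE, na = "NA"
  )
  invisible(path)
}

#' Read a result table written by [write_tsv_deterministic()]
#'
#' @param path path to the TSV file.
#' @return data.frame.
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
}

#' Write a set of result tables
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if absent).
#' @return named character vector of written paths, invisibly.
#' @export
write_results <- function(tables, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) ann_stop(paste0("cannot create ", out_dir), "archannot_io_error")
  }
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv_deterministic(tables[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}

#' Load a complete input bundle from a directory
#'
#' Reads the files written by [generate_dataset()] (or assembled by hand in
#' the same layout) into the in-memory bundle consumed by the pipeline
#' stages.
#'
#' @param dir directory containing `mag_metadata.tsv`, `proteins.fasta`,
#'   `clusters_mm2.tsv`, `superclusters.tsv`, `ko_annotations.tsv`,
#'   `evidence.json`, `genes.gff3`, `gene_ko.tsv`, `coverage.tsv`,
#'   `targets.txt`.
#' @return a named list (`mags`, `proteins`, `clusters`, `superclusters`,
#'   `ko`, `evidence`, `features`, `coverage`, `targets`).
#' @export
load_input_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  need <- function(f) {
    if (!file.exists(p(f))) format_error("input bundle is missing ", f)
    p(f)
  }
  list(
    mags = read_mag_metadata(need("mag_metadata.tsv")),
    proteins = read_protein_fasta(need("proteins.fasta")),
    clusters = read_cluster_table(need("clusters_mm2.tsv"), level = "mm2"),
    superclusters = read_cluster_table(need("superclusters.tsv"),
      level = "sourmash"
    ),
    ko = read_ko_table(need("ko_annotations.tsv")),
    evidence = read_evidence_bundles(need("evidence.json")),
    features = read_gene_features(need("genes.gff3"), ko_path = p("gene_ko.tsv")),
    coverage = read_coverage(need("coverage.tsv")),
    targets = readLines(need("targets.txt"))
  )
}

#' Validate an input bundle directory
#'
#' Parses every file of a bundle and cross-checks referential integrity:
#' every cluster member resolves to a protein, every protein's MAG to the
#' metadata table, every supercluster member to a cluster.
#'
#' @param dir bundle directory (see [load_input_bundle()]).
#' @return a named list of record counts, invisibly.
#' @export
validate_input_bundle <- function(dir) {
  b <- load_input_bundle(dir)
  orphan <- setdiff(b$clusters$member_id, b$proteins$protein_id)
  if (length(orphan) > 0) {
    validation_error(
      "cluster member(s) without protein record: ",
      paste(utils::head(orphan, 5), collapse = ", ")
    )
  }
  orphan_mag <- setdiff(b$proteins$mag_id, b$mags$mag_id)
  if (length(orphan_mag) > 0) {
    validation_error(
      "protein(s) from unknown MAG: ",
      paste(utils::head(orphan_mag, 5), collapse = ", ")
    )
  }
  orphan_sc <- setdiff(b$superclusters$member_id, b$clusters$cluster_id)
  if (length(orphan_sc) > 0) {
    validation_error(
      "supercluster member(s) without level-1 cluster: ",
      paste(utils::head(orphan_sc, 5), collapse = ", ")
    )
  }
  invisible(list(
    mags = nrow(b$mags), proteins = nrow(b$proteins),
    clusters = length(unique(b$clusters$cluster_id)),
    superclusters = length(unique(b$superclusters$cluster_id)),
    ko_rows = nrow(b$ko), evidence = length(b$evidence),
    genes = nrow(b$features), coverage_rows = nrow(b$coverage)
  ))
}
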