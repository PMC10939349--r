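# Cluster-level inclusion/exclusion: environment exclusivity, size gates,
# and KEGG-annotation completeness, applied in that order.

member_environments <- function(clusters, proteins, mag_meta) {
  pi <- match(clusters$member_id, proteins$protein_id)
  if (anyNA(pi)) {
    validation_error(
      "cluster member(s) without protein record: ",
      paste(utils::head(clusters$member_id[is.na(pi)], 5), collapse = ", ")
    )
  }
  mi <- match(proteins$mag_id[pi], mag_meta$mag_id)
  if (anyNA(mi)) {
    validation_error(
      "protein(s) from MAG absent in metadata: ",
      paste(utils::head(clusters$member_id[is.na(mi)], 5), collapse = ", ")
    )
  }
  mag_meta$environment[mi]
}

#' Determine the domain of each level-1 cluster
#'
#' Level-1 clusters are built per domain, so a cluster whose members span
#' both archaea and bacteria is rejected as malformed input.
#'
#' @param clusters cluster membership table (`cluster_id`, `member_id`).
#' @param proteins protein table (`protein_id`, `mag_id`).
#' @param mag_meta MAG metadata table.
#' @return named character vector, cluster_id -> `"archaea"`/`"bacteria"`.
#' @export
cluster_domains <- function(clusters, proteins, mag_meta) {
  pi <- match(clusters$member_id, proteins$protein_id)
  if (anyNA(pi)) {
    validation_error(
      "cluster member(s) without protein record: ",
      paste(utils::head(clusters$member_id[is.na(pi)], 5), collapse = ", ")
    )
  }
  mi <- match(proteins$mag_id[pi], mag_meta$mag_id)
  dom <- split(mag_meta$domain[mi], clusters$cluster_id)
  n_dom <- vapply(dom, function(d) length(unique(d)), integer(1))
  if (any(n_dom > 1)) {
    validation_error(
      "cluster(s) mixing archaeal and bacterial members: ",
      paste(names(dom)[n_dom > 1], collapse = ", ")
    )
  }
  vapply(dom, function(d) d[1], character(1))
}

#' Filter clusters by environment exclusivity
#'
#' A cluster is retained iff it has at least one member and **every** member
#' was encoded by a MAG sampled from `target_env` — the gut-exclusivity rule:
#' clusters containing any protein from a MAG sampled in another environment
#' are excluded.
#'
#' @param clusters cluster membership table (`cluster_id`, `member_id`,
#'   members are protein ids).
#' @param proteins protein table (`protein_id`, `mag_id`).
#' @param mag_meta MAG metadata table.
#' @param target_env environment label (normalized before comparison);
#'   default `"human gut"`.
#' @return sorted character vector of retained cluster ids.
#' @export
filter_by_environment <- function(clusters, proteins, mag_meta,
                                  target_env = "human gut") {
  if (nrow(clusters) == 0) {
    return(character(0))
  }
  env <- member_environments(clusters, proteins, mag_meta)
  target <- normalize_environment(target_env)
  all_target <- vapply(
    split(env == target, clusters$cluster_id), all, logical(1)
  )
  as.character(sort(names(all_target)[all_target]))
}

#' Filter clusters by minimum member count
#'
#' Size gates default to 2 proteins per archaeal cluster and 10 per
#' bacterial cluster.
#'
#' @param clusters cluster membership table.
#' @param min_size minimum member count (>= 1).
#' @return sorted character vector of retained cluster ids.
#' @export
filter_by_min_size <- function(clusters, min_size) {
  if (min_size < 1) config_error("min_size must be >= 1")
  n <- table(clusters$cluster_id)
  as.character(sort(names(n)[n >= min_size]))
}

#' Filter clusters by KEGG-annotation completeness
#'
#' In mode `all_members` a cluster is retained iff every member protein has
#' at least one KO; in mode `representative` iff the cluster's
#' representative has at least one KO (useful when annotation tables are
#' effectively cluster-level).
#'
#' @param clusters cluster membership table.
#' @param ko_table KO table (`subject_id` = protein id, `ko_id`).
#' @param mode `"all_members"` (default, strictest reading of "complete
#'   KEGG annotations") or `"representative"`.
#' @param representatives named character vector cluster_id ->
#'   representative protein id; required for mode `"representative"`.
#' @return sorted character vector of retained cluster ids.
#' @export
filter_fully_annotated <- function(clusters, ko_table,
                                   mode = c("all_members", "representative"),
                                   representatives = NULL) {
  mode <- match.arg(mode)
  annotated <- unique(ko_table$subject_id)
  if (mode == "all_members") {
    ok <- vapply(
      split(clusters$member_id %in% annotated, clusters$cluster_id),
      all, logical(1)
    )
    as.character(sort(names(ok)[ok]))
  } else {
    if (is.null(representatives)) {
      config_error("mode 'representative' requires a representatives map")
    }
    ids <- unique(clusters$cluster_id)
    as.character(sort(ids[representatives[ids] %in% annotated]))
  }
}

#' Pick cluster representatives
#'
#' The representative of a cluster is its longest member sequence, ties
#' broken lexicographically by protein id; without sequence lengths the
#' lexicographically smallest protein id is used.
#'
#' @param clusters cluster membership table.
#' @param proteins protein table; a `length` or `sequence` column supplies
#'   lengths when available.
#' @return named character vector cluster_id -> representative protein id.
#' @export
cluster_representatives <- function(clusters, proteins = NULL) {
  len <- rep(0L, nrow(clusters))
  if (!is.null(proteins)) {
    pi <- match(clusters$member_id, proteins$protein_id)
    if (!is.null(proteins$length)) {
      len <- ifelse(is.na(pi), 0L, proteins$length[pi])
    } else if (!is.null(proteins$sequence)) {
      len <- ifelse(is.na(pi), 0L, nchar(proteins$sequence[pi]))
    }
  }
  df <- data.frame(
    cluster_id = clusters$cluster_id, member_id = clusters$member_id,
    len = as.integer(len)
  )
  # longest first, then lexicographic member id
  df <- df[order(df$cluster_id, -df$len, df$member_id), , drop = FALSE]
  first <- !duplicated(df$cluster_id)
  stats::setNames(df$member_id[first], df$cluster_id[first])
}

#' Run the full cluster-selection funnel
#'
#' Applies, per domain and in this order: the environment-exclusivity
#' filter, the per-domain minimum-size gate, and the annotation-completeness
#' gate. Stage counts are recorded per domain; counts are non-increasing
#' along the funnel.
#'
#' @param bundle input bundle (see [load_input_bundle()]); `mags`,
#'   `proteins`, `clusters`, and `ko` are used.
#' @param target_env environment label; default `"human gut"`.
#' @param min_size named vector with per-domain size gates; default
#'   `c(archaea = 2, bacteria = 10)`.
#' @param annotation_mode passed to [filter_fully_annotated()].
#' @return an object of class `selection_report`: a list with `stages`
#'   (data.frame domain/stage/n_clusters) and `retained` (named list of
#'   cluster-id vectors per domain).
#' @export
run_selection <- function(bundle, target_env = "human gut",
                          min_size = c(archaea = 2, bacteria = 10),
                          annotation_mode = c("all_members", "representative")) {
  annotation_mode <- match.arg(annotation_mode)
  domains <- cluster_domains(bundle$clusters, bundle$proteins, bundle$mags)
  reps <- NULL
  if (annotation_mode == "representative") {
    reps <- cluster_representatives(bundle$clusters, bundle$proteins)
  }
  stages <- list()
  retained <- list()
  for (dom in c("archaea", "bacteria")) {
    dom_ids <- names(domains)[domains == dom]
    cl <- bundle$clusters[bundle$clusters$cluster_id %in% dom_ids, ,
      drop = FALSE
    ]
    s1 <- length(dom_ids)
    env_ok <- filter_by_environment(cl, bundle$proteins, bundle$mags,
      target_env = target_env
    )
    cl2 <- cl[cl$cluster_id %in% env_ok, , drop = FALSE]
    size_ok <- filter_by_min_size(cl2, min_size[[dom]])
    cl3 <- cl2[cl2$cluster_id %in% size_ok, , drop = FALSE]
    ann_ok <- filter_fully_annotated(cl3, bundle$ko,
      mode = annotation_mode, representatives = reps
    )
    stages[[dom]] <- data.frame(
      domain = dom,
      stage = c("input", "environment", "size", "annotation"),
      n_clusters = c(s1, length(env_ok), length(size_ok), length(ann_ok))
    )
    retained[[dom]] <- ann_ok
  }
  structure(
    list(stages = do.call(rbind, stages), retained = retained),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Cluster selection funnel\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}
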