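# Unique/homologous partition of archaeal superclusters by KEGG-ortholog
# sharing with the bacterial protein catalog.

#' Derive per-cluster KO sets
#'
#' If the KO table is cluster-level (subjects are cluster ids) it is used
#' directly. For protein-level tables, mode `representative` takes the
#' representative member's KOs (the default: cluster-level annotations are
#' usually propagated from representatives) and mode `union` the union over
#' all members.
#'
#' @param clusters cluster membership table (`cluster_id`, `member_id`).
#' @param ko_table KO table (`subject_id`, `ko_id`).
#' @param mode `"representative"` or `"union"`.
#' @param representatives named map cluster_id -> representative protein id;
#'   required for protein-level tables in mode `"representative"`.
#' @return named list cluster_id -> sorted character vector of KO ids.
#' @export
cluster_ko_sets <- function(clusters, ko_table,
                            mode = c("representative", "union"),
                            representatives = NULL) {
  mode <- match.arg(mode)
  ids <- unique(clusters$cluster_id)
  by_subject <- split(ko_table$ko_id, ko_table$subject_id)
  cluster_level <- any(ids %in% names(by_subject))
  out <- if (cluster_level) {
    lapply(stats::setNames(ids, ids), function(cid) {
      sort(unique(by_subject[[cid]]))
    })
  } else if (mode == "representative") {
    if (is.null(representatives)) {
      config_error("mode 'representative' requires a representatives map")
    }
    lapply(stats::setNames(ids, ids), function(cid) {
      sort(unique(by_subject[[representatives[[cid]]]]))
    })
  } else {
    members <- split(clusters$member_id, clusters$cluster_id)
    lapply(stats::setNames(ids, ids), function(cid) {
      sort(unique(unlist(by_subject[members[[cid]]], use.names = FALSE)))
    })
  }
  lapply(out, function(v) if (is.null(v)) character(0) else v)
}

#' Derive per-supercluster KO sets
#'
#' The KO set of a supercluster is the union over its member level-1
#' clusters.
#'
#' @param superclusters supercluster membership table (`cluster_id` =
#'   supercluster id, `member_id` = level-1 cluster id).
#' @param cluster_kos named list from [cluster_ko_sets()].
#' @return named list supercluster_id -> sorted character vector of KO ids.
#' @export
supercluster_ko_sets <- function(superclusters, cluster_kos) {
  members <- split(superclusters$member_id, superclusters$cluster_id)
  lapply(members, function(m) {
    sort(unique(unlist(cluster_kos[m], use.names = FALSE)))
  })
}

#' Collect the KO universe of a set of clusters
#'
#' @param cluster_ids character vector of cluster ids.
#' @param cluster_kos named list cluster_id -> KO ids.
#' @return sorted character vector: the union of the clusters' KO sets.
#' @export
collect_ko_universe <- function(cluster_ids, cluster_kos) {
  as.character(sort(unique(unlist(cluster_kos[cluster_ids],
    use.names = FALSE
  ))))
}

#' Partition archaeal superclusters by KO sharing with bacteria
#'
#' A supercluster is *homologous* iff its KO set intersects the bacterial KO
#' universe, else *unique*. By default the universe is the global KO set of
#' all retained bacterial clusters; pass a narrower universe for the
#' within-supercluster-only reading.
#'
#' @param arch_super_kos named list supercluster_id -> KO set (from
#'   [supercluster_ko_sets()]); every entry must be non-empty (guaranteed by
#'   the annotation-completeness gate).
#' @param bacterial_universe character vector of bacterial KO ids.
#' @return an object of class `partition_result`: list with sorted
#'   `unique_ids`, `homologous_ids`, and `venn` counts
#'   (`archaea_only`, `shared`, `bacteria_only`) over KO sets.
#' @export
partition_by_ko <- function(arch_super_kos, bacterial_universe) {
  if (length(arch_super_kos) > 0 && is.null(names(arch_super_kos))) {
    validation_error("arch_super_kos must be named by supercluster id")
  }
  empty <- lengths(arch_super_kos) == 0
  if (any(empty)) {
    validation_error(
      "supercluster(s) without KO annotation (annotation gate violated): ",
      paste(names(arch_super_kos)[empty], collapse = ", ")
    )
  }
  shared_flag <- vapply(
    arch_super_kos,
    function(kos) any(kos %in% bacterial_universe), logical(1)
  )
  arch_universe <- sort(unique(unlist(arch_super_kos, use.names = FALSE)))
  shared_kos <- intersect(arch_universe, bacterial_universe)
  structure(
    list(
      unique_ids = as.character(sort(names(arch_super_kos)[!shared_flag])),
      homologous_ids = as.character(sort(names(arch_super_kos)[shared_flag])),
      venn = c(
        archaea_only = length(arch_universe) - length(shared_kos),
        shared = length(shared_kos),
        bacteria_only = length(setdiff(bacterial_universe, arch_universe))
      )
    ),
    class = "partition_result"
  )
}

#' Assign stable u*/h* labels to a partition
#'
#' Unique superclusters receive labels `u1, u2, ...` and homologous ones
#' `h1, h2, ...`. Ordering is lexicographic by supercluster id (`by_id`,
#' the default, reproducible without occurrence data) or by descending
#' member-protein count with ties broken by id (`by_occurrence_desc`).
#'
#' @param partition a `partition_result`.
#' @param order `"by_id"` or `"by_occurrence_desc"`.
#' @param occurrence named numeric vector supercluster_id -> member protein
#'   count; required for `"by_occurrence_desc"`.
#' @return named character vector supercluster_id -> label.
#' @export
assign_labels <- function(partition, order = c("by_id", "by_occurrence_desc"),
                          occurrence = NULL) {
  order <- match.arg(order)
  rank_ids <- function(ids) {
    if (length(ids) == 0) {
      return(character(0))
    }
    if (order == "by_id") {
      sort(ids)
    } else {
      if (is.null(occurrence)) {
        config_error("order 'by_occurrence_desc' requires occurrence counts")
      }
      occ <- occurrence[ids]
      occ[is.na(occ)] <- 0
      ids[base::order(-occ, ids)]
    }
  }
  u <- rank_ids(partition$unique_ids)
  h <- rank_ids(partition$homologous_ids)
  stats::setNames(
    c(
      if (length(u)) paste0("u", seq_along(u)),
      if (length(h)) paste0("h", seq_along(h))
    ),
    c(u, h)
  )
}

#' @export
print.partition_result <- function(x, ...) {
  cat(
    "KO partition:", length(x$unique_ids), "unique,",
    length(x$homologous_ids), "homologous supercluster(s)\n"
  )
  cat(
    "KO venn: archaea-only", x$venn[["archaea_only"]],
    "| shared", x$venn[["shared"]],
    "| bacteria-only", x$venn[["bacteria_only"]], "\n"
  )
  invisible(x)
}
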