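# Gene-neighborhood extraction (10-kb flank windows) and screening for
# horizontal-gene-transfer context motifs.

#' Extract the flank window around a target gene
#'
#' The window spans 10 kb up- and downstream of the target gene's
#' boundaries: `[max(1, start - window), end + window]`, truncated at
#' coordinate 1 and never crossing contig boundaries. Every gene on the
#' target's contig whose span overlaps the window by at least 1 bp is
#' included (both strands), the target itself with offset 0. Offsets are
#' signed: negative for genes ending upstream of the target start, positive
#' for genes starting downstream of the target end, 0 for genes overlapping
#' the target.
#'
#' @param features gene features (see [read_gene_features()]).
#' @param target_gene_id id of the gene of interest.
#' @param window flank length in bp on each side; default 10000.
#' @param mode `"overlap"` (default: >= 1 bp overlap decides membership) or
#'   `"containment"` (gene fully inside the window).
#' @return an object of class `synteny_window`: list with
#'   `target_gene_id`, `contig_id`, `window_start`, `window_end`, and
#'   `flank_genes` (features sorted by start, with an `offset` column).
#' @export
extract_flank_window <- function(features, target_gene_id, window = 10000,
                                 mode = c("overlap", "containment")) {
  mode <- match.arg(mode)
  ti <- match(target_gene_id, features$gene_id)
  if (is.na(ti)) {
    validation_error("unknown target gene: ", target_gene_id)
  }
  target <- features[ti, , drop = FALSE]
  wstart <- max(1, target$start - window)
  wend <- target$end + window
  on_contig <- features[features$contig_id == target$contig_id, ,
    drop = FALSE
  ]
  keep <- if (mode == "overlap") {
    on_contig$start <= wend & on_contig$end >= wstart
  } else {
    on_contig$start >= wstart & on_contig$end <= wend
  }
  flank <- on_contig[keep, , drop = FALSE]
  flank <- flank[order(flank$start, flank$gene_id), , drop = FALSE]
  flank$offset <- ifelse(flank$end < target$start, flank$end - target$start,
    ifelse(flank$start > target$end, flank$start - target$end, 0L)
  )
  rownames(flank) <- NULL
  structure(
    list(
      target_gene_id = target_gene_id,
      contig_id = target$contig_id,
      window_start = wstart,
      window_end = wend,
      flank_genes = flank
    ),
    class = "synteny_window"
  )
}

gene_has_ko <- function(flank, kos) {
  if (is.null(flank$ko_ids)) {
    return(rep(FALSE, nrow(flank)))
  }
  vapply(flank$ko_ids, function(k) any(k %in% kos), logical(1))
}

#' Flag horizontal-gene-transfer context motifs in a flank window
#'
#' The default motifs mirror the bacterial genomic context of the
#' sporulation stage V genes: a site-specific DNA recombinase (K06400)
#' encoded upstream and Type IV pilus assembly proteins (K02662, K02664)
#' encoded downstream of the gene of interest. A flag is raised only if a
#' matching gene lies strictly on the stated side of the target (contig
#' coordinates; set `strand_relative = TRUE` to orient sides by the
#' target's strand).
#'
#' @param window a `synteny_window`.
#' @param upstream_kos KO set for the upstream motif; default `"K06400"`.
#' @param downstream_kos KO set for the downstream motif; default
#'   `c("K02662", "K02664")`.
#' @param strand_relative orient upstream/downstream by the target strand
#'   (default `FALSE`: contig coordinates).
#' @return an object of class `hgt_context_flags`: list with
#'   `upstream_recombinase`, `downstream_pilus`, and `matched` (data.frame
#'   `gene_id`, `ko`, `side`, `offset`).
#' @export
flag_hgt_context <- function(window, upstream_kos = "K06400",
                             downstream_kos = c("K02662", "K02664"),
                             strand_relative = FALSE) {
  flank <- window$flank_genes
  target <- flank[flank$gene_id == window$target_gene_id, , drop = FALSE]
  before <- flank$offset < 0
  after <- flank$offset > 0
  flip <- strand_relative && nrow(target) == 1 && target$strand == "-"
  upstream_side <- if (flip) after else before
  downstream_side <- if (flip) before else after

  up_hit <- gene_has_ko(flank, upstream_kos) & upstream_side
  down_hit <- gene_has_ko(flank, downstream_kos) & downstream_side
  matched <- rbind(
    if (any(up_hit)) {
      data.frame(
        gene_id = flank$gene_id[up_hit],
        ko = vapply(
          flank$ko_ids[up_hit],
          function(k) paste(intersect(k, upstream_kos), collapse = ","),
          character(1)
        ),
        side = "upstream", offset = flank$offset[up_hit]
      )
    },
    if (any(down_hit)) {
      data.frame(
        gene_id = flank$gene_id[down_hit],
        ko = vapply(
          flank$ko_ids[down_hit],
          function(k) paste(intersect(k, downstream_kos), collapse = ","),
          character(1)
        ),
        side = "downstream", offset = flank$offset[down_hit]
      )
    }
  )
  structure(
    list(
      target_gene_id = window$target_gene_id,
      upstream_recombinase = any(up_hit),
      downstream_pilus = any(down_hit),
      matched = if (is.null(matched)) {
        data.frame(
          gene_id = character(), ko = character(), side = character(),
          offset = integer()
        )
      } else {
        matched
      }
    ),
    class = "hgt_context_flags"
  )
}

#' Build a plot-ready synteny table
#'
#' One row per flank gene across the given windows, with signed offset,
#' strand, collapsed KO ids, side relative to the target, and a motif flag.
#' Ordering (target, then start position) is deterministic.
#'
#' @param windows list of `synteny_window` objects.
#' @param upstream_kos,downstream_kos motif KO sets (see
#'   [flag_hgt_context()]).
#' @return data.frame with columns `target_gene_id`, `gene_id`, `offset`,
#'   `strand`, `kos`, `side`, `is_motif`.
#' @export
synteny_table <- function(windows, upstream_kos = "K06400",
                          downstream_kos = c("K02662", "K02664")) {
  rows <- lapply(windows, function(w) {
    flank <- w$flank_genes
    side <- ifelse(flank$offset < 0, "upstream",
      ifelse(flank$offset > 0, "downstream", "overlap")
    )
    is_motif <- (gene_has_ko(flank, upstream_kos) & side == "upstream") |
      (gene_has_ko(flank, downstream_kos) & side == "downstream")
    data.frame(
      target_gene_id = w$target_gene_id,
      gene_id = flank$gene_id,
      offset = flank$offset,
      strand = flank$strand,
      kos = if (is.null(flank$ko_ids)) {
        ""
      } else {
        vapply(flank$ko_ids, paste, character(1), collapse = ",")
      },
      side = side,
      is_motif = is_motif
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
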