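# The reconciliation engine: confidence tiers over structure-match E-values
# and template TM-scores, and the priority ladder that reduces an evidence
# bundle to one final function call per subject.
#
# Tier equivalence (rank 4..0):
#   PF likelihood   E-value        TR significance  TM-score
#   certain         < 1e-6         very_high        > 0.7
#   probable        < 0.01         high             > 0.5
#   possible        < 0.1          medium           > 0.4
#   long_shot       < 10           low              > 0.3
#   none            otherwise      none             otherwise
# All thresholds are strict, exactly as printed; boundary values fall to the
# weaker tier.

PF_TIERS <- c("certain", "probable", "possible", "long_shot", "none")
TR_TIERS <- c("very_high", "high", "medium", "low", "none")
TIER_RANKS <- stats::setNames(
  rep(4:0, 2), c(PF_TIERS, TR_TIERS)
)[c(PF_TIERS, TR_TIERS)]

#' Rank of a confidence tier
#'
#' @param tier tier name (PF likelihood or TR significance vocabulary).
#' @return integer rank, 4 (certain / very_high) down to 0 (none).
#' @export
tier_rank <- function(tier) {
  r <- TIER_RANKS[tier]
  if (anyNA(r)) validation_error("unknown tier: ", paste(tier[is.na(r)]))
  unname(r)
}

#' Classify a structure-match E-value into a PF likelihood tier
#'
#' Bands, all strict: certain `< 1e-6`, probable `< 0.01`, possible
#' `< 0.1`, long shot `< 10`; anything else is `none`.
#'
#' @param e_value non-negative numeric vector of E-values.
#' @return character vector of tier names.
#' @export
classify_pf_likelihood <- function(e_value) {
  e_value <- as.numeric(e_value)
  if (anyNA(e_value) || any(e_value < 0)) {
    validation_error("E-value must be non-negative")
  }
  ifelse(e_value < 1e-6, "certain",
    ifelse(e_value < 0.01, "probable",
      ifelse(e_value < 0.1, "possible",
        ifelse(e_value < 10, "long_shot", "none")
      )
    )
  )
}

#' Classify a template TM-score into a TR significance tier
#'
#' Bands, all strict: very high `> 0.7`, high `> 0.5`, medium `> 0.4`,
#' low `> 0.3`; anything else is `none`.
#'
#' @param tm_score numeric vector in \[0, 1\].
#' @return character vector of tier names.
#' @export
classify_tr_significance <- function(tm_score) {
  tm_score <- as.numeric(tm_score)
  if (anyNA(tm_score) || any(tm_score < 0 | tm_score > 1)) {
    validation_error("TM-score must lie in [0, 1]")
  }
  ifelse(tm_score > 0.7, "very_high",
    ifelse(tm_score > 0.5, "high",
      ifelse(tm_score > 0.4, "medium",
        ifelse(tm_score > 0.3, "low", "none")
      )
    )
  )
}

#' Is a TR template hit admissible?
#'
#' A template is used for prediction only if confidence `> 0.6`, E-value
#' `< 0.001`, and coverage `> 0.3` (all strict).
#'
#' @param confidence numeric in \[0, 1\], or a TR hit row / list carrying
#'   `confidence`, `e_value`, `coverage`.
#' @param e_value,coverage numerics, when `confidence` is given as a scalar.
#' @return logical vector.
#' @export
tr_admissible <- function(confidence, e_value = NULL, coverage = NULL) {
  if (is.list(confidence)) {
    hit <- confidence
    confidence <- hit$confidence
    e_value <- hit$e_value
    coverage <- hit$coverage
  }
  confidence > 0.6 & e_value < 0.001 & coverage > 0.3
}

#' Structure-match coverage ratio
#'
#' The PF coverage of a structure match is the ratio of the longest fitted
#' segment to the query sequence length.
#'
#' @param longest_fitted_segment residue count of the longest fitted
#'   segment.
#' @param query_length residue count of the query (> 0).
#' @return numeric in \[0, 1\].
#' @export
pf_coverage <- function(longest_fitted_segment, query_length) {
  if (any(query_length <= 0)) {
    validation_error("query_length must be positive")
  }
  if (any(longest_fitted_segment < 0 |
    longest_fitted_segment > query_length)) {
    validation_error("longest_fitted_segment must lie in [0, query_length]")
  }
  longest_fitted_segment / query_length
}

# best PF match: one candidate pool over both report sections, lowest
# E-value first, 3D functional templates preferred at equal E-value
best_pf_match <- function(pf_matches) {
  if (nrow(pf_matches) == 0) {
    return(NULL)
  }
  kind_pref <- ifelse(pf_matches$kind == "template_3d", 0L, 1L)
  ord <- order(pf_matches$e_value, kind_pref, pf_matches$function_label)
  pf_matches[ord[1], , drop = FALSE]
}

# best TR hit: admissible hit of highest TM-score; ties broken by coverage,
# identity, then template id for determinism
best_tr_hit <- function(tr_hits) {
  if (nrow(tr_hits) == 0) {
    return(NULL)
  }
  adm <- tr_hits[tr_admissible(tr_hits), , drop = FALSE]
  if (nrow(adm) == 0) {
    return(NULL)
  }
  ord <- order(-adm$tm_score, -adm$coverage, -adm$identity, adm$template_id)
  adm[ord[1], , drop = FALSE]
}

#' Tokenize a function label for agreement checks
#'
#' Case-insensitive word tokens of length >= 4, since the sequence- and
#' structure-annotation vocabularies word the same function differently.
#'
#' @param x character vector of labels.
#' @return list of character vectors of tokens.
#' @export
label_tokens <- function(x) {
  lapply(strsplit(tolower(as.character(x)), "[^a-z0-9]+"), function(t) {
    unique(t[nchar(t) >= 4])
  })
}

labels_agree <- function(a, b, match = c("token", "exact")) {
  match <- match.arg(match)
  if (is.na(a) || is.na(b) || a == "" || b == "") {
    return(FALSE)
  }
  if (match == "exact") {
    return(tolower(a) == tolower(b))
  }
  length(intersect(label_tokens(a)[[1]], label_tokens(b)[[1]])) > 0
}

#' Reconcile an evidence bundle into a consensus annotation
#'
#' Deterministic application of the priority ladder:
#'
#' 1. The best PF match is drawn from one candidate pool over both report
#'    sections (lowest E-value, 3D templates preferred at ties); PF may
#'    assign a function only at tier *certain*. The best TR hit is the
#'    admissible hit of highest TM-score.
#' 2. Both present with the same function label (case-insensitive):
#'    source `consensus`, tier = the higher-ranked of the two.
#' 3. Both present with different labels: PF below *certain* cannot assign,
#'    so TR wins; likewise TR wins when the PF report has no 3D functional
#'    hits; otherwise the higher tier rank wins, and at equal rank the
#'    higher coverage, then the higher identity, then TR (final
#'    deterministic tie-break).
#' 4. Exactly one present: that source (PF only at tier *certain*).
#' 5. `df_supported` is set when some DF prediction with score > 0.7 shares
#'    a word token (>= 4 characters) with the final label; DF never sets
#'    the label itself.
#' 6. `agreement` compares the structure call with the sequence KO label by
#'    the same token rule: `consistent`, `disparate`, `structure_only`,
#'    `sequence_only`, or `unannotated`.
#'
#' @param bundle an `evidence_bundle`.
#' @param agreement_match `"token"` (default) or `"exact"` label comparison
#'   for steps 5-6.
#' @return one-row data.frame: `subject_id`, `final_label`, `source`,
#'   `tier`, `tier_rank`, `df_supported`, `agreement`.
#' @export
reconcile <- function(bundle, agreement_match = c("token", "exact")) {
  agreement_match <- match.arg(agreement_match)
  stopifnot(inherits(bundle, "evidence_bundle"))
  pf <- best_pf_match(bundle$pf_matches)
  tr <- best_tr_hit(bundle$tr_hits)
  has_3d <- any(bundle$pf_matches$kind == "template_3d")

  pf_tier <- if (!is.null(pf)) classify_pf_likelihood(pf$e_value) else NULL
  tr_tier <- if (!is.null(tr)) classify_tr_significance(tr$tm_score) else NULL

  take <- function(source, label, tier) {
    list(source = source, label = label, tier = tier, rank = tier_rank(tier))
  }
  res <- if (!is.null(pf) && !is.null(tr)) {
    if (tolower(pf$function_label) == tolower(tr$function_label)) {
      hi <- if (tier_rank(tr_tier) >= tier_rank(pf_tier)) tr_tier else pf_tier
      take("consensus", tr$function_label, hi)
    } else if (pf_tier != "certain") {
      take("TR", tr$function_label, tr_tier)
    } else if (!has_3d) {
      take("TR", tr$function_label, tr_tier)
    } else if (tier_rank(tr_tier) > tier_rank(pf_tier)) {
      take("TR", tr$function_label, tr_tier)
    } else if (tier_rank(pf_tier) > tier_rank(tr_tier)) {
      take("PF", pf$function_label, pf_tier)
    } else {
      pf_cov <- pf_coverage(pf$longest_fitted_segment, pf$query_length)
      pf_ident <- pf$percent_identity / 100
      if (tr$coverage > pf_cov) {
        take("TR", tr$function_label, tr_tier)
      } else if (pf_cov > tr$coverage) {
        take("PF", pf$function_label, pf_tier)
      } else if (tr$identity >= pf_ident) {
        take("TR", tr$function_label, tr_tier)
      } else {
        take("PF", pf$function_label, pf_tier)
      }
    }
  } else if (!is.null(tr)) {
    take("TR", tr$function_label, tr_tier)
  } else if (!is.null(pf) && pf_tier == "certain") {
    take("PF", pf$function_label, pf_tier)
  } else {
    list(source = "none", label = "unannotated", tier = "none", rank = 0L)
  }

  df_supported <- FALSE
  if (res$source != "none" && nrow(bundle$df_predictions) > 0) {
    strong <- bundle$df_predictions[bundle$df_predictions$score > 0.7, ,
      drop = FALSE
    ]
    df_supported <- any(vapply(
      strong$term_name,
      function(tn) labels_agree(tn, res$label, match = agreement_match),
      logical(1)
    ))
  }

  seq_present <- !is.null(bundle$sequence_ko) &&
    length(bundle$sequence_ko$ko_ids) > 0
  seq_label <- if (seq_present) {
    lbl <- bundle$sequence_ko$label
    if (is.na(lbl) || lbl == "") {
      paste(bundle$sequence_ko$ko_ids, collapse = " ")
    } else {
      lbl
    }
  } else {
    NA_character_
  }
  agreement <- if (res$source != "none" && seq_present) {
    if (labels_agree(res$label, seq_label, match = agreement_match)) {
      "consistent"
    } else {
      "disparate"
    }
  } else if (res$source != "none") {
    "structure_only"
  } else if (seq_present) {
    "sequence_only"
  } else {
    "unannotated"
  }

  data.frame(
    subject_id = bundle$subject_id,
    final_label = res$label,
    source = res$source,
    tier = res$tier,
    tier_rank = res$rank,
    df_supported = df_supported,
    agreement = agreement
  )
}

#' Annotate all subjects
#'
#' Applies [reconcile()] to each bundle and assembles one row per subject.
#' Subjects listed in `labels` but lacking a bundle produce a warning and an
#' unannotated row. Rows are ordered by label (prefix, then index), else by
#' subject id.
#'
#' @param bundles named list of `evidence_bundle` objects.
#' @param labels optional named map subject_id -> `u*`/`h*` label (from
#'   [assign_labels()]).
#' @param groups optional named map subject_id -> `unique`/`homologous`.
#' @param agreement_match passed to [reconcile()].
#' @return data.frame with columns `subject_id`, `label`, `group`,
#'   `final_label`, `source`, `tier`, `tier_rank`, `df_supported`,
#'   `agreement`.
#' @export
annotate_all <- function(bundles, labels = NULL, groups = NULL,
                         agreement_match = c("token", "exact")) {
  agreement_match <- match.arg(agreement_match)
  subjects <- if (!is.null(labels)) names(labels) else names(bundles)
  if (length(subjects) == 0) {
    return(data.frame(
      subject_id = character(), label = character(), group = character(),
      final_label = character(), source = character(), tier = character(),
      tier_rank = integer(), df_supported = logical(),
      agreement = character()
    ))
  }
  missing <- setdiff(subjects, names(bundles))
  if (length(missing) > 0) {
    warning(
      "no evidence bundle for subject(s): ",
      paste(missing, collapse = ", "), "; recorded as unannotated"
    )
  }
  rows <- lapply(subjects, function(s) {
    if (s %in% names(bundles)) {
      reconcile(bundles[[s]], agreement_match = agreement_match)
    } else {
      data.frame(
        subject_id = s, final_label = "unannotated", source = "none",
        tier = "none", tier_rank = 0L, df_supported = FALSE,
        agreement = "unannotated"
      )
    }
  })
  out <- do.call(rbind, rows)
  out$label <- if (!is.null(labels)) unname(labels[out$subject_id]) else NA
  out$group <- if (!is.null(groups)) unname(groups[out$subject_id]) else NA
  if (!is.null(labels)) {
    prefix <- sub("^([a-z]+).*$", "\\1", out$label)
    idx <- suppressWarnings(as.integer(sub("^[a-z]+", "", out$label)))
    out <- out[order(prefix, idx, out$subject_id), , drop = FALSE]
  } else {
    out <- out[order(out$subject_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  out[c(
    "subject_id", "label", "group", "final_label", "source", "tier",
    "tier_rank", "df_supported", "agreement"
  )]
}
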