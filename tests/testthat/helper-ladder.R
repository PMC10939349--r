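# Independent table-driven interpreter of the evidence-reconciliation rules,
# plus a bundle builder over abstract tier descriptors. Kept structurally
# different from the package implementation on purpose: expected outcomes are
# looked up from an ordered rule table over descriptor fields, never computed
# from E-values or TM-scores.

LADDER_RANK <- c(
  certain = 4, probable = 3, possible = 2, long_shot = 1, none = 0,
  very_high = 4, high = 3, medium = 2, low = 1
)

# descriptor fields: pf_tier ("absent", "certain", ..., "none"),
# tr_tier ("absent", "inadmissible", "very_high", ..., "low"),
# labels_equal, pf_is_3d, pf_cov, tr_cov, pf_ident (0-1), tr_ident
ladder_oracle <- function(d) {
  pf_present <- d$pf_tier != "absent"
  tr_present <- !d$tr_tier %in% c("absent", "inadmissible")
  pick <- function(source) {
    label <- switch(source,
      consensus = ,
      PF = d$pf_label,
      TR = d$tr_label,
      none = "unannotated"
    )
    tier <- switch(source,
      consensus = if (LADDER_RANK[[d$tr_tier]] >= LADDER_RANK[[d$pf_tier]]) {
        d$tr_tier
      } else {
        d$pf_tier
      },
      PF = d$pf_tier,
      TR = d$tr_tier,
      none = "none"
    )
    list(source = source, label = label, tier = tier)
  }
  rules <- list(
    function() if (!pf_present && !tr_present) pick("none"),
    function() if (!pf_present) pick("TR"),
    function() {
      if (!tr_present) {
        if (d$pf_tier == "certain") pick("PF") else pick("none")
      }
    },
    function() if (d$labels_equal) pick("consensus"),
    function() if (d$pf_tier != "certain") pick("TR"),
    function() if (!d$pf_is_3d) pick("TR"),
    function() if (LADDER_RANK[[d$tr_tier]] < 4) pick("PF"),
    function() if (d$tr_cov > d$pf_cov) pick("TR"),
    function() if (d$pf_cov > d$tr_cov) pick("PF"),
    function() if (d$tr_ident >= d$pf_ident) pick("TR"),
    function() pick("PF")
  )
  for (r in rules) {
    res <- r()
    if (!is.null(res)) {
      return(res)
    }
  }
}

# representative score values strictly inside each tier band
PF_TIER_EVALUE <- c(
  certain = 1e-8, probable = 1e-4, possible = 0.05, long_shot = 1,
  none = 50
)
TR_TIER_TM <- c(very_high = 0.8, high = 0.6, medium = 0.45, low = 0.35)

descriptor_bundle <- function(d, subject = "s1") {
  pf <- NULL
  if (d$pf_tier != "absent") {
    qlen <- 200
    pf <- data.frame(
      kind = if (d$pf_is_3d) "template_3d" else "sequence_vs_pdb",
      e_value = PF_TIER_EVALUE[[d$pf_tier]],
      percent_identity = d$pf_ident * 100,
      longest_fitted_segment = round(d$pf_cov * qlen),
      query_length = qlen,
      function_label = d$pf_label
    )
  }
  tr <- NULL
  if (d$tr_tier == "inadmissible") {
    tr <- data.frame(
      template_id = "tmpl", confidence = 0.5, e_value = 1e-4,
      coverage = d$tr_cov, identity = d$tr_ident, tm_score = 0.8,
      function_label = d$tr_label
    )
  } else if (d$tr_tier != "absent") {
    tr <- data.frame(
      template_id = "tmpl", confidence = 0.8, e_value = 1e-4,
      coverage = d$tr_cov, identity = d$tr_ident,
      tm_score = TR_TIER_TM[[d$tr_tier]],
      function_label = d$tr_label
    )
  }
  evidence_bundle(subject, pf_matches = pf, tr_hits = tr)
}

enumerate_descriptors <- function() {
  grid <- expand.grid(
    pf_tier = c("absent", "certain", "probable", "possible", "long_shot",
      "none"),
    tr_tier = c("absent", "inadmissible", "very_high", "high", "medium",
      "low"),
    labels_equal = c(TRUE, FALSE),
    pf_is_3d = c(TRUE, FALSE),
    cov_case = c("tr_gt", "pf_gt", "tie_ident_tr", "tie_ident_pf"),
    stringsAsFactors = FALSE
  )
  lapply(seq_len(nrow(grid)), function(i) {
    g <- as.list(grid[i, , drop = FALSE])
    covs <- switch(g$cov_case,
      tr_gt = list(pf_cov = 0.5, tr_cov = 0.8, pf_ident = 0.4,
        tr_ident = 0.4),
      pf_gt = list(pf_cov = 0.8, tr_cov = 0.5, pf_ident = 0.4,
        tr_ident = 0.4),
      tie_ident_tr = list(pf_cov = 0.5, tr_cov = 0.5, pf_ident = 0.3,
        tr_ident = 0.6),
      tie_ident_pf = list(pf_cov = 0.5, tr_cov = 0.5, pf_ident = 0.6,
        tr_ident = 0.3)
    )
    c(g, covs, list(
      pf_label = "alpha amylase domain",
      tr_label = if (g$labels_equal) {
        "alpha amylase domain"
      } else {
        "beta lactamase fold"
      }
    ))
  })
}

random_evidence_bundle <- function(i) {
  pf_n <- sample(0:3, 1)
  pf <- if (pf_n > 0) {
    qlen <- sample(80:400, pf_n, replace = TRUE)
    data.frame(
      kind = sample(c("sequence_vs_pdb", "template_3d"), pf_n,
        replace = TRUE
      ),
      e_value = 10^stats::runif(pf_n, -12, 2),
      percent_identity = stats::runif(pf_n, 0, 100),
      longest_fitted_segment = pmax(1, round(stats::runif(pf_n, 0.1, 1) *
        qlen)),
      query_length = qlen,
      function_label = sample(letters, pf_n)
    )
  }
  tr_n <- sample(0:3, 1)
  tr <- if (tr_n > 0) {
    data.frame(
      template_id = sprintf("t%d", seq_len(tr_n)),
      confidence = stats::runif(tr_n),
      e_value = 10^stats::runif(tr_n, -8, 0),
      coverage = stats::runif(tr_n),
      identity = stats::runif(tr_n),
      tm_score = stats::runif(tr_n),
      function_label = sample(letters, tr_n)
    )
  }
  df_n <- sample(0:2, 1)
  dfp <- if (df_n > 0) {
    data.frame(
      term_id = sprintf("GO:%07d", sample(1e6, df_n)),
      score = stats::runif(df_n),
      term_name = sample(c("amylase activity", "binding", "transport"), df_n)
    )
  }
  seq_ko <- if (stats::runif(1) < 0.7) {
    list(ko_ids = sprintf("K%05d", sample(99999, 1)), label = "alpha amylase")
  }
  evidence_bundle(sprintf("r%d", i),
    sequence_ko = seq_ko,
    pf_matches = pf, tr_hits = tr, df_predictions = dfp
  )
}
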