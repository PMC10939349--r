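test_that("E-value and TM-score tier classifiers follow the printed bands", {
  expect_equal(classify_pf_likelihood(1e-7), "certain")
  expect_equal(classify_pf_likelihood(0.05), "possible")
  expect_equal(classify_pf_likelihood(1e-6), "probable") # strict boundary
  expect_equal(classify_pf_likelihood(15), "none")
  expect_error(classify_pf_likelihood(-1), class = "archannot_validation_error")

  expect_equal(classify_tr_significance(0.75), "very_high")
  expect_equal(classify_tr_significance(0.45), "medium")
  expect_equal(classify_tr_significance(0.30), "none") # strict boundary
  expect_error(classify_tr_significance(1.2),
    class = "archannot_validation_error"
  )

  expect_equal(tier_rank(c("certain", "very_high", "none")), c(4L, 4L, 0L))
})

test_that("tier classifiers agree with the band table at boundaries +/- eps", {
  eps <- 1e-12
  pf_expected <- rbind(
    c(1e-6, "certain", "probable", "probable"),
    c(0.01, "probable", "possible", "possible"),
    c(0.1, "possible", "long_shot", "long_shot"),
    c(10, "long_shot", "none", "none")
  )
  for (i in seq_len(nrow(pf_expected))) {
    b <- as.numeric(pf_expected[i, 1])
    expect_equal(classify_pf_likelihood(b - eps), pf_expected[i, 2])
    expect_equal(classify_pf_likelihood(b), pf_expected[i, 3])
    expect_equal(classify_pf_likelihood(b + eps), pf_expected[i, 4])
  }
  tr_expected <- rbind(
    c(0.7, "high", "high", "very_high"),
    c(0.5, "medium", "medium", "high"),
    c(0.4, "low", "low", "medium"),
    c(0.3, "none", "none", "low")
  )
  for (i in seq_len(nrow(tr_expected))) {
    b <- as.numeric(tr_expected[i, 1])
    expect_equal(classify_tr_significance(b - eps), tr_expected[i, 2])
    expect_equal(classify_tr_significance(b), tr_expected[i, 3])
    expect_equal(classify_tr_significance(b + eps), tr_expected[i, 4])
  }
})

test_that("tier assignment is monotone in the underlying score", {
  e_values <- sort(10^runif(200, -10, 2))
  ranks_pf <- tier_rank(classify_pf_likelihood(e_values))
  expect_true(all(diff(ranks_pf) <= 0)) # larger E-value never raises tier
  tms <- sort(runif(200))
  ranks_tr <- tier_rank(classify_tr_significance(tms))
  expect_true(all(diff(ranks_tr) >= 0))
})

test_that("TR admissibility uses three strict thresholds", {
  expect_true(tr_admissible(0.7, 1e-4, 0.5))
  expect_false(tr_admissible(0.6, 1e-4, 0.5)) # confidence not > 0.6
  expect_false(tr_admissible(0.7, 0.001, 0.5)) # e-value not < 0.001
  expect_false(tr_admissible(0.7, 1e-4, 0.3)) # coverage not > 0.3
})

test_that("structure-match coverage is the fitted-segment ratio", {
  expect_equal(pf_coverage(50, 100), 0.5)
  expect_equal(pf_coverage(0, 100), 0)
  expect_equal(pf_coverage(100, 100), 1)
  expect_error(pf_coverage(10, 0), class = "archannot_validation_error")
  expect_error(pf_coverage(120, 100), class = "archannot_validation_error")
})

make_pf <- function(e_value, label = "alpha amylase domain",
                    kind = "template_3d", seg = 100, qlen = 200,
                    ident = 40) {
  data.frame(
    kind = kind, e_value = e_value, percent_identity = ident,
    longest_fitted_segment = seg, query_length = qlen,
    function_label = label
  )
}

make_tr <- function(tm, label = "beta lactamase fold", coverage = 0.5,
                    identity = 0.4, confidence = 0.8, e_value = 1e-4) {
  data.frame(
    template_id = "t1", confidence = confidence, e_value = e_value,
    coverage = coverage, identity = identity, tm_score = tm,
    function_label = label
  )
}

test_that("the reconciliation ladder resolves the canonical cases", {
  # consensus at matching labels, tier = higher rank
  b <- evidence_bundle("s",
    pf_matches = make_pf(1e-8, "alpha amylase domain"),
    tr_hits = make_tr(0.8, "alpha amylase domain")
  )
  r <- reconcile(b)
  expect_equal(r$source, "consensus")
  expect_equal(r$final_label, "alpha amylase domain")
  expect_equal(r$tier_rank, 4L)

  # PF below certain loses to an admissible TR template
  r2 <- reconcile(evidence_bundle("s",
    pf_matches = make_pf(1e-4, "alpha amylase domain"),
    tr_hits = make_tr(0.8, "beta lactamase fold")
  ))
  expect_equal(r2$source, "TR")
  expect_equal(r2$final_label, "beta lactamase fold")

  # equal rank: higher coverage wins
  r3 <- reconcile(evidence_bundle("s",
    pf_matches = make_pf(1e-8, "alpha amylase domain", seg = 120, qlen = 200),
    tr_hits = make_tr(0.8, "beta lactamase fold", coverage = 0.8)
  ))
  expect_equal(r3$final_label, "beta lactamase fold") # 0.8 > 0.6
  r4 <- reconcile(evidence_bundle("s",
    pf_matches = make_pf(1e-8, "alpha amylase domain", seg = 180, qlen = 200),
    tr_hits = make_tr(0.8, "beta lactamase fold", coverage = 0.6)
  ))
  expect_equal(r4$final_label, "alpha amylase domain") # 0.9 > 0.6

  # no 3D functional hits -> TR priority even against a certain match
  r5 <- reconcile(evidence_bundle("s",
    pf_matches = make_pf(1e-8, "alpha amylase domain",
      kind = "sequence_vs_pdb"
    ),
    tr_hits = make_tr(0.6, "beta lactamase fold")
  ))
  expect_equal(r5$source, "TR")

  # lone PF assigns only at certain
  r6 <- reconcile(evidence_bundle("s", pf_matches = make_pf(1e-8)))
  expect_equal(r6$source, "PF")
  r7 <- reconcile(evidence_bundle("s", pf_matches = make_pf(1e-4)))
  expect_equal(r7$final_label, "unannotated")

  # inadmissible TR templates are invisible to the ladder
  r8 <- reconcile(evidence_bundle("s",
    tr_hits = make_tr(0.8, confidence = 0.5)
  ))
  expect_equal(r8$source, "none")

  # empty bundle
  r9 <- reconcile(evidence_bundle("s"))
  expect_equal(r9$final_label, "unannotated")
  expect_equal(r9$source, "none")
})

test_that("reconcile matches the independent rule interpreter exhaustively", {
  for (d in enumerate_descriptors()) {
    expected <- ladder_oracle(d)
    got <- reconcile(descriptor_bundle(d))
    info <- paste(d$pf_tier, d$tr_tier, d$labels_equal, d$pf_is_3d,
      d$cov_case,
      sep = "/"
    )
    expect_equal(got$source, expected$source, info = info)
    expect_equal(got$final_label, expected$label, info = info)
    expect_equal(got$tier, expected$tier, info = info)
  }
})

test_that("reconcile is total and deterministic on random bundles", {
  set.seed(99)
  bundles <- lapply(1:400, random_evidence_bundle)
  first <- lapply(bundles, reconcile)
  second <- lapply(bundles, reconcile)
  expect_identical(first, second)
  for (r in first) {
    expect_true(r$source %in% c("consensus", "TR", "PF", "none"))
    # source none iff unannotated
    expect_equal(r$source == "none", r$final_label == "unannotated")
  }
})

test_that("DF support and agreement categories follow the token rule", {
  b <- evidence_bundle("s",
    sequence_ko = list(ko_ids = "K00001", label = "amylase family enzyme"),
    pf_matches = make_pf(1e-8, "alpha amylase domain"),
    df_predictions = data.frame(
      term_id = "GO:1", score = 0.9, term_name = "amylase activity"
    )
  )
  r <- reconcile(b)
  expect_true(r$df_supported)
  expect_equal(r$agreement, "consistent") # shares token "amylase"

  # low-score DF predictions never count
  b2 <- evidence_bundle("s",
    pf_matches = make_pf(1e-8, "alpha amylase domain"),
    df_predictions = data.frame(
      term_id = "GO:1", score = 0.5, term_name = "amylase activity"
    )
  )
  expect_false(reconcile(b2)$df_supported)
  expect_equal(reconcile(b2)$agreement, "structure_only")

  # disparate when no token (>= 4 chars) is shared
  b3 <- evidence_bundle("s",
    sequence_ko = list(ko_ids = "K00001", label = "membrane transporter"),
    pf_matches = make_pf(1e-8, "alpha amylase domain")
  )
  expect_equal(reconcile(b3)$agreement, "disparate")
  # exact mode is stricter
  expect_equal(
    reconcile(b3, agreement_match = "exact")$agreement, "disparate"
  )

  # sequence KO without structure call
  b4 <- evidence_bundle("s",
    sequence_ko = list(ko_ids = "K00001", label = "membrane transporter")
  )
  expect_equal(reconcile(b4)$agreement, "sequence_only")
})

test_that("annotate_all is total, ordered, and warns on missing bundles", {
  bundles <- list(
    sA = evidence_bundle("sA", pf_matches = make_pf(1e-8)),
    sB = evidence_bundle("sB")
  )
  labels <- c(sA = "u1", sB = "h1", sC = "h2")
  groups <- c(sA = "unique", sB = "homologous", sC = "homologous")
  expect_warning(
    ann <- annotate_all(bundles, labels = labels, groups = groups),
    "sC"
  )
  expect_equal(nrow(ann), 3)
  expect_equal(ann$label, c("h1", "h2", "u1")) # prefix then index
  expect_equal(ann$final_label[ann$label == "h2"], "unannotated")
  # rerun gives the identical table
  expect_identical(
    suppressWarnings(annotate_all(bundles, labels = labels, groups = groups)),
    suppressWarnings(annotate_all(bundles, labels = labels, groups = groups))
  )
})

test_that("consensus recovers the generator's expected labels", {
  for (seed in 1:10) {
    g <- generate_dataset(small_config(
      seed = seed,
      agreement_probability = c(0, 0.5, 1)[seed %% 3 + 1]
    ))
    ann <- annotate_all(g$bundle$evidence)
    exp_lab <- unlist(g$manifest$expected_final_label)
    expect_equal(nrow(ann), length(exp_lab))
    expect_equal(
      ann$final_label,
      as.character(unname(exp_lab[ann$subject_id]))
    )
  }
})
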