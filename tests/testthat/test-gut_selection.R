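test_that("environment exclusivity keeps all-gut clusters only", {
  mags <- tiny_mags()
  proteins <- tiny_proteins()
  clusters <- tiny_clusters()
  # c1: members from gut MAGs only; c2: one soil member; c3: gut bacteria
  retained <- filter_by_environment(clusters, proteins, mags, "human gut")
  expect_equal(retained, c("c1", "c3"))

  # unknown MAG is reported with the offending protein
  bad_prot <- proteins
  bad_prot$mag_id[1] <- "M99"
  expect_error(
    filter_by_environment(clusters, bad_prot, mags, "human gut"),
    "p1",
    class = "archannot_validation_error"
  )

  # idempotence: filtering the retained set again changes nothing
  sub <- clusters[clusters$cluster_id %in% retained, ]
  expect_equal(
    filter_by_environment(sub, proteins, mags, "human gut"),
    retained
  )
})

test_that("environment filter matches the brute-force triple scan", {
  for (seed in 1:10) {
    g <- generate_dataset(small_config(seed = seed))
    b <- g$bundle
    expect_lte(nrow(b$proteins), 500)
    expect_equal(
      filter_by_environment(b$clusters, b$proteins, b$mags, "human gut"),
      oracle_env_filter(b$clusters, b$proteins, b$mags, "human gut")
    )
  }
})

test_that("size gate honors the per-domain thresholds", {
  clusters <- as_cluster_table(data.frame(
    cluster_id = c("a1", rep("a2", 2), rep("b1", 10), rep("b2", 9)),
    member_id = sprintf("p%02d", 1:22)
  ))
  expect_false("a1" %in% filter_by_min_size(clusters, 2)) # singleton
  expect_true("a2" %in% filter_by_min_size(clusters, 2))
  expect_true("b1" %in% filter_by_min_size(clusters, 10)) # exactly 10
  expect_false("b2" %in% filter_by_min_size(clusters, 10))
  # threshold 1 is the identity
  expect_equal(
    filter_by_min_size(clusters, 1),
    sort(unique(clusters$cluster_id))
  )
})

test_that("annotation gate distinguishes all-members and representative", {
  clusters <- as_cluster_table(data.frame(
    cluster_id = rep("c1", 3), member_id = c("p1", "p2", "p3")
  ))
  ko_all <- data.frame(
    subject_id = c("p1", "p2", "p3"), ko_id = "K00001"
  )
  ko_partial <- ko_all[1:2, ]
  reps <- c(c1 = "p1")
  expect_equal(filter_fully_annotated(clusters, ko_all), "c1")
  expect_equal(filter_fully_annotated(clusters, ko_partial), character(0))
  expect_equal(
    filter_fully_annotated(clusters, ko_partial,
      mode = "representative", representatives = reps
    ),
    "c1"
  )
  empty_ko <- data.frame(subject_id = character(), ko_id = character())
  expect_equal(filter_fully_annotated(clusters, empty_ko), character(0))
  expect_equal(
    filter_fully_annotated(clusters, empty_ko,
      mode = "representative", representatives = reps
    ),
    character(0)
  )
})

test_that("representatives prefer the longest sequence, ties by id", {
  clusters <- as_cluster_table(data.frame(
    cluster_id = c("c1", "c1", "c2", "c2"),
    member_id = c("p1", "p2", "pB", "pA")
  ))
  proteins <- data.frame(
    protein_id = c("p1", "p2", "pA", "pB"),
    mag_id = "M1",
    length = c(10L, 30L, 20L, 20L)
  )
  reps <- cluster_representatives(clusters, proteins)
  expect_equal(reps[["c1"]], "p2") # longest
  expect_equal(reps[["c2"]], "pA") # tie -> lexicographic
})

test_that("selection funnel is ordered, non-increasing, and truth-recovering", {
  g <- generate_dataset(small_config(seed = 21))
  b <- g$bundle
  report <- run_selection(b)
  for (dom in c("archaea", "bacteria")) {
    counts <- report$stages$n_clusters[report$stages$domain == dom]
    expect_true(all(diff(counts) <= 0))
  }
  # stage-2 (environment) count equals the planted gut-exclusive count
  doms <- cluster_domains(b$clusters, b$proteins, b$mags)
  planted <- g$manifest$gut_exclusive_cluster_ids
  for (dom in c("archaea", "bacteria")) {
    stage2 <- report$stages$n_clusters[
      report$stages$domain == dom & report$stages$stage == "environment"
    ]
    expect_equal(stage2, sum(doms[planted] == dom))
  }

  # size and annotation gates commute
  env_ok <- filter_by_environment(b$clusters, b$proteins, b$mags, "human gut")
  arch_env <- intersect(env_ok, names(doms)[doms == "archaea"])
  cl <- b$clusters[b$clusters$cluster_id %in% arch_env, ]
  size_then_ann <- filter_fully_annotated(
    cl[cl$cluster_id %in% filter_by_min_size(cl, 2), ], b$ko
  )
  ann_first <- filter_fully_annotated(cl, b$ko)
  ann_then_size <- filter_by_min_size(
    cl[cl$cluster_id %in% ann_first, ], 2
  )
  expect_equal(size_then_ann, ann_then_size)
})

test_that("a bundle without gut MAGs yields an empty selection", {
  g <- generate_dataset(small_config(seed = 22))
  b <- g$bundle
  b$mags$environment <- "soil"
  report <- run_selection(b)
  expect_equal(unname(unlist(report$retained)), character(0))
  expect_true(all(report$stages$n_clusters[
    report$stages$stage == "environment"
  ] == 0))
})

test_that("clusters mixing domains are rejected as malformed", {
  mags <- tiny_mags()
  proteins <- tiny_proteins()
  mixed <- as_cluster_table(data.frame(
    cluster_id = c("cx", "cx"), member_id = c("p1", "p5") # archaea + bacteria
  ))
  expect_error(
    cluster_domains(mixed, proteins, mags),
    "cx",
    class = "archannot_validation_error"
  )
})
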