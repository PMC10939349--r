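test_that("MAG metadata is parsed, normalized, and validated", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "mag_id\tdomain\ttaxonomy\tenvironment\tcatalog",
    "M1\tarchaea\td__Archaea\t Human  Gut \tGEM",
    "M2\tbacteria\td__Bacteria\tsoil\tUHGG",
    "M3\tArchaea\td__Archaea\thuman gut\tUHGG"
  ), path)
  mags <- read_mag_metadata(path)
  expect_equal(nrow(mags), 3)
  expect_equal(mags$environment[1], "human gut")
  expect_equal(mags$domain[3], "archaea")

  # missing column is a format error naming the column
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "mag_id\ttaxonomy\tenvironment\tcatalog",
    "M1\td__Archaea\thuman gut\tGEM"
  ), path2)
  expect_error(read_mag_metadata(path2),
    "domain",
    class = "archannot_format_error"
  )

  # duplicate mag_id and unknown domain are validation errors
  expect_error(
    as_mag_table(data.frame(
      mag_id = c("M1", "M1"), domain = "archaea", taxonomy = "t",
      environment = "human gut", catalog = "c"
    )),
    "duplicate",
    class = "archannot_validation_error"
  )
  expect_error(
    as_mag_table(data.frame(
      mag_id = "M1", domain = "eukaryota", taxonomy = "t",
      environment = "human gut", catalog = "c"
    )),
    "M1",
    class = "archannot_validation_error"
  )
})

test_that("cluster tables are partitions: grouping, collapsing, rejection", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("c1\tp1", "c1\tp2", "c2\tp3"), path)
  cl <- read_cluster_table(path, level = "mm2")
  expect_equal(sort(cl$member_id[cl$cluster_id == "c1"]), c("p1", "p2"))
  expect_equal(cl$member_id[cl$cluster_id == "c2"], "p3")

  # duplicate membership collapses with a warning
  writeLines(c("c1\tp1", "c1\tp1", "c2\tp3"), path)
  expect_warning(cl2 <- read_cluster_table(path), "duplicate")
  expect_equal(nrow(cl2), 2)

  # a member in two clusters violates the partition property
  writeLines(c("c1\tp1", "c2\tp1"), path)
  expect_error(read_cluster_table(path),
    "p1",
    class = "archannot_validation_error"
  )

  # empty file yields an empty cluster set
  file.create(path2 <- withr::local_tempfile(fileext = ".tsv"))
  expect_equal(nrow(read_cluster_table(path2)), 0)
})

test_that("evidence bundles are range-checked on read", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(list(
    subject_id = "s1",
    sequence_ko = list(ko_ids = list("K00001"), label = "some kinase"),
    pf_matches = list(),
    tr_hits = list(list(
      template_id = "t1", confidence = 0.7, e_value = 1e-4,
      coverage = 0.5, identity = 0.4, tm_score = 0.75,
      function_label = "kinase fold"
    )),
    df_predictions = list()
  )), auto_unbox = TRUE), path)
  bundles <- read_evidence_bundles(path)
  expect_length(bundles, 1)
  expect_equal(bundles$s1$tr_hits$tm_score, 0.75)
  expect_equal(nrow(bundles$s1$pf_matches), 0)

  # tm_score out of [0,1] names the subject
  writeLines(jsonlite::toJSON(list(list(
    subject_id = "s9",
    tr_hits = list(list(
      template_id = "t1", confidence = 0.7, e_value = 1e-4,
      coverage = 0.5, identity = 0.4, tm_score = 1.5,
      function_label = "x"
    ))
  )), auto_unbox = TRUE), path)
  expect_error(read_evidence_bundles(path),
    "s9",
    class = "archannot_validation_error"
  )

  # negative PF e-value violates the invariant
  expect_error(
    evidence_bundle("s2", pf_matches = data.frame(
      kind = "template_3d", e_value = -1, percent_identity = 50,
      longest_fitted_segment = 10, query_length = 20, function_label = "x"
    )),
    "s2",
    class = "archannot_validation_error"
  )
})

test_that("gene features, coverage, and result tables round-trip", {
  features <- data.frame(
    contig_id = c("ctg1", "ctg1"),
    gene_id = c("g1", "g2"),
    start = c(100L, 2000L),
    end = c(1000L, 2900L),
    strand = c("+", "-")
  )
  features$ko_ids <- list("K00001", character(0))
  gff <- withr::local_tempfile(fileext = ".gff3")
  ko <- withr::local_tempfile(fileext = ".tsv")
  write_gene_features(features, gff, ko_path = ko)
  back <- read_gene_features(gff, ko_path = ko)
  expect_equal(back$gene_id, features$gene_id)
  expect_equal(back$start, features$start)
  expect_equal(back$end, features$end)
  expect_equal(back$ko_ids, features$ko_ids)

  # end < start is rejected
  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "ctg1\tProdigal\tCDS\t500\t100\t.\t+\t0\tID=gbad"
  ), bad)
  expect_error(read_gene_features(bad), class = "archannot_validation_error")

  cov_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsample_id\tmean_coverage", "g1\ts1\t3.5"), cov_path)
  cov <- read_coverage(cov_path)
  expect_equal(cov$mean_coverage, 3.5)
  writeLines(c("gene_id\tsample_id\tmean_coverage", "g1\ts1\t-1"), cov_path)
  expect_error(read_coverage(cov_path), class = "archannot_validation_error")

  # result tables: write(read(x)) == x and writers are byte-deterministic
  tab <- data.frame(
    label = c("u1", "u2"), ko_id = c("K00001", "K00002"),
    n_select = c(2L, 5L), n_total = c(1000L, 1000L),
    relative_occurrence = c(2000, 5000)
  )
  out <- withr::local_tempdir()
  paths <- write_results(list(occurrence = tab), out)
  expect_equal(read_result_table(paths[["occurrence"]]), tab)
  first <- readBin(paths[["occurrence"]], "raw", file.size(paths[["occurrence"]]))
  write_results(list(occurrence = tab), out)
  second <- readBin(paths[["occurrence"]], "raw", file.size(paths[["occurrence"]]))
  expect_identical(first, second)
})

test_that("protein FASTA keeps MAG provenance", {
  proteins <- data.frame(
    protein_id = c("p1", "p2"), mag_id = c("M1", "M2"),
    sequence = c("MKLV", "MMAC")
  )
  path <- withr::local_tempfile(fileext = ".faa")
  write_protein_fasta(proteins, path)
  back <- read_protein_fasta(path)
  expect_equal(back$protein_id, proteins$protein_id)
  expect_equal(back$mag_id, proteins$mag_id)
  expect_equal(back$sequence, proteins$sequence)
  expect_equal(back$length, c(4L, 4L))
})
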