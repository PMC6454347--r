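test_that("init_database creates nine empty constrained tables", {
  db <- init_database()
  counts <- db_row_counts(db)
  expect_length(counts, 9)
  expect_true(all(counts == 0))
  expect_setequal(names(counts),
                  c("person", "condition_occurrence", "procedure_occurrence",
                    "specimen", "care_site", "genomic_test", "target_gene",
                    "variant_occurrence", "variant_annotation"))
})

test_that("on-disk init refuses to clobber and refuses foreign paths", {
  dir <- tempfile("gcdmdb")
  db <- init_database(dir)
  expect_true(file.exists(file.path(dir, "gcdm_meta.json")))
  expect_error(init_database(dir), "already initialized")
  expect_silent(init_database(dir, overwrite = TRUE))

  plain <- tempfile()
  writeLines("not a database", plain)
  expect_error(init_database(plain), "not a database directory")
  foreign <- tempfile()
  dir.create(foreign)
  writeLines("x", file.path(foreign, "something.txt"))
  expect_error(init_database(foreign), "non-empty")
})

test_that("insert_records returns the batch size and enforces vocabularies", {
  db <- init_database()
  n <- insert_records(db, "person", data.frame(
    person_id = 1:3, gender = c("male", "female", "unknown"),
    age_years = c(61L, 45L, NA), race = NA_character_))
  expect_identical(n, 3L)
  expect_identical(nrow(db_table(db, "person")), 3L)

  err <- expect_error(
    insert_records(db, "specimen", data.frame(
      specimen_id = 1L, person_id = 1L, specimen_role = "tumor",
      specimen_type = NA_character_, collection_date = NA_character_,
      anatomic_site = NA_character_)),
    class = "gcdm_constraint_error")
  expect_match(conditionMessage(err), "specimen_role")
  expect_identical(nrow(db_table(db, "specimen")), 0L)
})

test_that("foreign keys and domain ranges are enforced at insert", {
  db <- make_panel_db(2)
  expect_error(
    add_variant(db, person = 1, gene = "EGFR") -> ignored,
    NA)  # sanity: a valid insert passes
  expect_error(
    insert_records(db, "variant_occurrence", data.frame(
      variant_occurrence_id = 99L, procedure_id = 1L,
      specimen_id_target = 1L, specimen_id_reference = NA_integer_,
      target_gene_id = 999L, reference_sequence = NA_character_,
      rs_id = NA_character_, hgvs_c = NA_character_,
      hgvs_p = NA_character_, read_depth = NA_integer_,
      exon_number = NA_integer_, sequence_alteration = "SNP",
      variant_feature = "missense", genomic_start = NA_integer_,
      genomic_end = NA_integer_)),
    "target_gene_id")

  expect_error(
    insert_records(db, "person", data.frame(
      person_id = 50L, gender = "male", age_years = 180L,
      race = NA_character_)),
    "range")
  expect_error(
    insert_records(db, "variant_annotation", data.frame(
      variant_annotation_id = 1L, variant_occurrence_id = 1L,
      annotation_db_name = "x", annotation_db_version = "1",
      variant_origin = "somatic", pathogenicity = NA_character_,
      allele_frequency = 1.4, medication = NA_character_)),
    "range")
})

test_that("stored protein HGVS must be three-letter and well-formed", {
  db <- make_panel_db(2)
  expect_error(add_variant(db, 1, "EGFR", hgvs_p = "p.L858R"),
               class = "gcdm_constraint_error")
  expect_silent(add_variant(db, 1, "EGFR", hgvs_p = "p.Leu858Arg"))
  # wildcard residues are a query construct, not observations
  expect_error(add_variant(db, 2, "KRAS", hgvs_p = "p.Gly12Xaa"),
               class = "gcdm_constraint_error")
})

test_that("validate_database flags orphans and malformed HGVS from raw writes", {
  db <- make_panel_db(3)
  add_variant(db, 1, "EGFR", hgvs_p = "p.Leu858Arg")
  expect_identical(nrow(validate_database(db)), 0L)

  # orphan annotation injected past the insert guard
  raw <- db$tables$variant_annotation
  db$tables$variant_annotation <- rbind(raw, data.frame(
    variant_annotation_id = 7L, variant_occurrence_id = 999L,
    annotation_db_name = "x", annotation_db_version = "1",
    variant_origin = "somatic", pathogenicity = NA_character_,
    allele_frequency = NA_real_, medication = NA_character_))
  viol <- validate_database(db)
  expect_identical(nrow(viol), 1L)
  expect_match(viol$rule, "variant_occurrence_id")

  # malformed frameshift tail (fsTer with no offset digits)
  db2 <- make_panel_db(2)
  add_variant(db2, 1, "EGFR", hgvs_p = "p.Leu858Arg")
  db2$tables$variant_occurrence$hgvs_p[1] <- "p.Leu858ArgfsTer"
  viol2 <- validate_database(db2)
  expect_identical(nrow(viol2), 1L)
  expect_match(viol2$rule, "hgvs_p")
})

test_that("databases built only through insert_records validate cleanly", {
  for (seed in c(11, 12)) {
    db <- generate_cohort(cohort_spec(
      60, gene_probs = c(EGFR = 0.5, TP53 = 0.4, KRAS = 0.2),
      pattern_probs = list(EGFR = c("p.Leu858Arg" = 0.2)), seed = seed))
    expect_identical(nrow(validate_database(db)), 0L)
  }
})

test_that("specimen_id_reference is nullable everywhere", {
  db <- generate_cohort(cohort_spec(30, gene_probs = c(EGFR = 0.8),
                                    seed = 5))
  db$tables$variant_occurrence$specimen_id_reference <- NA_integer_
  expect_identical(nrow(validate_database(db)), 0L)
})

test_that("dump and reload round-trips the database", {
  db <- generate_cohort(cohort_spec(
    25, gene_probs = c(EGFR = 0.6, KRAS = 0.3), seed = 9))
  dir <- tempfile("dump")
  db_save(db, dir)
  db2 <- db_load(dir)
  for (nm in names(db$tables))
    expect_equal(db2$tables[[nm]], db$tables[[nm]], ignore_attr = TRUE)
})

test_that("insert count conservation holds across batches", {
  db <- init_database()
  total <- 0L
  for (batch in list(1:3, 4:4, 5:9)) {
    total <- total + insert_records(db, "person", data.frame(
      person_id = batch, gender = "female", age_years = 50L,
      race = NA_character_))
  }
  expect_identical(total, nrow(db_table(db, "person")))
  expect_error(insert_records(db, "person", data.frame(
    person_id = 3L, gender = "male", age_years = 40L,
    race = NA_character_)), "duplicate")
})
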