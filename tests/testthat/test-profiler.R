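test_that("demographics reproduce printed margins with half-up rounding", {
  d <- cohort_demographics(table1_fixture("ausom_like"))
  path <- d[d$category_group == "pathology" &
              d$category == "lung adenocarcinoma", ]
  expect_identical(path$count, 92L)
  expect_identical(path$percent, 80.7)

  d2 <- cohort_demographics(table1_fixture("tcga_like"))
  unk <- d2[d2$category_group == "age" & d2$category == "unknown", ]
  expect_identical(unk$count, 170L)
  expect_identical(unk$percent, 16.0)
  # every group's counts sum to the cohort size
  for (g in unique(d$category_group))
    expect_identical(sum(d$count[d$category_group == g]), 114L)
})

test_that("a single-patient cohort yields a 100.0 percent row", {
  db <- init_database()
  insert_records(db, "person", data.frame(
    person_id = 1L, gender = "male", age_years = 70L, race = NA_character_))
  d <- cohort_demographics(db)
  male <- d[d$category_group == "gender" & d$category == "male", ]
  expect_identical(male$count, 1L)
  expect_identical(male$percent, 100.0)
  expect_error(cohort_demographics(init_database()),
               class = "gcdm_empty_cohort")
})

test_that("gene frequency deduplicates per patient and filters features", {
  db <- make_panel_db(10)
  for (p in 1:3) add_variant(db, p, "EGFR", feature = "missense")
  for (i in 1:4) add_variant(db, 5, "TP53",
                             hgvs_p = sprintf("p.Arg%dHis", 100 + i))
  add_variant(db, 7, "KRAS", feature = "intron")

  gf <- gene_variant_frequency(db)
  expect_identical(gf$n_patients_with_variant[gf$hgnc_symbol == "EGFR"], 3L)
  expect_identical(gf$frequency[gf$hgnc_symbol == "EGFR"], 0.3)
  # four distinct TP53 variants in one patient count once
  expect_identical(gf$n_patients_with_variant[gf$hgnc_symbol == "TP53"], 1L)
  expect_identical(gf$n_patients_with_variant[gf$hgnc_symbol == "KRAS"], 1L)

  gfp <- gene_variant_frequency(db, protein_altering_only = TRUE)
  expect_identical(gfp$n_patients_with_variant[gfp$hgnc_symbol == "KRAS"], 0L)
  # ordering contract: non-increasing frequency
  expect_true(all(diff(gf$frequency) <= 0))
})

test_that("top_gene_union honors overlap structure", {
  mk <- function(genes, freqs) data.frame(
    hgnc_symbol = genes, n_patients_with_variant = 1L,
    n_patients_total = 10L, frequency = freqs, stringsAsFactors = FALSE)
  a <- mk(paste0("G", 1:12), seq(0.95, by = -0.05, length.out = 12))
  expect_identical(top_gene_union(a, a, k = 10), paste0("G", 1:10))

  b <- mk(paste0("H", 1:12), seq(0.90, by = -0.05, length.out = 12))
  expect_length(top_gene_union(a, b, k = 10), 20)

  # overlap of 5 between the two top-10 sets gives 15 genes
  c_ <- mk(c(paste0("G", 1:5), paste0("H", 1:7)),
           seq(0.99, by = -0.05, length.out = 12))
  expect_length(top_gene_union(a, c_, k = 10), 15)
  expect_error(top_gene_union(a, b, k = 0), "k must be")
})

test_that("variant-type proportions are over variant rows and sum to one", {
  db <- make_panel_db(10)
  for (p in 1:8) add_variant(db, p, "TP53", alteration = "SNP")
  add_variant(db, 9, "TP53", alteration = "insertion",
              feature = "frameshift")
  add_variant(db, 10, "TP53", alteration = "deletion",
              feature = "frameshift")
  vt <- variant_type_proportions(db, "sequence_alteration")
  expect_identical(vt$proportion[vt$type == "SNP"], 0.8)
  expect_equal(sum(vt$proportion), 1, tolerance = 1e-9)

  db1 <- make_panel_db(2)
  add_variant(db1, 1, "EGFR", alteration = "CNV", feature = "other")
  vt1 <- variant_type_proportions(db1, "sequence_alteration")
  expect_identical(vt1$proportion[vt1$type == "CNV"], 1.0)
  expect_error(variant_type_proportions(make_panel_db(2)), "no variants")
})

test_that("actionable profiling deduplicates per pattern and per gene", {
  db <- make_panel_db(10)
  add_variant(db, 1, "KRAS", hgvs_p = "p.Gly12Cys")
  add_variant(db, 2, "EGFR", hgvs_p = "p.Leu858Arg")
  add_variant(db, 2, "EGFR", hgvs_p = "p.Thr790Met")
  act <- suppressWarnings(actionable_frequency(db))

  k12 <- act[act$gene == "KRAS" & act$pattern == "p.Gly12Xaa", ]
  expect_identical(k12$n_patients, 1L)
  l858 <- act[act$gene == "EGFR" & act$pattern == "p.Leu858Arg", ]
  t790 <- act[act$gene == "EGFR" & act$pattern == "p.Thr790Met", ]
  any_egfr <- act[act$gene == "EGFR" & act$pattern == "(any)", ]
  expect_identical(l858$n_patients, 1L)
  expect_identical(t790$n_patients, 1L)
  expect_identical(any_egfr$n_patients, 1L)  # same patient, counted once

  empty <- structure(list(name = "none", version = "0", genes = list()),
                     class = "actionable_registry")
  expect_identical(nrow(actionable_frequency(db, empty)), 0L)
})

test_that("condition stratification uses per-condition denominators", {
  db <- make_panel_db(10)  # 5 LUAD (odd ids), 5 LUSC (even ids)
  add_variant(db, 1, "EGFR", hgvs_p = "p.Leu858Arg")
  add_variant(db, 3, "EGFR", hgvs_p = "p.Leu858Arg")
  act <- suppressWarnings(
    actionable_frequency(db, stratify_by_condition = TRUE))
  luad <- act[act$condition == "lung adenocarcinoma" &
                act$pattern == "p.Leu858Arg", ]
  lusc <- act[act$condition == "lung squamous cell carcinoma" &
                act$pattern == "p.Leu858Arg", ]
  expect_identical(luad$n_patients, 2L)
  expect_identical(luad$n_total, 5L)
  expect_identical(lusc$n_patients, 0L)
})

test_that("waterfall cells take the highest-priority feature", {
  db <- make_panel_db(4, genes = c("TP53", "EGFR", "KRAS"))
  add_variant(db, 1, "TP53", feature = "missense")
  add_variant(db, 1, "TP53", feature = "nonsense")
  add_variant(db, 2, "TP53", feature = "missense")
  add_variant(db, 2, "EGFR", feature = "splice")
  wf <- waterfall_matrix(db, top_n = 3)
  expect_identical(wf$matrix["TP53", "1"], "nonsense")
  expect_identical(wf$matrix["TP53", "2"], "missense")
  # adding a lower-priority variant never changes the cell
  add_variant(db, 1, "TP53", feature = "synonymous")
  add_variant(db, 1, "TP53", feature = "missense")
  wf2 <- waterfall_matrix(db, top_n = 3)
  expect_identical(wf2$matrix["TP53", "1"], "nonsense")
})

test_that("waterfall genes sort by frequency and absent genes show none", {
  db <- make_panel_db(10, genes = c("TP53", "EGFR", "KRAS"))
  for (p in 1:6) add_variant(db, p, "TP53")
  for (p in 1:3) add_variant(db, p, "EGFR")
  add_variant(db, 1, "KRAS")
  wf <- waterfall_matrix(db, genes = c("KRAS", "EGFR", "TP53", "BRAF"))
  expect_identical(wf$genes, c("TP53", "EGFR", "KRAS", "BRAF"))
  expect_identical(unname(wf$frequencies), c(0.6, 0.3, 0.1, 0))
  expect_true(all(wf$matrix["BRAF", ] == "none"))
  # staircase: mutated-everywhere patients come first
  expect_identical(wf$patients[1], 1L)
})

test_that("query_variant matches patterns and is monotone", {
  db <- make_panel_db(10)
  add_variant(db, 1, "EGFR", hgvs_p = "p.Leu858Arg")
  add_variant(db, 4, "EGFR", hgvs_p = "p.Leu858Arg")
  add_variant(db, 6, "EGFR", hgvs_p = "p.Thr790Met")
  res <- query_variant(db, "EGFR", "p.Leu858Arg")
  expect_identical(res$n_patients, 2L)
  expect_identical(res$n_total, 10L)
  expect_identical(res$frequency, 0.2)
  expect_gte(query_variant(db, "EGFR")$n_patients, res$n_patients)
  # one-letter patterns are accepted at the query boundary
  expect_identical(query_variant(db, "EGFR", "p.L858R")$n_patients, 2L)
})

test_that("wildcard query equals a brute-force codon scan", {
  db <- make_panel_db(20)
  alts <- c("Cys", "Asp", "Val", "Ala")
  for (p in 1:8) add_variant(db, p, "KRAS",
                             hgvs_p = sprintf("p.Gly12%s", alts[(p %% 4) + 1]))
  add_variant(db, 3, "KRAS", hgvs_p = "p.Gly12Cys")   # duplicate carrier
  add_variant(db, 9, "KRAS", hgvs_p = "p.Gly13Asp")   # wrong codon
  add_variant(db, 10, "KRAS", hgvs_p = "p.Gly12Ter")  # nonsense, excluded

  # independent oracle: scan stored rows, regex the codon, dedupe patients
  vo <- db_table(db, "variant_occurrence")
  tg <- db_table(db, "target_gene")
  pr <- db_table(db, "procedure_occurrence")
  sym <- tg$hgnc_symbol[match(vo$target_gene_id, tg$target_gene_id)]
  hits <- !is.na(vo$hgvs_p) & sym == "KRAS" &
    grepl("^p\\.Gly12(?!Ter$)[A-Z][a-z]{2}$", vo$hgvs_p, perl = TRUE)
  oracle <- length(unique(pr$person_id[match(vo$procedure_id[hits],
                                             pr$procedure_id)]))
  expect_identical(query_variant(db, "KRAS", "p.Gly12Xaa")$n_patients,
                   oracle)
  expect_identical(oracle, 8L)
})

test_that("aggregate export carries no patient-level identifiers", {
  db <- make_panel_db(6)
  # distinctive person ids that would be recognizable in the export
  db$tables$person$person_id <- db$tables$person$person_id + 987650L
  db$tables$condition_occurrence$person_id <-
    db$tables$condition_occurrence$person_id + 987650L
  db$tables$procedure_occurrence$person_id <-
    db$tables$procedure_occurrence$person_id + 987650L
  db$tables$specimen$person_id <- db$tables$specimen$person_id + 987650L
  add_variant(db, 1, "EGFR", hgvs_p = "p.Leu858Arg")
  agg <- export_aggregate(db, "site X")
  txt <- as.character(jsonlite::toJSON(unclass(agg), auto_unbox = TRUE))
  expect_false(grepl("person_id", txt))
  expect_false(grepl("98765", txt))
  expect_identical(agg$n_patients, 6L)
})

test_that("small-cell suppression masks counts strictly below k", {
  db <- make_panel_db(10)
  add_variant(db, 1, "EGFR", hgvs_p = "p.Leu858Arg")
  add_variant(db, 2, "EGFR", hgvs_p = "p.Leu858Arg")
  add_variant(db, 3, "EGFR", hgvs_p = "p.Leu858Arg")
  raw <- export_aggregate(db, "s", suppression_k = 0)
  expect_identical(raw$genes$EGFR, 3L)
  sup <- export_aggregate(db, "s", suppression_k = 5)
  expect_identical(sup$genes$EGFR, "<5")
  expect_identical(sup$genes$KRAS, 0L)  # zero stays visible
})

test_that("chi-squared matches the closed form and is symmetric", {
  res <- chi_squared_2x2(30, 100, 10, 100)
  expect_equal(res$statistic, 12.5, tolerance = 1e-12)
  expect_identical(res$df, 1L)

  same <- chi_squared_2x2(10, 100, 10, 100)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)

  a <- chi_squared_2x2(17, 80, 41, 120)
  b <- chi_squared_2x2(41, 120, 17, 80)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_error(chi_squared_2x2(0, 50, 0, 60),
               class = "gcdm_degenerate_table")
  expect_error(chi_squared_2x2(50, 50, 60, 60),
               class = "gcdm_degenerate_table")
})

test_that("aggregate comparison reports ratios and flags significance", {
  db <- make_panel_db(10)
  for (p in 1:4) add_variant(db, p, "EGFR", hgvs_p = "p.Leu858Arg")
  x <- export_aggregate(db, "x")
  same <- compare_aggregates(x, x)
  expect_true(all(same$ratio[!is.na(same$ratio)] == 1))
  expect_true(all(same$chi2[!is.na(same$chi2)] == 0))
  expect_false(any(same$significant, na.rm = TRUE))

  db2 <- make_panel_db(10)
  for (p in 1:2) add_variant(db2, p, "EGFR", hgvs_p = "p.Leu858Arg")
  y <- export_aggregate(db2, "y")
  cmp <- compare_aggregates(x, y)
  eg <- cmp[cmp$item == "gene:EGFR", ]
  expect_identical(eg$ratio, 2.00)

  y$schema_version <- "0.0"
  expect_error(compare_aggregates(x, y), "schema")

  sup <- export_aggregate(db2, "y", suppression_k = 5)
  expect_error(compare_aggregates(x, sup), "suppressed")
})
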