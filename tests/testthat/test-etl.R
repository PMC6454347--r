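test_that("read_maf parses the dialect and tolerates comments and case", {
  rows <- default_maf_rows()
  names(rows)[1] <- "HUGO_SYMBOL"  # case-insensitive header match
  path <- write_maf_fixture(rows, comments = c("#version 2.4", "# extra"))
  rec <- read_maf(path)
  expect_s3_class(rec, "maf_records")
  expect_identical(nrow(rec), 3L)
  expect_identical(rec$hugo_symbol, c("EGFR", "KRAS", "TP53"))
  expect_identical(rec$hgvs_p_short[1], "p.L858R")
  expect_true(is.na(rec$dbsnp_rs[2]))
})

test_that("read_maf reports missing mandatory columns by name", {
  rows <- default_maf_rows()
  rows$Variant_Classification <- NULL
  path <- write_maf_fixture(rows)
  expect_error(read_maf(path), "variant_classification")
})

test_that("load_maf maps, expands, restricts to panel and conserves rows", {
  db <- init_database()
  insert_records(db, "person", data.frame(
    person_id = 1:2, gender = "male", age_years = 60L,
    race = NA_character_))
  rows <- rbind(default_maf_rows(), data.frame(
    Hugo_Symbol = "ZZGENE", Chromosome = "1", Start_Position = "5",
    End_Position = "5", Variant_Classification = "Missense_Mutation",
    Variant_Type = "SNP", dbSNP_RS = "", Tumor_Sample_Barcode = "S1",
    HGVSp_Short = "p.A5T", HGVSc = "c.13G>A", t_depth = "99"))
  rec <- read_maf(write_maf_fixture(rows))
  panel <- panel_definition(c("EGFR", "KRAS", "TP53", "BRAF"))
  rep <- load_maf(db, rec, panel, c(S1 = 1L, S2 = 2L))

  expect_identical(rep$rows_read, 4L)
  expect_identical(rep$rows_loaded, 3L)
  expect_identical(rep$skip_reasons$off_panel, 1L)
  expect_identical(rep$rows_read, rep$rows_loaded + rep$rows_skipped)

  vo <- db_table(db, "variant_occurrence")
  expect_identical(nrow(vo), 3L)
  tg <- db_table(db, "target_gene")
  sym <- tg$hgnc_symbol[match(vo$target_gene_id, tg$target_gene_id)]
  expect_setequal(sym, c("EGFR", "KRAS", "TP53"))
  expect_identical(vo$hgvs_p[sym == "KRAS"], "p.Gly12Cys")
  expect_identical(vo$variant_feature[sym == "TP53"], "nonsense")
  expect_identical(vo$sequence_alteration, rep("SNP", 3))
  expect_identical(vo$read_depth[sym == "EGFR"], 512L)
  expect_identical(nrow(validate_database(db)), 0L)
})

test_that("only one sample per patient survives a MAF load", {
  db <- init_database()
  insert_records(db, "person", data.frame(
    person_id = 1L, gender = "female", age_years = 55L,
    race = NA_character_))
  rows <- default_maf_rows()[1:2, ]
  rows$Tumor_Sample_Barcode <- c("S1b", "S1a")
  rec <- read_maf(write_maf_fixture(rows))
  panel <- panel_definition(c("EGFR", "KRAS"))
  rep <- load_maf(db, rec, panel, c(S1a = 1L, S1b = 1L))
  expect_identical(rep$rows_loaded, 1L)
  expect_identical(rep$skip_reasons$duplicate_sample, 1L)
  # the lexicographically first barcode wins absent collection dates
  vo <- db_table(db, "variant_occurrence")
  tg <- db_table(db, "target_gene")
  expect_identical(tg$hgnc_symbol[match(vo$target_gene_id,
                                        tg$target_gene_id)], "KRAS")
})

test_that("panel restriction commutes with loading", {
  panel <- panel_definition(c("EGFR", "TP53"))
  rows <- default_maf_rows()
  rec_full <- read_maf(write_maf_fixture(rows))
  canon <- vapply(rows$Hugo_Symbol, function(g)
    normalize_gene_symbol(g)$symbol, character(1))
  rec_pre <- rec_full[canon %in% panel$genes, ]

  load_into <- function(rec) {
    db <- init_database()
    insert_records(db, "person", data.frame(
      person_id = 1:2, gender = "male", age_years = 60L,
      race = NA_character_))
    load_maf(db, rec, panel, c(S1 = 1L, S2 = 2L))
    vo <- db_table(db, "variant_occurrence")
    tg <- db_table(db, "target_gene")
    pr <- db_table(db, "procedure_occurrence")
    key <- paste(pr$person_id[match(vo$procedure_id, pr$procedure_id)],
                 tg$hgnc_symbol[match(vo$target_gene_id, tg$target_gene_id)],
                 vo$hgvs_p, vo$variant_feature, vo$sequence_alteration)
    sort(key)
  }
  expect_identical(load_into(rec_full), load_into(rec_pre))
})

write_vcf_fixture <- function() {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"gene|consequence|hgvs_c|hgvs_p\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    paste("7", "55259515", "rs121434568", "T", "G", "100", "PASS",
          "ANN=EGFR|missense_variant|c.2573T>G|p.L858R;DP=500", sep = "\t"),
    paste("12", "25398284", ".", "C", "A", "80", "PASS",
          "ANN=KRAS|missense_variant|c.34G>T|p.G12C;DP=300", sep = "\t"),
    paste("17", "100", ".", "AT", "A", "50", "PASS",
          "ANN=TP53|frameshift_variant|c.100del|;DP=120", sep = "\t"),
    paste("7", "200", ".", "A", "AGG", "60", "q10",
          "ANN=EGFR|inframe_insertion|c.200_201insGG|", sep = "\t"),
    paste("1", "300", ".", "G", "C", "30", "PASS",
          "ANN=ZZGENE|missense_variant|c.1G>C|", sep = "\t")),
    path)
  path
}

test_that("load_vcf filters, converts coordinates and maps annotation", {
  db <- init_database()
  insert_records(db, "person", data.frame(
    person_id = 1L, gender = "male", age_years = 62L, race = NA_character_))
  panel <- panel_definition(c("EGFR", "KRAS", "TP53"))
  rep <- load_vcf(db, write_vcf_fixture(), panel, person_id = 1L)

  expect_identical(rep$rows_read, 5L)
  expect_identical(rep$rows_loaded, 3L)
  expect_identical(rep$skip_reasons$filter_failed, 1L)
  expect_identical(rep$skip_reasons$off_panel, 1L)

  vo <- db_table(db, "variant_occurrence")
  tg <- db_table(db, "target_gene")
  sym <- tg$hgnc_symbol[match(vo$target_gene_id, tg$target_gene_id)]
  expect_identical(vo$hgvs_p[sym == "EGFR"], "p.Leu858Arg")
  expect_identical(vo$read_depth[sym == "EGFR"], 500L)
  expect_identical(vo$rs_id[sym == "EGFR"], "rs121434568")
  # VCF deletion AT>A at 100 lands on the deleted base: 101..101
  del <- vo[sym == "TP53", ]
  expect_identical(del$genomic_start, 101L)
  expect_identical(del$genomic_end, 101L)
  expect_identical(del$sequence_alteration, "deletion")
  expect_identical(del$variant_feature, "frameshift")
  expect_identical(nrow(validate_database(db)), 0L)
})

test_that("VCF coordinate conversion matches hand-converted cases", {
  cases <- list(
    list(100L, "AT", "A", 101L, 101L, "deletion"),
    list(100L, "ACT", "A", 101L, 102L, "deletion"),
    list(100L, "A", "AT", 100L, 101L, "insertion"),
    list(100L, "A", "G", 100L, 100L, "SNP"),
    list(100L, "AC", "GT", 100L, 101L, "MNP"))
  for (cs in cases) {
    got <- gcdm:::vcf_to_maf_coords(cs[[1]], cs[[2]], cs[[3]])
    expect_identical(got$start, cs[[4]],
                     label = paste(cs[[2]], ">", cs[[3]], "start"))
    expect_identical(got$end, cs[[5]],
                     label = paste(cs[[2]], ">", cs[[3]], "end"))
    expect_identical(got$class, cs[[6]],
                     label = paste(cs[[2]], ">", cs[[3]], "class"))
  }
})

test_that("load_vcf requires the annotation INFO field", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    paste("7", "10", ".", "A", "G", "10", "PASS", "DP=5", sep = "\t")), path)
  db <- init_database()
  insert_records(db, "person", data.frame(
    person_id = 1L, gender = "male", age_years = 60L, race = NA_character_))
  expect_error(load_vcf(db, path, panel_definition("EGFR"), 1L), "ANN")
})

test_that("load_clinical inserts valid rows and skips invariant violations", {
  src <- table1_fixture("ausom_like")
  dir <- tempfile("clin")
  db_save(src, dir)
  db <- init_database()
  rep <- load_clinical(db, list(
    person = file.path(dir, "person.tsv"),
    condition_occurrence = file.path(dir, "condition_occurrence.tsv")))
  expect_identical(rep$rows_read, 228L)
  expect_identical(rep$rows_loaded, 228L)
  expect_identical(nrow(db_table(db, "person")), 114L)
  expect_identical(nrow(db_table(db, "condition_occurrence")), 114L)

  # negative age violates the person invariant and is skipped, not fatal
  db2 <- init_database()
  rep2 <- load_clinical(db2, list(person = data.frame(
    person_id = 1:2, gender = c("male", "female"),
    age_years = c(-3L, 61L), race = NA_character_)))
  expect_identical(rep2$rows_loaded, 1L)
  expect_identical(rep2$skip_reasons$invariant_violation, 1L)

  # empty condition table: no rows, no error
  empty <- file.path(tempdir(), "empty_cond.tsv")
  utils::write.table(db_table(db, "condition_occurrence")[0, ], empty,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rep3 <- load_clinical(init_database(), list(condition_occurrence = empty))
  expect_identical(rep3$rows_read, 0L)
})
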