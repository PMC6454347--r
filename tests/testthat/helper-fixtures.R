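# In-code fixtures shared across test files. Everything is built
# programmatically; no stored data files.

# Minimal populated database: n patients with alternating demographics,
# a small registered panel, and per-patient procedure + target specimen
# rows, ready for add_variant().
make_panel_db <- function(n_patients = 10,
                          genes = c("EGFR", "KRAS", "TP53", "BRAF")) {
  db <- init_database()
  ids <- seq_len(n_patients)
  insert_records(db, "person", data.frame(
    person_id = ids,
    gender = rep(c("male", "female"), length.out = n_patients),
    age_years = 40L + ids, race = NA_character_))
  insert_records(db, "condition_occurrence", data.frame(
    condition_id = ids, person_id = ids,
    condition_name = rep(c("lung adenocarcinoma",
                           "lung squamous cell carcinoma"),
                         length.out = n_patients),
    condition_type = "primary condition", stage = "I"))
  insert_records(db, "care_site",
                 data.frame(care_site_id = 1L, site_name = "test site"))
  insert_records(db, "genomic_test", data.frame(
    genomic_test_id = 1L, care_site_id = 1L, test_name = "test-panel",
    test_version = "1", sequencing_device = NA_character_,
    analytical_tools = NA_character_, reference_databases = NA_character_,
    reference_genome_build = "GRCh37"))
  insert_records(db, "target_gene", data.frame(
    target_gene_id = seq_along(genes), genomic_test_id = 1L,
    hgnc_symbol = genes,
    hgnc_id = vapply(genes, function(g) normalize_gene_symbol(g)$hgnc_id,
                     character(1))))
  insert_records(db, "procedure_occurrence", data.frame(
    procedure_id = ids, person_id = ids,
    acquisition_method = "biopsy", genomic_test_name = "test-panel"))
  insert_records(db, "specimen", data.frame(
    specimen_id = ids, person_id = ids, specimen_role = "target",
    specimen_type = NA_character_, collection_date = NA_character_,
    anatomic_site = "lung"))
  db
}

# Append one variant occurrence for a patient; procedure and specimen ids
# equal the person id in make_panel_db().
add_variant <- function(db, person, gene, hgvs_p = NA_character_,
                        feature = "missense", alteration = "SNP",
                        hgvs_c = NA_character_) {
  tg <- db_table(db, "target_gene")
  gid <- tg$target_gene_id[tg$hgnc_symbol == gene]
  stopifnot(length(gid) == 1)
  insert_records(db, "variant_occurrence", data.frame(
    variant_occurrence_id = nrow(db_table(db, "variant_occurrence")) + 1L,
    procedure_id = person, specimen_id_target = person,
    specimen_id_reference = NA_integer_, target_gene_id = gid,
    reference_sequence = NA_character_, rs_id = NA_character_,
    hgvs_c = hgvs_c, hgvs_p = hgvs_p, read_depth = 500L,
    exon_number = 2L, sequence_alteration = alteration,
    variant_feature = feature, genomic_start = NA_integer_,
    genomic_end = NA_integer_))
  invisible(db)
}

# Canonical three-letter grammar corpus used for the parse/format
# round-trip and idempotence properties (> 50 expressions).
hgvs_corpus <- function() {
  res <- c("Ala", "Arg", "Gly", "Leu", "Ser", "Thr", "Val", "Glu")
  grid <- expand.grid(r = res, a = c("Arg", "Met", "Lys"),
                      stringsAsFactors = FALSE)
  grid <- grid[grid$r != grid$a, ]
  subs <- sprintf("p.%s%d%s", grid$r, 100 + seq_len(nrow(grid)), grid$a)
  c(subs,
    sprintf("p.%s%dTer", res, 30 + seq_along(res)),
    sprintf("p.%s%d=", res, 200 + seq_along(res)),
    sprintf("p.%s%ddel", res, 10 + seq_along(res)),
    "p.Glu746_Ala750del", "p.Lys745_Glu746del",
    "p.Gly12dup", "p.Glu746_Ala750dup",
    "p.Lys745_Glu746insAlaSer", "p.Thr751_Ile759insAsn",
    "p.Leu747_Thr751delinsPro", "p.Glu746delinsValAla",
    "p.Leu747Profs", "p.Leu747ProfsTer12", "p.Gly12fs",
    "p.Ala50ValfsTer9")
}

# One-letter inputs paired with their expected three-letter expansions.
one_letter_cases <- function() {
  c("p.L858R" = "p.Leu858Arg",
    "p.Q61K" = "p.Gln61Lys",
    "p.G12C" = "p.Gly12Cys",
    "p.T790M" = "p.Thr790Met",
    "p.V600E" = "p.Val600Glu",
    "p.W24*" = "p.Trp24Ter",
    "p.G12=" = "p.Gly12=",
    "p.E746_A750del" = "p.Glu746_Ala750del",
    "p.K745_E746insAS" = "p.Lys745_Glu746insAlaSer",
    "p.L747_T751delinsP" = "p.Leu747_Thr751delinsPro",
    "p.L747Pfs*12" = "p.Leu747ProfsTer12",
    "p.G12dup" = "p.Gly12dup")
}

# Write a small MAF file; rows is a data.frame with MAF-dialect columns.
write_maf_fixture <- function(rows, path = tempfile(fileext = ".maf"),
                              comments = c("#version 2.4")) {
  con <- file(path, "w")
  writeLines(comments, con)
  suppressWarnings(utils::write.table(rows, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE, na = ""))
  close(con)
  path
}

default_maf_rows <- function() {
  data.frame(
    Hugo_Symbol = c("EGFR", "KRAS", "TP53"),
    Chromosome = c("7", "12", "17"),
    Start_Position = c("55259515", "25398284", "7577120"),
    End_Position = c("55259515", "25398284", "7577120"),
    Variant_Classification = c("Missense_Mutation", "Missense_Mutation",
                               "Nonsense_Mutation"),
    Variant_Type = c("SNP", "SNP", "SNP"),
    dbSNP_RS = c("rs121434568", "", ""),
    Tumor_Sample_Barcode = c("S1", "S1", "S2"),
    HGVSp_Short = c("p.L858R", "p.G12C", "p.R342*"),
    HGVSc = c("c.2573T>G", "c.34G>T", "c.1024C>T"),
    t_depth = c("512", "433", "208"),
    stringsAsFactors = FALSE)
}

# Sum two aggregate-report count structures element-wise by name.
agg_count_vector <- function(a) {
  u <- unlist(a[c("n_patients", "n_variants", "demographics", "genes",
                  "sequence_alteration", "variant_feature", "actionable",
                  "actionable_denominators")])
  stopifnot(is.numeric(u))
  u
}

agg_sum <- function(a, b) {
  ua <- agg_count_vector(a); ub <- agg_count_vector(b)
  keys <- union(names(ua), names(ub))
  out <- stats::setNames(numeric(length(keys)), keys)
  out[names(ua)] <- out[names(ua)] + ua
  out[names(ub)] <- out[names(ub)] + ub
  out
}
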