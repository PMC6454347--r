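# ETL from standard somatic-variant formats into the model: MAF
# (cBioPortal/TCGA dialect), annotated VCF, and clinical tables in the
# package's own TSV dump dialect. All loaders return a LoadReport with
# rows_read = rows_loaded + rows_skipped, and commit all-or-nothing.

next_id <- function(db, table) {
  pk <- schema_table(table)$primary_key
  x <- db$tables[[table]][[pk]]
  if (length(x) == 0) 1L else max(x) + 1L
}

load_report <- function(rows_read, rows_loaded, skip_reasons = list(),
                        notes = list()) {
  stopifnot(rows_read == rows_loaded + sum(unlist(skip_reasons)))
  structure(list(rows_read = as.integer(rows_read),
                 rows_loaded = as.integer(rows_loaded),
                 rows_skipped = as.integer(rows_read - rows_loaded),
                 skip_reasons = skip_reasons, notes = notes),
            class = "gcdm_load_report")
}

#' @export
print.gcdm_load_report <- function(x, ...) {
  cat(jsonlite::toJSON(unclass(x), auto_unbox = TRUE, pretty = TRUE), "\n")
  invisible(x)
}

# ---- panel definitions ------------------------------------------------------

#' Load a gene-panel definition
#'
#' @param path JSON with the test metadata fields of the genomic-test table
#'   (`test_name`, `test_version`, `sequencing_device`, `analytical_tools`,
#'   `reference_databases`, `reference_genome_build`) and an ordered
#'   `genes` array of HGNC symbols.
#' @param hgnc HGNC table used to canonicalize the symbols; construction
#'   fails if any symbol is unknown or duplicated after canonicalization.
#' @return A `panel_definition`.
#' @export
load_panel <- function(path, hgnc = default_hgnc_table()) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  panel_definition(p$genes, test_name = p$test_name %||% "panel",
                   test_version = p$test_version %||% NA_character_,
                   sequencing_device = p$sequencing_device %||% NA_character_,
                   analytical_tools = p$analytical_tools %||% NA_character_,
                   reference_databases = p$reference_databases %||% NA_character_,
                   reference_genome_build = p$reference_genome_build %||% NA_character_,
                   hgnc = hgnc)
}

#' Construct a panel definition from symbols
#'
#' @param genes Character vector of HGNC symbols or aliases.
#' @param test_name,test_version,sequencing_device,analytical_tools,reference_databases,reference_genome_build
#'   Genomic-test metadata.
#' @param hgnc HGNC table for canonicalization.
#' @return A `panel_definition`: canonical symbols, their accessions, and
#'   the test metadata.
#' @export
panel_definition <- function(genes, test_name = "panel",
                             test_version = NA_character_,
                             sequencing_device = NA_character_,
                             analytical_tools = NA_character_,
                             reference_databases = NA_character_,
                             reference_genome_build = NA_character_,
                             hgnc = default_hgnc_table()) {
  canon <- vapply(genes, function(g) normalize_gene_symbol(g, hgnc)$symbol,
                  character(1), USE.NAMES = FALSE)
  if (anyDuplicated(canon))
    stop(sprintf("panel gene '%s' duplicated after canonicalization",
                 canon[duplicated(canon)][1]), call. = FALSE)
  ids <- vapply(canon, function(g) normalize_gene_symbol(g, hgnc)$hgnc_id,
                character(1), USE.NAMES = FALSE)
  structure(list(genes = canon, hgnc_ids = ids, test_name = test_name,
                 test_version = test_version,
                 sequencing_device = sequencing_device,
                 analytical_tools = analytical_tools,
                 reference_databases = reference_databases,
                 reference_genome_build = reference_genome_build),
            class = "panel_definition")
}

#' Bundled 49-gene cancer-panel definition
#' @return A `panel_definition`.
#' @export
default_panel <- function() {
  load_panel(system.file("extdata", "panel_49genes.json", package = "gcdm",
                         mustWork = TRUE))
}

#' Register a panel in a database
#'
#' Creates (if needed) a care-site row, a genomic-test row carrying the
#' panel's metadata, and one target-gene row per panel gene. Registering
#' the same panel (by test name) twice is a no-op returning the existing
#' registration.
#'
#' @param db A `gcdm_db`.
#' @param panel A `panel_definition`.
#' @param care_site_id Care site to attach the test to (created if absent).
#' @param site_name Name for a newly created care site.
#' @return List with `genomic_test_id` and `gene_ids` (named vector,
#'   symbol to target_gene_id).
#' @export
register_panel <- function(db, panel, care_site_id = 1L,
                           site_name = "default site") {
  stopifnot(inherits(db, "gcdm_db"), inherits(panel, "panel_definition"))
  gt <- db$tables$genomic_test
  hit <- which(gt$test_name == panel$test_name &
                 gt$care_site_id == care_site_id)
  if (length(hit) == 1) {
    gtid <- gt$genomic_test_id[hit]
  } else {
    if (!care_site_id %in% db$tables$care_site$care_site_id)
      insert_records(db, "care_site",
                     data.frame(care_site_id = care_site_id,
                                site_name = site_name))
    gtid <- next_id(db, "genomic_test")
    insert_records(db, "genomic_test", data.frame(
      genomic_test_id = gtid, care_site_id = care_site_id,
      test_name = panel$test_name, test_version = panel$test_version,
      sequencing_device = panel$sequencing_device,
      analytical_tools = panel$analytical_tools,
      reference_databases = panel$reference_databases,
      reference_genome_build = panel$reference_genome_build,
      stringsAsFactors = FALSE))
    insert_records(db, "target_gene", data.frame(
      target_gene_id = next_id(db, "target_gene") +
        seq_along(panel$genes) - 1L,
      genomic_test_id = gtid, hgnc_symbol = panel$genes,
      hgnc_id = panel$hgnc_ids, stringsAsFactors = FALSE))
  }
  tg <- db$tables$target_gene
  tg <- tg[tg$genomic_test_id == gtid, ]
  list(genomic_test_id = gtid,
       gene_ids = stats::setNames(tg$target_gene_id, tg$hgnc_symbol))
}

# ---- MAF --------------------------------------------------------------------

# canonical name -> acceptable headers (lower-cased match)
MAF_COLUMNS <- list(
  hugo_symbol = c("hugo_symbol"),
  variant_classification = c("variant_classification"),
  variant_type = c("variant_type"),
  chromosome = c("chromosome", "chrom"),
  start_position = c("start_position", "start"),
  end_position = c("end_position", "end"),
  dbsnp_rs = c("dbsnp_rs", "dbsnp_rs_id"),
  tumor_sample_barcode = c("tumor_sample_barcode"),
  hgvs_c = c("hgvsc", "hgvs_c"),
  hgvs_p_short = c("hgvsp_short", "hgvsp", "hgvs_p"),
  read_depth = c("t_depth", "read_depth", "dp"),
  exon_number = c("exon_number", "exon"),
  reference_sequence = c("refseq", "transcript_id", "reference_sequence"),
  sv_class = c("sv_class")
)

#' Read a MAF file
#'
#' Tab-separated, `#` comment lines skipped, column names matched
#' case-insensitively against the canonical MAF set (`HGVSp_Short` and
#' `HGVSp` both accepted, `t_depth` used for read depth). The optional
#' non-standard `sv_class` column is the dedicated channel through which
#' panel exports declare CNV and translocation events, which plain MAF
#' cannot express.
#'
#' @param path MAF file.
#' @return A `maf_records` data frame with normalized column names.
#' @export
read_maf <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE)
  have <- tolower(names(df))
  out <- list()
  for (canon in names(MAF_COLUMNS)) {
    i <- which(have %in% MAF_COLUMNS[[canon]])[1]
    out[[canon]] <- if (is.na(i)) rep(NA_character_, nrow(df)) else df[[i]]
  }
  mandatory <- c("hugo_symbol", "variant_classification",
                 "tumor_sample_barcode")
  absent <- mandatory[vapply(mandatory, function(c)
    all(is.na(out[[c]])) && !any(have %in% MAF_COLUMNS[[c]]), logical(1))]
  if (length(absent) > 0)
    stop(sprintf("MAF is missing mandatory column(s): %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  out[] <- lapply(out, function(x) { x[!is.na(x) & x == ""] <- NA; x })
  bad <- which(is.na(out$tumor_sample_barcode))
  if (length(bad) > 0)
    stop(sprintf("MAF record %d has an empty Tumor_Sample_Barcode", bad[1]),
         call. = FALSE)
  s <- suppressWarnings(as.integer(out$start_position))
  e <- suppressWarnings(as.integer(out$end_position))
  bad <- which(!is.na(s) & !is.na(e) & s > e)
  if (length(bad) > 0)
    stop(sprintf("MAF record %d has Start_Position > End_Position", bad[1]),
         call. = FALSE)
  structure(out, class = c("maf_records", "data.frame"))
}

# Decide the structural class of one MAF record. Precedence: explicit
# sv_class column (panel exports) > class implied by the consequence term
# (Frame_Shift_Del etc.) > Variant_Type map > allele-length inference.
resolve_alteration <- function(sv_class, implied, variant_type, mapping) {
  if (!is.na(sv_class)) {
    sa <- map_alteration(sv_class, mapping)
    if (!is.na(sa)) return(sa)
  }
  if (!is.na(implied)) return(implied)
  if (!is.na(variant_type)) {
    sa <- map_alteration(variant_type, mapping)
    if (!is.na(sa)) return(sa)
  }
  NA_character_
}

#' Load MAF records into a database
#'
#' One variant-occurrence row is created per record whose canonicalized
#' gene belongs to the panel; protein HGVS is expanded to three-letter
#' form, consequence terms are mapped to the two-level variant typing, and
#' per-sample procedure and target-specimen rows are created. Only one
#' sample per patient is kept (earliest `collection_dates` entry, ties and
#' missing dates broken lexicographically by barcode); records from other
#' samples are skipped with reason `duplicate_sample`. Records whose gene
#' is off-panel (`off_panel`), whose sample has no patient mapping
#' (`unknown_sample`), or whose structural class cannot be determined
#' (`unknown_alteration`) are skipped with those reasons. The batch
#' commits all-or-nothing.
#'
#' @param db A `gcdm_db` with clinical rows already loaded for the
#'   referenced patients.
#' @param records A `maf_records` data frame from [read_maf()].
#' @param panel A `panel_definition` (registered on first use).
#' @param patient_of_sample Named vector mapping tumor sample barcode to
#'   `person_id`.
#' @param collection_dates Optional named vector mapping barcode to
#'   ISO-8601 specimen collection date.
#' @param mapping A `feature_mapping`.
#' @param hgnc An `hgnc_table`.
#' @param care_site_id Care site for panel registration.
#' @return A `gcdm_load_report`.
#' @export
load_maf <- function(db, records, panel, patient_of_sample,
                     collection_dates = NULL,
                     mapping = default_feature_mapping(),
                     hgnc = default_hgnc_table(), care_site_id = 1L) {
  stopifnot(inherits(db, "gcdm_db"), is.data.frame(records))
  n <- nrow(records)
  backup <- db$tables
  on_error_restore <- function(e) { db$tables <- backup; stop(e) }
  tryCatch({
    reg <- register_panel(db, panel, care_site_id = care_site_id)
    skip <- rep(NA_character_, n)
    person <- unname(patient_of_sample[records$tumor_sample_barcode])
    skip[is.na(person)] <- "unknown_sample"

    # one sample per patient
    samples <- unique(records$tumor_sample_barcode)
    samples <- samples[!is.na(patient_of_sample[samples])]
    sdate <- if (is.null(collection_dates)) rep(NA_character_, length(samples))
             else unname(collection_dates[samples])
    ord <- order(unname(patient_of_sample[samples]),
                 is.na(sdate), sdate, samples)
    samples <- samples[ord]
    keep_sample <- samples[!duplicated(unname(patient_of_sample[samples]))]
    dup <- is.na(skip) & !(records$tumor_sample_barcode %in% keep_sample)
    skip[dup] <- "duplicate_sample"

    canon <- normalize_gene_symbols(records$hugo_symbol, hgnc)
    skip[is.na(skip) & (is.na(canon) | !(canon %in% panel$genes))] <- "off_panel"

    # consequence mapping (vectorized over distinct terms)
    terms <- records$variant_classification
    uterm <- unique(terms[!is.na(terms)])
    cmap <- lapply(uterm, function(t)
      suppressWarnings(map_consequence(t, mapping)))
    names(cmap) <- uterm
    vf <- vapply(terms, function(t)
      if (is.na(t)) "other" else cmap[[t]]$variant_feature, character(1),
      USE.NAMES = FALSE)
    implied <- vapply(terms, function(t)
      if (is.na(t)) NA_character_ else cmap[[t]]$sequence_alteration,
      character(1), USE.NAMES = FALSE)
    sa <- vapply(seq_len(n), function(i)
      resolve_alteration(records$sv_class[i], implied[i],
                         records$variant_type[i], mapping), character(1))
    skip[is.na(skip) & is.na(sa)] <- "unknown_alteration"

    hgvs_dropped <- 0L
    hp <- vapply(records$hgvs_p_short, function(x) {
      if (is.na(x)) return(NA_character_)
      tryCatch(expand_protein_hgvs(x, allow_wildcard = FALSE),
               error = function(e) { hgvs_dropped <<- hgvs_dropped + 1L
                                     NA_character_ })
    }, character(1), USE.NAMES = FALSE)

    keep <- which(is.na(skip))
    # per-sample clinical plumbing
    kept_samples <- unique(records$tumor_sample_barcode[keep])
    if (length(kept_samples) > 0) {
      pid <- unname(patient_of_sample[kept_samples])
      proc_ids <- next_id(db, "procedure_occurrence") +
        seq_along(kept_samples) - 1L
      spec_ids <- next_id(db, "specimen") + seq_along(kept_samples) - 1L
      insert_records(db, "procedure_occurrence", data.frame(
        procedure_id = proc_ids, person_id = pid,
        acquisition_method = NA_character_,
        genomic_test_name = panel$test_name, stringsAsFactors = FALSE))
      insert_records(db, "specimen", data.frame(
        specimen_id = spec_ids, person_id = pid, specimen_role = "target",
        specimen_type = NA_character_,
        collection_date = if (is.null(collection_dates)) NA_character_
                          else unname(collection_dates[kept_samples]),
        anatomic_site = NA_character_, stringsAsFactors = FALSE))
      si <- match(records$tumor_sample_barcode[keep], kept_samples)
      vo <- data.frame(
        variant_occurrence_id = next_id(db, "variant_occurrence") +
          seq_along(keep) - 1L,
        procedure_id = proc_ids[si],
        specimen_id_target = spec_ids[si],
        specimen_id_reference = NA_integer_,
        target_gene_id = unname(reg$gene_ids[canon[keep]]),
        reference_sequence = records$reference_sequence[keep],
        rs_id = records$dbsnp_rs[keep],
        hgvs_c = records$hgvs_c[keep],
        hgvs_p = hp[keep],
        read_depth = suppressWarnings(as.integer(records$read_depth[keep])),
        exon_number = suppressWarnings(as.integer(records$exon_number[keep])),
        sequence_alteration = sa[keep],
        variant_feature = vf[keep],
        genomic_start = suppressWarnings(as.integer(records$start_position[keep])),
        genomic_end = suppressWarnings(as.integer(records$end_position[keep])),
        stringsAsFactors = FALSE)
      insert_records(db, "variant_occurrence", vo)
    }
    reasons <- as.list(table(skip[!is.na(skip)]))
    load_report(n, length(keep), reasons,
                notes = if (hgvs_dropped > 0)
                  list(hgvs_unparseable = hgvs_dropped) else list())
  }, error = on_error_restore)
}

# ---- VCF --------------------------------------------------------------------

# VCF -> 1-based inclusive (MAF-convention) coordinates, stripping the
# shared anchor base of indels. Returns start, end and the structural class.
vcf_to_maf_coords <- function(pos, ref, alt) {
  pos <- as.integer(pos)
  if (nchar(ref) == nchar(alt)) {
    cls <- if (nchar(ref) == 1) "SNP" else "MNP"
    return(list(start = pos, end = pos + nchar(ref) - 1L, class = cls))
  }
  if (substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substring(ref, 2); alt <- substring(alt, 2); pos <- pos + 1L
  }
  if (nchar(alt) == 0 || nchar(ref) > nchar(alt)) {
    return(list(start = pos, end = pos + nchar(ref) - 1L,
                class = "deletion"))
  }
  # insertion: flanked by the base before and the base after
  list(start = pos - 1L, end = pos, class = "insertion")
}

#' Load an annotated VCF into a database
#'
#' One variant-occurrence row is created per ALT allele of each record
#' passing FILTER (`PASS` or `.`); others are skipped with reason
#' `filter_failed`. Consequence annotation is taken from a configurable
#' INFO field whose `|`-separated sub-field order is given in
#' `annotation_spec`; for multi-allelic records the i-th annotation entry
#' annotates the i-th ALT allele. Read depth comes from `DP`; indel
#' coordinates are converted to the 1-based inclusive convention used
#' throughout the model. Alleles in off-panel genes are skipped with
#' reason `off_panel`, malformed annotation entries with
#' `malformed_annotation`.
#'
#' @param db A `gcdm_db` with the patient's person row loaded.
#' @param path VCF (v4.x, uncompressed or bgzipped).
#' @param panel A `panel_definition`.
#' @param person_id Patient the single-sample VCF belongs to.
#' @param annotation_spec List with `field` (INFO key, default `"ANN"`),
#'   `fields` (sub-field order, default
#'   `c("gene", "consequence", "hgvs_c", "hgvs_p")`) and `sep`
#'   (default `"|"`).
#' @param mapping A `feature_mapping`.
#' @param hgnc An `hgnc_table`.
#' @param care_site_id Care site for panel registration.
#' @return A `gcdm_load_report`.
#' @export
load_vcf <- function(db, path, panel, person_id,
                     annotation_spec = list(field = "ANN",
                                            fields = c("gene", "consequence",
                                                       "hgvs_c", "hgvs_p"),
                                            sep = "|"),
                     mapping = default_feature_mapping(),
                     hgnc = default_hgnc_table(), care_site_id = 1L) {
  stopifnot(inherits(db, "gcdm_db"))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  info_meta <- vcf@meta[grepl(sprintf("^##INFO=<ID=%s[,>]",
                                      annotation_spec$field), vcf@meta)]
  if (length(info_meta) == 0)
    stop(sprintf("VCF lacks the annotation INFO field '%s'",
                 annotation_spec$field), call. = FALSE)
  ann_raw <- vcfR::extract.info(vcf, element = annotation_spec$field)
  dp_raw <- suppressWarnings(
    as.integer(vcfR::extract.info(vcf, element = "DP")))

  backup <- db$tables
  tryCatch({
    reg <- register_panel(db, panel, care_site_id = care_site_id)
    proc_id <- next_id(db, "procedure_occurrence")
    spec_id <- next_id(db, "specimen")
    insert_records(db, "procedure_occurrence", data.frame(
      procedure_id = proc_id, person_id = person_id,
      acquisition_method = NA_character_,
      genomic_test_name = panel$test_name, stringsAsFactors = FALSE))
    insert_records(db, "specimen", data.frame(
      specimen_id = spec_id, person_id = person_id, specimen_role = "target",
      specimen_type = NA_character_, collection_date = NA_character_,
      anatomic_site = NA_character_, stringsAsFactors = FALSE))

    rows <- list(); reasons <- character(0); n_alleles <- 0L
    for (i in seq_len(nrow(fix))) {
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
      anns <- if (is.na(ann_raw[i])) character(0)
              else strsplit(ann_raw[i], ",", fixed = TRUE)[[1]]
      for (j in seq_along(alts)) {
        n_alleles <- n_alleles + 1L
        filt <- fix$FILTER[i]
        if (!is.na(filt) && !(filt %in% c("PASS", "."))) {
          reasons <- c(reasons, "filter_failed"); next
        }
        ann <- if (j <= length(anns)) anns[j] else NA_character_
        if (is.na(ann)) { reasons <- c(reasons, "malformed_annotation"); next }
        parts <- strsplit(ann, annotation_spec$sep, fixed = TRUE)[[1]]
        fields <- stats::setNames(
          parts[seq_along(annotation_spec$fields)], annotation_spec$fields)
        if (is.na(fields["gene"]) || is.na(fields["consequence"]) ||
            fields["gene"] == "") {
          reasons <- c(reasons, "malformed_annotation"); next
        }
        gene <- normalize_gene_symbols(fields[["gene"]], hgnc)
        if (is.na(gene) || !(gene %in% panel$genes)) {
          reasons <- c(reasons, "off_panel"); next
        }
        cons <- suppressWarnings(map_consequence(fields[["consequence"]],
                                                 mapping))
        crd <- vcf_to_maf_coords(fix$POS[i], fix$REF[i], alts[j])
        hp <- fields[["hgvs_p"]]
        hp <- if (is.na(hp) || hp == "") NA_character_ else
          tryCatch(expand_protein_hgvs(hp, allow_wildcard = FALSE),
                   error = function(e) NA_character_)
        rows[[length(rows) + 1]] <- data.frame(
          variant_occurrence_id = NA_integer_,  # assigned below
          procedure_id = proc_id, specimen_id_target = spec_id,
          specimen_id_reference = NA_integer_,
          target_gene_id = unname(reg$gene_ids[gene]),
          reference_sequence = NA_character_,
          rs_id = if (is.na(fix$ID[i]) || fix$ID[i] == ".") NA_character_
                  else fix$ID[i],
          hgvs_c = if (is.na(fields["hgvs_c"]) || fields[["hgvs_c"]] == "")
                     NA_character_ else fields[["hgvs_c"]],
          hgvs_p = hp, read_depth = dp_raw[i], exon_number = NA_integer_,
          sequence_alteration = if (!is.na(cons$sequence_alteration))
            cons$sequence_alteration else crd$class,
          variant_feature = cons$variant_feature,
          genomic_start = crd$start, genomic_end = crd$end,
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows) > 0) {
      vo <- do.call(rbind, rows)
      vo$variant_occurrence_id <- next_id(db, "variant_occurrence") +
        seq_len(nrow(vo)) - 1L
      insert_records(db, "variant_occurrence", vo)
    }
    load_report(n_alleles, length(rows), as.list(table(reasons)))
  }, error = function(e) { db$tables <- backup; stop(e) })
}

# ---- clinical tables --------------------------------------------------------

#' Load clinical tables from delimited files
#'
#' Accepts a named list (names are table names: `person`,
#' `condition_occurrence`, `procedure_occurrence`, `specimen`,
#' `care_site`) of file paths or data frames in the dump dialect of
#' [db_save()]. Rows violating a column or key invariant are skipped with
#' reason `invariant_violation`; valid rows are inserted. Tables load in
#' dependency order regardless of the order given.
#'
#' @param db A `gcdm_db`.
#' @param tables Named list of paths or data frames.
#' @return A `gcdm_load_report` aggregated over all tables.
#' @export
load_clinical <- function(db, tables) {
  stopifnot(inherits(db, "gcdm_db"), is.list(tables))
  order_pref <- c("care_site", "person", "condition_occurrence",
                  "procedure_occurrence", "specimen")
  unknown <- setdiff(names(tables), order_pref)
  if (length(unknown) > 0)
    stop(sprintf("not a clinical table: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  total_read <- 0L; total_loaded <- 0L; reasons <- list()
  for (nm in intersect(order_pref, names(tables))) {
    x <- tables[[nm]]
    if (!is.data.frame(x))
      x <- utils::read.delim(x, colClasses = "character", na.strings = "",
                             check.names = FALSE)
    total_read <- total_read + nrow(x)
    if (nrow(x) == 0) next
    tbl <- schema_table(nm)
    df <- coerce_rows(tbl, x, where = "load_clinical")
    viol <- rbind(check_columns(tbl, df), check_keys(tbl, df, db),
                  check_references(tbl, df, db))
    bad <- unique(viol$row)
    good <- setdiff(seq_len(nrow(df)), bad)
    if (length(good) > 0)
      insert_records(db, nm, df[good, , drop = FALSE])
    total_loaded <- total_loaded + length(good)
    if (length(bad) > 0)
      reasons$invariant_violation <- (reasons$invariant_violation %||% 0L) +
        length(bad)
  }
  load_report(total_read, total_loaded, reasons)
}
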