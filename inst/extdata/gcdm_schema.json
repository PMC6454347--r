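{
  "schema_version": "1.0",
  "vocabularies": {
    "gender": ["male", "female", "unknown"],
    "stage": ["I", "II", "III", "IV", "unknown"],
    "specimen_role": ["target", "reference"],
    "sequence_alteration": ["SNP", "insertion", "deletion", "MNP", "CNV", "translocation"],
    "variant_feature": ["missense", "nonsense", "frameshift", "inframe", "splice", "synonymous", "intron", "other"],
    "variant_origin": ["somatic", "germline", "unknown"]
  },
  "tables": [
    {
      "name": "person",
      "primary_key": "person_id",
      "columns": [
        {"name": "person_id", "type": "integer", "nullable": false},
        {"name": "gender", "type": "text", "nullable": false, "vocabulary": "gender"},
        {"name": "age_years", "type": "integer", "nullable": true, "min": 0, "max": 149},
        {"name": "race", "type": "text", "nullable": true}
      ]
    },
    {
      "name": "condition_occurrence",
      "primary_key": "condition_id",
      "columns": [
        {"name": "condition_id", "type": "integer", "nullable": false},
        {"name": "person_id", "type": "integer", "nullable": false,
         "references": {"table": "person", "column": "person_id"}},
        {"name": "condition_name", "type": "text", "nullable": false},
        {"name": "condition_type", "type": "text", "nullable": true},
        {"name": "stage", "type": "text", "nullable": false, "vocabulary": "stage"}
      ]
    },
    {
      "name": "procedure_occurrence",
      "primary_key": "procedure_id",
      "columns": [
        {"name": "procedure_id", "type": "integer", "nullable": false},
        {"name": "person_id", "type": "integer", "nullable": false,
         "references": {"table": "person", "column": "person_id"}},
        {"name": "acquisition_method", "type": "text", "nullable": true},
        {"name": "genomic_test_name", "type": "text", "nullable": true}
      ]
    },
    {
      "name": "specimen",
      "primary_key": "specimen_id",
      "columns": [
        {"name": "specimen_id", "type": "integer", "nullable": false},
        {"name": "person_id", "type": "integer", "nullable": false,
         "references": {"table": "person", "column": "person_id"}},
        {"name": "specimen_role", "type": "text", "nullable": false, "vocabulary": "specimen_role"},
        {"name": "specimen_type", "type": "text", "nullable": true},
        {"name": "collection_date", "type": "date", "nullable": true},
        {"name": "anatomic_site", "type": "text", "nullable": true}
      ]
    },
    {
      "name": "care_site",
      "primary_key": "care_site_id",
      "columns": [
        {"name": "care_site_id", "type": "integer", "nullable": false},
        {"name": "site_name", "type": "text", "nullable": true}
      ]
    },
    {
      "name": "genomic_test",
      "primary_key": "genomic_test_id",
      "columns": [
        {"name": "genomic_test_id", "type": "integer", "nullable": false},
        {"name": "care_site_id", "type": "integer", "nullable": false,
         "references": {"table": "care_site", "column": "care_site_id"}},
        {"name": "test_name", "type": "text", "nullable": true},
        {"name": "test_version", "type": "text", "nullable": true},
        {"name": "sequencing_device", "type": "text", "nullable": true},
        {"name": "analytical_tools", "type": "text", "nullable": true},
        {"name": "reference_databases", "type": "text", "nullable": true},
        {"name": "reference_genome_build", "type": "text", "nullable": true}
      ]
    },
    {
      "name": "target_gene",
      "primary_key": "target_gene_id",
      "unique": [["genomic_test_id", "hgnc_symbol"]],
      "columns": [
        {"name": "target_gene_id", "type": "integer", "nullable": false},
        {"name": "genomic_test_id", "type": "integer", "nullable": false,
         "references": {"table": "genomic_test", "column": "genomic_test_id"}},
        {"name": "hgnc_symbol", "type": "text", "nullable": false},
        {"name": "hgnc_id", "type": "text", "nullable": true}
      ]
    },
    {
      "name": "variant_occurrence",
      "primary_key": "variant_occurrence_id",
      "columns": [
        {"name": "variant_occurrence_id", "type": "integer", "nullable": false},
        {"name": "procedure_id", "type": "integer", "nullable": false,
         "references": {"table": "procedure_occurrence", "column": "procedure_id"}},
        {"name": "specimen_id_target", "type": "integer", "nullable": false,
         "references": {"table": "specimen", "column": "specimen_id"}},
        {"name": "specimen_id_reference", "type": "integer", "nullable": true,
         "references": {"table": "specimen", "column": "specimen_id"}},
        {"name": "target_gene_id", "type": "integer", "nullable": false,
         "references": {"table": "target_gene", "column": "target_gene_id"}},
        {"name": "reference_sequence", "type": "text", "nullable": true},
        {"name": "rs_id", "type": "text", "nullable": true},
        {"name": "hgvs_c", "type": "text", "nullable": true},
        {"name": "hgvs_p", "type": "text", "nullable": true},
        {"name": "read_depth", "type": "integer", "nullable": true, "min": 0},
        {"name": "exon_number", "type": "integer", "nullable": true, "min": 1},
        {"name": "sequence_alteration", "type": "text", "nullable": false, "vocabulary": "sequence_alteration"},
        {"name": "variant_feature", "type": "text", "nullable": false, "vocabulary": "variant_feature"},
        {"name": "genomic_start", "type": "integer", "nullable": true, "min": 1},
        {"name": "genomic_end", "type": "integer", "nullable": true, "min": 1}
      ]
    },
    {
      "name": "variant_annotation",
      "primary_key": "variant_annotation_id",
      "columns": [
        {"name": "variant_annotation_id", "type": "integer", "nullable": false},
        {"name": "variant_occurrence_id", "type": "integer", "nullable": false,
         "references": {"table": "variant_occurrence", "column": "variant_occurrence_id"}},
        {"name": "annotation_db_name", "type": "text", "nullable": true},
        {"name": "annotation_db_version", "type": "text", "nullable": true},
        {"name": "variant_origin", "type": "text", "nullable": false, "vocabulary": "variant_origin"},
        {"name": "pathogenicity", "type": "text", "nullable": true},
        {"name": "allele_frequency", "type": "number", "nullable": true, "min": 0, "max": 1},
        {"name": "medication", "type": "text", "nullable": true}
      ]
    }
  ]
}
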