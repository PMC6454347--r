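{
  "name": "maf-default",
  "version": "1.0",
  "variant_feature": {
    "Missense_Mutation": "missense",
    "Nonsense_Mutation": "nonsense",
    "Nonstop_Mutation": "other",
    "Frame_Shift_Del": "frameshift",
    "Frame_Shift_Ins": "frameshift",
    "In_Frame_Del": "inframe",
    "In_Frame_Ins": "inframe",
    "Splice_Site": "splice",
    "Splice_Region": "splice",
    "Silent": "synonymous",
    "Intron": "intron",
    "3'UTR": "other",
    "5'UTR": "other",
    "3'Flank": "other",
    "5'Flank": "other",
    "IGR": "other",
    "RNA": "other",
    "Translation_Start_Site": "other",
    "Targeted_Region": "other",
    "missense_variant": "missense",
    "stop_gained": "nonsense",
    "stop_lost": "other",
    "start_lost": "other",
    "frameshift_variant": "frameshift",
    "inframe_deletion": "inframe",
    "inframe_insertion": "inframe",
    "splice_acceptor_variant": "splice",
    "splice_donor_variant": "splice",
    "splice_region_variant": "splice",
    "synonymous_variant": "synonymous",
    "intron_variant": "intron",
    "5_prime_UTR_variant": "other",
    "3_prime_UTR_variant": "other",
    "upstream_gene_variant": "other",
    "downstream_gene_variant": "other"
  },
  "sequence_alteration_from_feature": {
    "Frame_Shift_Del": "deletion",
    "Frame_Shift_Ins": "insertion",
    "In_Frame_Del": "deletion",
    "In_Frame_Ins": "insertion",
    "inframe_deletion": "deletion",
    "inframe_insertion": "insertion"
  },
  "sequence_alteration": {
    "SNP": "SNP",
    "SNV": "SNP",
    "INS": "insertion",
    "DEL": "deletion",
    "DNP": "MNP",
    "TNP": "MNP",
    "ONP": "MNP",
    "MNP": "MNP",
    "CNV": "CNV",
    "AMP": "CNV",
    "LOSS": "CNV",
    "TRANSLOCATION": "translocation",
    "SV": "translocation",
    "FUSION": "translocation"
  }
}
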