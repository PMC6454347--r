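{
  "test_name": "cancer-panel-49",
  "test_version": "1.0",
  "sequencing_device": "bench-top NGS sequencer",
  "analytical_tools": "aligner+caller pipeline",
  "reference_databases": "dbSNP;COSMIC",
  "reference_genome_build": "GRCh37",
  "genes": [
    "TP53", "EGFR", "KRAS", "PIK3CA", "BRAF", "NRAS", "RET", "ALK", "ROS1",
    "MET", "ERBB2", "ERBB4", "AKT1", "PTEN", "STK11", "KEAP1", "NF1", "RB1",
    "CDKN2A", "ATM", "APC", "SMAD4", "FBXW7", "NOTCH1", "FGFR1", "FGFR2",
    "FGFR3", "IDH1", "IDH2", "JAK2", "JAK3", "KIT", "PDGFRA", "ABL1",
    "CTNNB1", "DDR2", "GNAS", "GNAQ", "HRAS", "MAP2K1", "MLH1", "MTOR",
    "SMARCA4", "SMO", "SRC", "VHL", "KDR", "CSF1R", "PTPN11"
  ]
}
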