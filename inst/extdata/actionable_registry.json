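{
  "name": "nsclc-default",
  "version": "1.0",
  "genes": {
    "EGFR": ["p.Leu858Arg", "p.Thr790Met"],
    "KRAS": ["p.Gly12Xaa", "p.Gly13Xaa"],
    "BRAF": ["p.Val600Glu"],
    "NRAS": ["p.Gln61Xaa"],
    "PIK3CA": ["p.Glu542Lys", "p.Glu545Lys", "p.His1047Arg"]
  },
  "notes": "EGFR point mutations and KRAS codon 12/13 wildcard groups are the NCCN-named NSCLC hotspots; BRAF, NRAS and PIK3CA entries are conventional hotspot defaults shipped for completeness and freely editable."
}
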