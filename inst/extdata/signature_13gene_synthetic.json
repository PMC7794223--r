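{
  "name": "default-13gene (partially synthetic placeholders)",
  "constituent": ["TERT", "TERC"],
  "markers": ["LIN9", "HELLS", "POLE2",
              "SYNM04", "SYNM05", "SYNM06", "SYNM07",
              "SYNM08", "SYNM09", "SYNM10", "SYNM11"],
  "note": "Only TERT, TERC, LIN9, HELLS and POLE2 are attested marker/constituent identities; SYNM04..SYNM11 are synthetic placeholders standing in for the published supplementary marker list, which must be substituted before scoring real data."
}
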