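.datatable.aware <- TRUE

utils::globalVariables(c(
  "precursor_quantity", "precursor_id", "protein_group", "stripped_sequence",
  "run_id", "protein_id", "quantity"))
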