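alleles:
  A: N2
  B: CB4856
panel_kind: IL
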