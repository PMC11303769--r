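>AmelX_synthetic constructed amelogenin-like X-isoform stand-in
MGTWILFACLLGAAFSMPLPPHPGHPGYINHSYEVLTPLKWYESMIRHPYPSYGYEPMGGWINHSYENSHSAINVQQHPPQHTLQPHHQPNLPPLEAWPSTDKTKREEVD
>AmelY_synthetic constructed amelogenin-like Y-isoform stand-in
MGTWILFACLLGAAFSMPLPPHPGHPGYINHSYEVLTPLKWYEAVLRYPYPSYGYEPMGGWINHSYENSHSAINVQQHPPQHTLQPHHQPNLPPLEAWPSTDKTKREEVD
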