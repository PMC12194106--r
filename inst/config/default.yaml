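in_channels: 3
stage_widths:
- 24
- 52
- 104
- 256
bottleneck_width: 840
dilation_rates:
- 1
- 3
- 5
- 7
attention_heads: 1
gsa_reduction: 8
encoder_variant: RDI
bottleneck_variant: DTA
skip_variant: CASC
input_size: 256
casc_grid: 32
attn_scale: sqrt
upsample_mode: deconv
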