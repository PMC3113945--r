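# Example style configuration: unspecified entries keep package defaults.
font: builtin5x7
colors:
  background: "#FFFFFF"
  reaction: "#0000BB"
  cluster: "#E8F0E8"
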