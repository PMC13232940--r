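# Two-condition base model: b and dA shared across presentation formats,
# guessing split fixed at 1/6 (stored as the literal 0.16667).
conditions: [combined, separate]
guess_split: 0.16667
equal:
  b: all
  dA: all
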