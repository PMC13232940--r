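# Four-condition base model (format x number of culprit-present lineups):
# b and dA shared across all conditions.
conditions: [combined_three, separate_three, combined_one, separate_one]
guess_split: 0.16667
equal:
  b: all
  dA: all
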