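# Frame-schedule presets for the two emulated acquisition protocols.
# Each schedule is a list of {count, duration_s} blocks; frames are
# contiguous starting at 0 s.
study1_26f:
  - {count: 1, duration_s: 30}
  - {count: 4, duration_s: 60}
  - {count: 3, duration_s: 120}
  - {count: 3, duration_s: 180}
  - {count: 15, duration_s: 300}
study2_32f:
  - {count: 8, duration_s: 15}
  - {count: 3, duration_s: 60}
  - {count: 5, duration_s: 120}
  - {count: 16, duration_s: 300}
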