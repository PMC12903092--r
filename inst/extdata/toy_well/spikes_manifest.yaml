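duration_s: 300.0
sampling_rate_hz: 12500.0
wells:
  A1:
    line: toy
    group: toy
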