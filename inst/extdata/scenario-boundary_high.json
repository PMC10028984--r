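{
  "name": "boundary_high",
  "intensity": 1,
  "on_intervals": [
    [0, 93]
  ],
  "mask": [
    ["-Inf", 0]
  ],
  "pulse_cadence": "0.6 s every 30 s, treated as continuous",
  "schedule": {
    "cycles": [
      {
        "cycle": 10,
        "start": 0,
        "end": 2.5
      },
      {
        "cycle": 11,
        "start": 7,
        "end": 16
      },
      {
        "cycle": 12,
        "start": 18,
        "end": 30
      },
      {
        "cycle": 13,
        "start": 32,
        "end": 45
      },
      {
        "cycle": 14,
        "start": 48,
        "end": 93
      }
    ],
    "gastrulation_time": 93
  }
}
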