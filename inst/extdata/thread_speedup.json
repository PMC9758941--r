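{
  "description": "Normalized multithreading speed-up relative to a single thread, averaged over database/query size combinations and node types, for two query sets (A: bacterial metagenomic short reads, 90-150 bp; B: spiked viral/HeLa short reads, 101 bp). Predictions at t threads are divided by the factor for t.",
  "speedup": {
    "A": { "1": 1.00, "2": 1.12, "4": 1.20, "8": 1.24 },
    "B": { "1": 1.00, "2": 1.25, "4": 1.40, "8": 1.53 }
  }
}
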