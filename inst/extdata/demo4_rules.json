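{
  "nodes": ["v1", "v2", "v3", "v4"],
  "rules": {
    "v1": {
      "type": "ncf",
      "regulators": [
        "v2"
      ],
      "canalyzing": 1,
      "canalyzed": 0,
      "default": 1
    },
    "v2": {
      "type": "ncf",
      "regulators": [
        "v3",
        "v4"
      ],
      "canalyzing": [0, 1],
      "canalyzed": [1, 0],
      "default": 1
    },
    "v3": {
      "type": "ncf",
      "regulators": [
        "v4"
      ],
      "canalyzing": 0,
      "canalyzed": 1,
      "default": 0
    },
    "v4": {
      "type": "ncf",
      "regulators": [
        "v1"
      ],
      "canalyzing": 1,
      "canalyzed": 0,
      "default": 1
    }
  }
}
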