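{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "clockrace run configuration",
  "type": "object",
  "required": ["seed", "out_dir"],
  "additionalProperties": false,
  "properties": {
    "seed": {
      "type": "integer",
      "description": "Master seed; all stage seeds are derived from it."
    },
    "out_dir": {
      "type": "string",
      "description": "Directory receiving traces.csv, features.csv, exit_by_offset.csv and summary.json."
    },
    "preset": {
      "type": "string",
      "enum": ["MCF10A", "RPE1", "RPE1_CCNA2dd", "RPE1_CCNA2dd_DIA", "U2OS"],
      "default": "MCF10A"
    },
    "treatment": {
      "type": "string",
      "enum": ["DMSO", "MITOGEN_REMOVAL", "MEKI", "CDK46I", "CDK1I",
               "CDK46I_CDK1I", "MEKI_DOSE"],
      "default": "CDK46I"
    },
    "n_cells": {"type": "integer", "minimum": 1, "default": 500},
    "n_race": {"type": "integer", "minimum": 1, "default": 100000},
    "decay_n": {"type": "integer", "minimum": 1, "default": 100},
    "decay_noise_cv": {"type": "number", "minimum": 0, "default": 0.04}
  }
}
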