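{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "mrnaqc QC report",
  "description": "Machine-readable quality report for a plasmid template or mRNA product sequencing run. Absent analyses are explicit nulls, never omitted.",
  "type": "object",
  "required": ["mode", "schema_version", "inputs", "success", "mapping",
               "length", "error", "consensus", "classes", "polya",
               "antisense", "cryptic_tss", "modification"],
  "properties": {
    "mode": {"enum": ["plasmid", "mrna"]},
    "schema_version": {"const": "1.0"},
    "success": {"type": "boolean"},
    "inputs": {
      "type": "object",
      "required": ["paths", "parameters", "tool_version"],
      "properties": {
        "paths": {"type": "object"},
        "parameters": {"type": "object"},
        "seed": {"type": ["integer", "null"]},
        "tool_version": {"type": "string"}
      }
    },
    "mapping": {
      "type": "object",
      "required": ["n_records", "n_primary", "n_mapped", "n_pass_filter",
                   "mapped_fraction"],
      "properties": {
        "mapped_fraction": {"type": "number", "minimum": 0, "maximum": 1},
        "unmapped_triage_fractions": {"type": ["object", "null"]}
      }
    },
    "length": {
      "type": ["object", "null"],
      "properties": {
        "n": {"type": "integer"},
        "mean": {"type": ["number", "null"]},
        "median": {"type": ["number", "null"]},
        "expected_length": {"type": ["integer", "null"]},
        "size_fraction": {"type": ["number", "null"], "minimum": 0, "maximum": 1}
      }
    },
    "error": {
      "type": ["object", "null"],
      "properties": {
        "global": {"type": "object"},
        "per_region": {"type": "object"},
        "corrected_global": {"type": "object"}
      }
    },
    "consensus": {
      "type": ["object", "null"],
      "properties": {
        "n_positions": {"type": "integer"},
        "n_masked": {"type": "integer"},
        "n_variants": {"type": "integer"},
        "identity_over_covered": {"type": ["number", "null"]}
      }
    },
    "classes": {
      "type": ["object", "null"],
      "properties": {
        "counts": {"type": "object"},
        "fractions": {"type": "object"},
        "antisense_fraction": {"type": "number", "minimum": 0, "maximum": 1},
        "upstream_fraction": {"type": "number", "minimum": 0, "maximum": 1},
        "downstream_fraction": {"type": "number", "minimum": 0, "maximum": 1},
        "on_target_fraction": {"type": "number", "minimum": 0, "maximum": 1}
      }
    },
    "polya": {
      "type": ["object", "null"],
      "properties": {
        "expected_length": {"type": "integer"},
        "deletion_rate": {"type": "number", "minimum": 0, "maximum": 1},
        "mean": {"type": "number"},
        "median": {"type": "number"},
        "n_used": {"type": "integer"},
        "n_excluded": {"type": "integer"}
      }
    },
    "antisense": {
      "type": ["object", "null"],
      "properties": {
        "fraction": {"type": ["number", "null"], "minimum": 0, "maximum": 1}
      }
    },
    "cryptic_tss": {
      "type": ["object", "null"],
      "properties": {
        "n_sites": {"type": "integer"},
        "total_fraction": {"type": "number"},
        "sites": {"type": ["array", "null"]}
      }
    },
    "modification": {
      "type": ["object", "null"],
      "properties": {
        "n_scored": {"type": "integer"},
        "n_flagged": {"type": "integer"},
        "flagged_fraction": {"type": ["number", "null"]},
        "mean_score": {"type": ["number", "null"]}
      }
    }
  }
}
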