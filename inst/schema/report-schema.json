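{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "probeseize pipeline report",
  "type": "object",
  "required": ["provenance", "stages", "manifest"],
  "properties": {
    "provenance": {
      "type": "object",
      "required": ["config_hash", "package_version", "seed"],
      "properties": {
        "config_hash": {"type": "string"},
        "package_version": {"type": "string"},
        "seed": {"type": "integer"}
      }
    },
    "stages": {"type": "object"},
    "manifest": {"type": "array", "items": {"type": "string"}}
  }
}
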