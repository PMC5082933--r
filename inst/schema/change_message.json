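{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "tcgavault change message",
  "description": "One message per added, modified or deleted repository file, emitted after each sync run for loading into downstream systems.",
  "type": "object",
  "required": ["logical_id", "action", "repo_version", "local_path", "md5", "run_id"],
  "properties": {
    "logical_id":   {"type": "string", "minLength": 1},
    "action":       {"type": "string", "enum": ["added", "modified", "deleted"]},
    "repo_version": {"type": "integer", "minimum": 1},
    "local_path":   {"type": "string"},
    "md5":          {"type": "string", "pattern": "^[0-9a-f]{32}$|^$"},
    "run_id":       {"type": "string", "minLength": 1},
    "datatype":     {"type": "string"},
    "barcode":      {"type": "string"},
    "timestamp":    {"type": "string"}
  },
  "additionalProperties": false
}
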