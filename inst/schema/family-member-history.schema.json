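{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "FamilyMemberHistory-style chain output",
  "description": "Shape of the FHIR-style JSON emitted by write_fhir(): one object per family-member chain with condition sub-entries.",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["resourceType", "fileName", "relationship", "sideOfFamily", "condition"],
    "properties": {
      "resourceType": {"const": "FamilyMemberHistory"},
      "fileName": {"type": "string"},
      "relationship": {
        "type": "object",
        "required": ["text"],
        "properties": {"text": {"type": "string", "minLength": 1}}
      },
      "sideOfFamily": {"enum": ["Maternal", "Paternal", "NA"]},
      "age": {
        "type": "object",
        "properties": {
          "value": {"type": "integer", "minimum": 0, "maximum": 130},
          "kind": {"enum": ["exact", "decade"]}
        }
      },
      "condition": {
        "type": "array",
        "items": {
          "type": "object",
          "required": ["kind", "text", "certainty"],
          "properties": {
            "kind": {"enum": ["observation", "living_status"]},
            "text": {"type": "string", "minLength": 1},
            "certainty": {"enum": ["negated", "nonnegated"]},
            "code": {
              "type": "object",
              "properties": {
                "cui": {"type": "string", "pattern": "^C[0-9]{7}$"},
                "snomed": {"type": "string", "pattern": "^[0-9]+$"}
              }
            }
          }
        }
      }
    }
  }
}
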