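{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "mi2castr canonical causal-statement document",
  "type": "object",
  "required": ["mi2cast_schema", "statements"],
  "properties": {
    "mi2cast_schema": {"const": "1.0"},
    "statements": {
      "type": "array",
      "items": {"$ref": "#/$defs/statement"}
    }
  },
  "$defs": {
    "curie": {"type": "string", "pattern": "^[a-z0-9._-]+:\\S+$"},
    "modification": {
      "type": "object",
      "required": ["modification_type"],
      "properties": {
        "modification_type": {"$ref": "#/$defs/curie"},
        "residue": {"$ref": "#/$defs/curie"},
        "position": {"type": "integer", "minimum": 1}
      }
    },
    "context": {
      "type": "object",
      "properties": {
        "biological_activity": {"$ref": "#/$defs/curie"},
        "modifications": {
          "type": "array",
          "items": {"$ref": "#/$defs/modification"}
        },
        "taxon": {"$ref": "#/$defs/curie"},
        "tissue": {"$ref": "#/$defs/curie"},
        "cell": {"$ref": "#/$defs/curie"},
        "compartment": {"$ref": "#/$defs/curie"},
        "experimental_setup": {
          "type": "array",
          "items": {"$ref": "#/$defs/curie"}
        }
      }
    },
    "entity": {
      "type": "object",
      "properties": {
        "identifier": {"$ref": "#/$defs/curie"},
        "biological_type": {"$ref": "#/$defs/curie"},
        "components": {"type": "array", "items": {"$ref": "#/$defs/curie"}},
        "context": {"$ref": "#/$defs/context"}
      }
    },
    "statement": {
      "type": "object",
      "required": ["source", "target", "relation", "evidence"],
      "properties": {
        "source": {"$ref": "#/$defs/entity"},
        "target": {"$ref": "#/$defs/entity"},
        "relation": {
          "type": "object",
          "properties": {
            "relation_term": {"$ref": "#/$defs/curie"},
            "mechanism": {"$ref": "#/$defs/curie"},
            "target_modification_effect": {"$ref": "#/$defs/modification"}
          }
        },
        "evidence": {
          "type": "object",
          "properties": {
            "references": {"type": "array", "items": {"$ref": "#/$defs/curie"}},
            "evidence_types": {"type": "array", "items": {"$ref": "#/$defs/curie"}},
            "interaction_context": {"$ref": "#/$defs/context"}
          }
        }
      }
    }
  }
}
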