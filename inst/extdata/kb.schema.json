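{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "epokb knowledge base exchange format",
  "type": "object",
  "required": ["format", "version", "languages", "roots", "properties",
               "concepts", "axioms"],
  "properties": {
    "format": {"const": "epokb-kb"},
    "version": {"const": 1},
    "languages": {"type": "array", "items": {"type": "string"}, "contains": {"const": "en"}},
    "roots": {
      "type": "object",
      "required": ["sign", "disorder", "anatomy", "technical"],
      "properties": {
        "sign": {"$ref": "#/$defs/conceptId"},
        "disorder": {"$ref": "#/$defs/conceptId"},
        "anatomy": {"$ref": "#/$defs/conceptId"},
        "technical": {
          "type": "array", "minItems": 3, "maxItems": 3,
          "items": {"$ref": "#/$defs/conceptId"},
          "description": "examination route, examination mode, echographic view - in this order"
        }
      }
    },
    "properties": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id"],
        "properties": {"id": {"type": "string"}, "parent": {"type": "string"}}
      }
    },
    "concepts": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "pref_labels", "alt_labels", "definitions",
                     "pmids", "image_paths"],
        "properties": {
          "id": {"$ref": "#/$defs/conceptId"},
          "pref_labels": {"type": "array", "items": {"$ref": "#/$defs/langText"}},
          "alt_labels": {"type": "array", "items": {"$ref": "#/$defs/langText"}},
          "definitions": {"type": "array", "items": {"$ref": "#/$defs/langText"}},
          "hidden_label": {"type": "string"},
          "fma_id": {"type": "string"},
          "pmids": {"type": "array", "items": {"type": "string"}},
          "image_paths": {"type": "array", "items": {"type": "string"}}
        }
      }
    },
    "axioms": {
      "type": "array",
      "items": {
        "oneOf": [
          {"type": "object", "required": ["kind", "child", "parent"],
           "properties": {"kind": {"const": "subclass_of"}}},
          {"type": "object", "required": ["kind", "child", "property", "filler"],
           "properties": {"kind": {"const": "subclass_of_restriction"}}},
          {"type": "object", "required": ["kind", "class", "genus", "restrictions"],
           "properties": {"kind": {"const": "equivalent_to_definition"},
                          "restrictions": {"type": "array", "minItems": 1}}},
          {"type": "object", "required": ["kind", "classes"],
           "properties": {"kind": {"const": "disjoint"},
                          "classes": {"type": "array", "minItems": 2}}}
        ]
      }
    }
  },
  "$defs": {
    "conceptId": {"type": "string", "minLength": 1},
    "langText": {
      "type": "object",
      "required": ["text", "lang"],
      "properties": {"text": {"type": "string", "minLength": 1},
                     "lang": {"type": "string"}}
    }
  }
}
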