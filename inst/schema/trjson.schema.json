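{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "trjson.schema.json",
  "title": "trjson transmission graph",
  "description": "A transmission network: samples as nodes, putative transmission links as edges, with typed attributes on both. Semantic rules not expressible here (unique node ids, edge endpoints referencing existing nodes, no self-loops, at most one edge per unordered pair when undirected or per ordered pair when directed, definition kinds agreeing with stored values) are enforced by validators.",
  "type": "object",
  "required": ["nodes", "edges"],
  "properties": {
    "directed": {
      "type": "boolean",
      "default": false,
      "description": "Directed graphs may carry one edge per ordered node pair, so up to two edges (one per direction) between two nodes; undirected graphs at most one per unordered pair."
    },
    "nodes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id"],
        "properties": {
          "id": {"type": "string", "minLength": 1}
        },
        "additionalProperties": {
          "$ref": "#/$defs/attributeValue"
        }
      }
    },
    "edges": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["source", "target"],
        "properties": {
          "source": {"type": "string", "minLength": 1},
          "target": {"type": "string", "minLength": 1}
        },
        "additionalProperties": {
          "$ref": "#/$defs/attributeValue"
        }
      }
    },
    "definitions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "scope", "kind"],
        "properties": {
          "name": {"type": "string"},
          "scope": {"enum": ["node", "edge"]},
          "kind": {"enum": ["string", "integer", "float"]},
          "description": {"type": "string"}
        },
        "additionalProperties": false
      }
    }
  },
  "additionalProperties": false,
  "$defs": {
    "attributeValue": {
      "type": ["string", "number"],
      "description": "Attribute values are strings, integers or floating-point numbers; booleans and null are not permitted."
    }
  }
}
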