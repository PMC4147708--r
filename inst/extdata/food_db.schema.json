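{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "foodswap combined food database",
  "type": "object",
  "required": ["records", "categories"],
  "properties": {
    "records": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["upc", "name", "category_id", "energy_kj", "protein_g",
                     "total_fat_g", "saturated_fat_g", "carbohydrate_g",
                     "sugars_g", "sodium_mg"],
        "properties": {
          "upc": {"type": "string", "pattern": "^[0-9]+$"},
          "name": {"type": "string"},
          "brand": {"type": ["string", "null"]},
          "category_id": {"type": "string"},
          "is_beverage": {"type": ["boolean", "null"]},
          "serving_size_g": {"type": ["number", "null"], "minimum": 0},
          "energy_kj": {"type": "number", "minimum": 0},
          "protein_g": {"type": "number", "minimum": 0},
          "total_fat_g": {"type": "number", "minimum": 0},
          "saturated_fat_g": {"type": "number", "minimum": 0},
          "carbohydrate_g": {"type": "number", "minimum": 0},
          "sugars_g": {"type": "number", "minimum": 0},
          "sodium_mg": {"type": "number", "minimum": 0},
          "fiber_g": {"type": ["number", "null"], "minimum": 0},
          "calcium_mg": {"type": ["number", "null"], "minimum": 0},
          "pct_fvnl_nonconc": {"type": ["number", "null"], "minimum": 0, "maximum": 100},
          "pct_fvnl_conc": {"type": ["number", "null"], "minimum": 0, "maximum": 100},
          "pct_non_fvnl": {"type": ["number", "null"], "minimum": 0, "maximum": 100},
          "provenance": {"enum": ["surveyed", "crowdsourced", null]}
        }
      }
    },
    "categories": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["category_id", "name", "is_beverage"],
        "properties": {
          "category_id": {"type": "string"},
          "name": {"type": "string"},
          "is_beverage": {"type": "boolean"},
          "fiber_possible": {"type": "boolean"},
          "fvnl_possible": {"type": "boolean"},
          "default_fvnl_pct": {"type": ["number", "null"], "minimum": 0, "maximum": 100},
          "npsc_category3_member": {"type": "boolean"},
          "is_cheese": {"type": "boolean"},
          "switch_excluded": {"type": "boolean"},
          "standard_message": {"type": ["string", "null"]}
        }
      }
    }
  }
}
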