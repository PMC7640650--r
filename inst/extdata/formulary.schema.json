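{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "akicds medication formulary",
  "description": "Maps drug names (matched after trimming and case-folding) to an AKI risk profile. Every entry must set at least one flag true; unlisted drugs resolve to class 'other' with both flags false.",
  "type": "object",
  "additionalProperties": {
    "type": "object",
    "required": ["risk_class", "may_cause_aki", "renally_cleared"],
    "properties": {
      "risk_class": {"enum": ["diuretic", "antibiotic", "acei_arb", "nsaid", "other"]},
      "may_cause_aki": {"type": "boolean"},
      "renally_cleared": {"type": "boolean"}
    }
  }
}
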