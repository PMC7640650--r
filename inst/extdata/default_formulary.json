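{
  "furosemide":          {"risk_class": "diuretic",   "may_cause_aki": true,  "renally_cleared": false},
  "hydrochlorothiazide": {"risk_class": "diuretic",   "may_cause_aki": true,  "renally_cleared": false},
  "metolazone":          {"risk_class": "diuretic",   "may_cause_aki": true,  "renally_cleared": false},
  "spironolactone":      {"risk_class": "diuretic",   "may_cause_aki": true,  "renally_cleared": false},
  "indapamide":          {"risk_class": "diuretic",   "may_cause_aki": true,  "renally_cleared": false},
  "gentamicin":          {"risk_class": "antibiotic", "may_cause_aki": true,  "renally_cleared": true},
  "tobramycin":          {"risk_class": "antibiotic", "may_cause_aki": true,  "renally_cleared": true},
  "amikacin":            {"risk_class": "antibiotic", "may_cause_aki": true,  "renally_cleared": true},
  "vancomycin":          {"risk_class": "antibiotic", "may_cause_aki": true,  "renally_cleared": true},
  "ramipril":            {"risk_class": "acei_arb",   "may_cause_aki": true,  "renally_cleared": false},
  "lisinopril":          {"risk_class": "acei_arb",   "may_cause_aki": true,  "renally_cleared": true},
  "perindopril":         {"risk_class": "acei_arb",   "may_cause_aki": true,  "renally_cleared": false},
  "enalapril":           {"risk_class": "acei_arb",   "may_cause_aki": true,  "renally_cleared": false},
  "losartan":            {"risk_class": "acei_arb",   "may_cause_aki": true,  "renally_cleared": false},
  "valsartan":           {"risk_class": "acei_arb",   "may_cause_aki": true,  "renally_cleared": false},
  "candesartan":         {"risk_class": "acei_arb",   "may_cause_aki": true,  "renally_cleared": false},
  "irbesartan":          {"risk_class": "acei_arb",   "may_cause_aki": true,  "renally_cleared": false},
  "ibuprofen":           {"risk_class": "nsaid",      "may_cause_aki": true,  "renally_cleared": false},
  "naproxen":            {"risk_class": "nsaid",      "may_cause_aki": true,  "renally_cleared": false},
  "ketorolac":           {"risk_class": "nsaid",      "may_cause_aki": true,  "renally_cleared": true},
  "diclofenac":          {"risk_class": "nsaid",      "may_cause_aki": true,  "renally_cleared": false},
  "indomethacin":        {"risk_class": "nsaid",      "may_cause_aki": true,  "renally_cleared": false},
  "celecoxib":           {"risk_class": "nsaid",      "may_cause_aki": true,  "renally_cleared": false},
  "digoxin":             {"risk_class": "other",      "may_cause_aki": false, "renally_cleared": true},
  "metformin":           {"risk_class": "other",      "may_cause_aki": false, "renally_cleared": true},
  "gabapentin":          {"risk_class": "other",      "may_cause_aki": false, "renally_cleared": true},
  "enoxaparin":          {"risk_class": "other",      "may_cause_aki": false, "renally_cleared": true},
  "morphine":            {"risk_class": "other",      "may_cause_aki": false, "renally_cleared": true}
}
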