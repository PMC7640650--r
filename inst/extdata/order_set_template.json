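{
  "investigations": {
    "base": [
      "Serum creatinine and electrolytes now and at least daily until AKI resolves",
      "Urinalysis with microscopy",
      "Urine albumin/creatinine or protein/creatinine ratio",
      "Complete blood count",
      "Review recent contrast exposures and medication history"
    ],
    "obstruction": [
      "Renal tract ultrasound (kidneys, ureters, bladder) - consider when obstruction is suspected or AKI is unexplained"
    ]
  },
  "fluid": {
    "hypovolemic": [
      "IV crystalloid bolus: prescriber to specify fluid type, volume and rate",
      "Reassess volume status after each bolus before prescribing further fluid"
    ],
    "euvolemic": [
      "Maintenance IV fluids: prescriber to specify fluid type and rate",
      "Match fluid prescription to measured losses; reassess at least daily"
    ],
    "hypervolemic": [
      "IV loop diuretic: prescriber to specify agent, dose and route",
      "Daily weight; strict intake/output recording"
    ]
  },
  "monitoring": {
    "bolus": [
      "Vital signs and oxygen saturation after each bolus",
      "Reassess for signs of volume overload (respiratory status, JVP, edema) after each bolus",
      "Strict intake/output recording; urine output review every shift"
    ],
    "overload_risk": [
      "Limit bolus volume and re-examine before any repeat bolus",
      "Escalate to prescriber if oxygen requirement increases or respiratory distress develops"
    ]
  },
  "medication_review": "Review and consider holding {drug} ({class}): may reduce kidney function during AKI",
  "consults": {
    "pharmacy": "Pharmacy consult: medication review and renal dose adjustment support",
    "nephrology_criteria": [
      "Consult nephrology if: stage 3 AKI, or creatinine still rising after 48 h of management",
      "Consult nephrology if: suspected glomerulonephritis, vasculitis, or myeloma kidney",
      "Consult nephrology/urology if: obstruction confirmed on imaging",
      "Consult nephrology urgently if: refractory hyperkalemia, acidosis, or volume overload (possible dialysis need)"
    ]
  }
}
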