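# ICD-9 code map: variable -> list of code patterns.
# Patterns are exact codes ("V600", "305.1") or prefixes ("304*").
# Periods are ignored ("305.1" == "3051").
#
# This shipped map is an editable, plausible DEFAULT for synthetic data and
# demonstrations; replace it with a validated code list before analyzing
# real data.
clinical:
  drug_use_disorder: ["304*", "3052*", "3053*", "3054*", "3055*", "3056*",
                      "3057*", "3058*", "3059*"]
  bipolar_disorder: ["2960*", "2961*", "2964*", "2965*", "2966*", "2967*",
                     "29680", "29681", "29689"]
  tobacco_use_disorder: ["3051*"]
  major_depressive_disorder: ["2962*", "2963*", "311"]
  alcohol_use_disorder: ["303*", "3050*"]
  cirrhosis: ["5712", "5715", "5716"]
  copd: ["490*", "491*", "492*", "494*", "496*"]
  renal_insufficiency: ["585*", "586"]
structured_sbdh:
  housing_insecurity: ["V600"]
  unemployment: ["V620"]
  social_isolation: ["V603", "V604"]
outcome:
  nonfatal_od: ["96500", "96501", "96502", "96509", "E8500", "E8501",
                "E8502"]
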