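# SBDH extraction lexicon.
# categories: per SBDH variable, trigger regexes (case-insensitive).
# negation / temporality: cue regexes scoped to `window` tokens around a
# trigger within the same sentence.
categories:
  housing_insecurity: ["homeless", "housing insecurity", "\\bshelter"]
  unemployment: ["unemploy"]
  social_isolation: ["lives alone", "lived alone", "socially isolated",
                     "social isolation"]
  alcohol_use: ["alcohol", "\\bwine\\b", "\\bbeers?\\b", "\\bdrinks\\b",
                "\\bdrink\\b", "\\bdrinker", "\\bvodka\\b", "\\bsober\\b"]
  smoking: ["smok", "cigarette", "\\btobacco"]
  illicit_drug_use: ["cocaine", "marijuana", "heroin", "recreational drug",
                     "illicit drug", "\\bnarcotics\\b"]
negation: ["\\bdenies\\b", "\\bdeny\\b", "\\bdenied\\b", "\\bno\\b",
           "\\bnot\\b", "\\bnon", "\\bnever\\b", "\\bwithout\\b",
           "does not", "doesn't"]
temporality: ["history of", "\\bh/o\\b", "\\bhx\\b", "\\bformer\\b",
              "\\bpast\\b", "\\bquit\\b", "used to", "\\bprior\\b",
              "sober since", "\\bremote\\b"]
window: 6
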