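{
  "drugs": [
    {
      "generic_name": "pregabalin",
      "brand_names": [
        "lyrica"
      ]
    },
    {
      "generic_name": "gabapentin",
      "brand_names": [
        "neurontin"
      ]
    },
    {
      "generic_name": "clonazepam",
      "brand_names": [
        "klonopin"
      ]
    },
    {
      "generic_name": "levetiracetam",
      "brand_names": [
        "kepra",
        "keppra"
      ]
    }
  ],
  "categories": [
    {
      "name": "drug_abuse_and_dependence",
      "scope": "primary",
      "pt_list": [
        "drug abuse",
        "drug dependence",
        "drug abuser",
        "substance abuse",
        "substance dependence",
        "drug use disorder",
        "substance use disorder",
        "dependence",
        "drug diversion"
      ]
    },
    {
      "name": "drug_withdrawal",
      "scope": "secondary",
      "pt_list": [
        "drug withdrawal syndrome",
        "withdrawal syndrome",
        "drug withdrawal syndrome neonatal",
        "substance withdrawal syndrome",
        "rebound effect"
      ]
    },
    {
      "name": "overdose",
      "scope": "secondary",
      "pt_list": [
        "overdose",
        "intentional overdose"
      ]
    },
    {
      "name": "tolerance",
      "scope": "secondary",
      "pt_list": [
        "drug tolerance",
        "drug tolerance increased"
      ]
    },
    {
      "name": "euphoria",
      "scope": "secondary",
      "pt_list": [
        "euphoric mood",
        "feeling abnormal",
        "feeling drunk",
        "feeling of relaxation",
        "dizziness",
        "thinking abnormal",
        "hallucination",
        "inappropriate affect"
      ]
    }
  ],
  "query_term_sets": [
    {
      "name": "drug_abuse_and_dependence",
      "search_terms": [
        "abuse",
        "dependence"
      ]
    },
    {
      "name": "drug_withdrawal",
      "search_terms": [
        "withdrawal"
      ]
    },
    {
      "name": "overdose",
      "search_terms": [
        "overdose"
      ]
    },
    {
      "name": "tolerance",
      "search_terms": [
        "tolerance"
      ]
    },
    {
      "name": "euphoria",
      "search_terms": [
        "high"
      ]
    }
  ]
}
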