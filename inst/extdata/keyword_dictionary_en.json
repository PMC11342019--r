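{
  "child": [
    {"term": "child", "variants": ["children"]},
    {"term": "boy", "variants": ["boys"]},
    {"term": "girl", "variants": ["girls"]},
    {"term": "infant", "variants": ["infants"]},
    {"term": "toddler", "variants": ["toddlers"]},
    {"term": "baby", "variants": ["babies"]},
    {"term": "minor", "variants": ["minors"]},
    {"term": "pupil", "variants": ["pupils"]},
    {"term": "kindergartner", "variants": ["kindergartners"]}
  ],
  "product": [
    {"term": "product", "variants": ["products"]},
    {"term": "magnetic beads"},
    {"term": "electric balance scooter", "variants": ["balance scooters"]},
    {"term": "button battery", "variants": ["button batteries"]},
    {"term": "crib", "variants": ["cribs"]},
    {"term": "stroller", "variants": ["strollers"]},
    {"term": "trampoline", "variants": ["trampolines"]},
    {"term": "electric kettle", "variants": ["electric kettles"]},
    {"term": "bunk bed", "variants": ["bunk beds"]},
    {"term": "laser pointer", "variants": ["laser pointers"]},
    {"term": "toy dart gun", "variants": ["toy dart guns"]},
    {"term": "toy", "variants": ["toys"]}
  ],
  "injury": [
    {"term": "injured"},
    {"term": "injury", "variants": ["injuries"]},
    {"term": "swallowed"},
    {"term": "burned"},
    {"term": "shocked"},
    {"term": "struck"},
    {"term": "trapped"},
    {"term": "strangled"},
    {"term": "fell"},
    {"term": "died"},
    {"term": "death", "variants": ["deaths"]},
    {"term": "fracture", "variants": ["fractures"]},
    {"term": "poisoning"},
    {"term": "asphyxia"},
    {"term": "laceration", "variants": ["lacerations"]},
    {"term": "hurt"}
  ],
  "environment": [
    {"term": "home"},
    {"term": "kindergarten"},
    {"term": "school"},
    {"term": "playground"},
    {"term": "park"},
    {"term": "mall"},
    {"term": "supermarket"},
    {"term": "balcony"},
    {"term": "slippery floor"}
  ],
  "activity": [
    {"term": "playing"},
    {"term": "climbing"},
    {"term": "riding"},
    {"term": "eating"},
    {"term": "bathing"},
    {"term": "running"}
  ],
  "other": [
    {"term": "recall", "variants": ["recalled"]},
    {"term": "regulator", "variants": ["regulators"]},
    {"term": "hospital"},
    {"term": "emergency"},
    {"term": "supervision"},
    {"term": "defect", "variants": ["defective"]},
    {"term": "warning"}
  ]
}
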