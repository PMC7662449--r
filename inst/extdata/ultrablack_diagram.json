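{
  "comment": "Two-generation Ultrablack path diagram: Angus (A) and Brahman (B) determine the Brangus composite (C) with squared path coefficients 0.625 and 0.375; a first-generation Ultrablack (D) receives half its variance from C and half directly from A. Edge coefficients are the square roots; the A-B correlation is taken as zero.",
  "nodes": ["A", "B", "C", "D"],
  "edges": [
    {"from": "A", "to": "C", "coef": 0.7905694150420949},
    {"from": "B", "to": "C", "coef": 0.6123724356957945},
    {"from": "A", "to": "D", "coef": 0.7071067811865476},
    {"from": "C", "to": "D", "coef": 0.7071067811865476}
  ],
  "arcs": []
}
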