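[
  {"herb": "Baishao",    "element": "wood",  "srgb": "#7A9B6D"},
  {"herb": "Rougui",     "element": "fire",  "srgb": "#C0716B"},
  {"herb": "Gancao",     "element": "earth", "srgb": "#C2A968"},
  {"herb": "Jiegeng",    "element": "metal", "srgb": "#BFBFB8"},
  {"herb": "Shudihuang", "element": "water", "srgb": "#5A5F66"}
]
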