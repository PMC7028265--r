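# Example code-list config for read_code_lists(). Codes may be dotted or
# undotted; they are normalized (upper-case, dots removed) on load and
# matched by prefix. Replaces the built-in defaults wholesale.
AUTOIMMUNE:
  icd9: ["571.6", "576.1", "571.42"]
  icd10: ["K74.3", "K83.0", "K75.4"]
HEMOCHROMATOSIS:
  icd9: ["275.0"]
  icd10: ["E83.10"]
ALCOHOL:
  icd9: ["305.0", "303", "291", "571.0", "571.1", "571.2", "571.3",
         "535.3", "357.5", "425.5", "980.0", "980.9", "790.3", "760.71"]
  icd10: ["F10", "X45", "Y15", "X65", "K70", "K292", "G312", "G621",
          "G721", "I426", "K852", "K860", "E244", "T510", "T519",
          "R780", "O354", "Q860", "P043"]
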