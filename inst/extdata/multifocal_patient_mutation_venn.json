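{
  "description": "Published shared-somatic-mutation Venn counts for a three-lesion hepatobiliary/pancreatic case (390-gene panel).",
  "per_lesion": {"pancreas": 63, "biliary_duct": 84, "omentum": 88},
  "pairwise": {"pancreas|biliary_duct": 38, "pancreas|omentum": 37, "biliary_duct|omentum": 46},
  "triple": 29
}
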