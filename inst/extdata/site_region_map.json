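{
  "version": "1.0-synthetic",
  "note": "21-site body-map vocabulary with the nine-region partition. The lower-limb constituents follow the published description (left/right hip, thigh, shin, calf, ankle, foot); the remaining site codes are a documented synthetic stand-in for the unpublished instrument map.",
  "sites": {
    "left_hip": "lower_limbs",
    "right_hip": "lower_limbs",
    "left_thigh": "lower_limbs",
    "right_thigh": "lower_limbs",
    "left_shin": "lower_limbs",
    "right_shin": "lower_limbs",
    "left_calf": "lower_limbs",
    "right_calf": "lower_limbs",
    "left_ankle": "lower_limbs",
    "right_ankle": "lower_limbs",
    "left_foot": "lower_limbs",
    "right_foot": "lower_limbs",
    "left_arm": "upper_limbs",
    "right_arm": "upper_limbs",
    "chest": "chest",
    "abdomen": "abdomen",
    "head": "head",
    "neck": "neck",
    "lower_back": "lower_back",
    "middle_back": "middle_back",
    "upper_back": "upper_back"
  }
}
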