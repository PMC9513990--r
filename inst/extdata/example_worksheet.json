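{
  "system": "subject_only",
  "subject": {
    "age": 54,
    "sex": "F",
    "pathology": "ischemic stroke, right hemiparesis",
    "upper_arm_cm": 30,
    "forearm_cm": 25,
    "dominant_arm": "right",
    "evaluated_arm": "right"
  },
  "skills": [
    { "name": "anterior_reaching_rest_height", "repetitions": 8 }
  ],
  "outcomes": ["kinematics", "emg"],
  "disturbance": { "kind": "none" },
  "seatback_deg": 105
}
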