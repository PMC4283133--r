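{
  "schema_version": "1.0",
  "patients": [
    {
      "patient_id": "bad",
      "events": [
        {"event_id": "e1", "text": "WBC 11.2", "semantic_type": "Lab",
         "raw_time": "02.8", "appearance_index": 1}
      ]
    }
  ]
}
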