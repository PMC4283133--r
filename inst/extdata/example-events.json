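{
  "schema_version": "1.0",
  "patients": [
    {
      "patient_id": "example",
      "events": [
        {"event_id": "op86", "text": "TG c Roux-en-Y anastomosis",
         "semantic_type": "Op", "raw_time": "86", "appearance_index": 1},
        {"event_id": "cc1", "text": "headache", "semantic_type": "Sx",
         "raw_time": "from late 02.7", "appearance_index": 2,
         "causal_links": ["mri"]},
        {"event_id": "cc2", "text": "dizziness", "semantic_type": "Sx",
         "raw_time": "", "appearance_index": 3},
        {"event_id": "mri", "text": "Br. MRI", "semantic_type": "Test",
         "raw_time": "02.8", "appearance_index": 4},
        {"event_id": "dx", "text": "r/o CRP diagnosis", "semantic_type": "Dx",
         "raw_time": "", "appearance_index": 5},
        {"event_id": "ntr", "text": "NTR of tm.", "semantic_type": "Op",
         "raw_time": "", "appearance_index": 6},
        {"event_id": "fam", "text": "FAM", "semantic_type": "Tx",
         "raw_time": "postop", "appearance_index": 7}
      ]
    }
  ]
}
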