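<?xml version="1.0" encoding="UTF-8"?>
<patient_set>
  <patient id="P0001"/>
  <patient id="P0002"/>
  <observation patient_id="P0001" concept_code="C50.911" concept_label="malignant neoplasm of unspecified site of right female breast" value=""/>
  <observation patient_id="P0001" concept_code="MED:01" concept_label="medication 01" value=""/>
  <observation patient_id="P0002" concept_code="MED:02" concept_label="medication 02" value=""/>
</patient_set>
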