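conversation_id: demo001
patient_id: pt001
dataset_label: user
metadata:
  race: white
turns:
- speaker_role: clinician
  text: How have you been since the last visit?
- speaker_role: patient
  text: The nausea has been rough, and I don’t have the appetite.
- speaker_role: clinician
  text: Take a few deep breaths for me.
- speaker_role: patient
  text: Okay.
- speaker_role: clinician
  text: Do you need any more Ativan?
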