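# Published turn-level confusion counts for a 1320-term PRO-CTCAE symptom
# keyword library, evaluated on transcribed outpatient oncology
# conversations: a validation sample (21225 turns, preliminary testing of
# the 1171-term draft) and a test sample (14674 turns, final library),
# each against a broad and a PRO-CTCAE-focused gold standard.
sample,standard,tp,fp,tn,fn
validation,broad,1018,558,18744,905
validation,proctcae,1381,175,19424,245
test,broad,921,315,12556,882
test,proctcae,1045,191,13157,281
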