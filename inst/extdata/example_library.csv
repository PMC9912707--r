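# version_label: example-0.1
# category_vocabulary: pain;gi;sleep_wake;neurological;cutaneous;mood_anxiety;respiratory;oral;sexual;other
type,term,categories,is_medication,is_clinician_authored,is_symptom_specific,source,rationale
keyword,nausea,gi,FALSE,FALSE,FALSE,a-priori,
keyword,ativan,mood_anxiety,TRUE,FALSE,FALSE,development-corpus,
keyword,fuzzy brain,neurological,FALSE,FALSE,FALSE,validation-adjustment,
exclusion,deep breaths,,FALSE,FALSE,FALSE,,physical-exam instruction
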