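quantity	value
transcripts_total	53023
transcripts_on_groups	44371
transcripts_on_reference	30342
markers_mapped_text	468
marker_bearing_scaffolds	409
scaffolds_on_reference	14990
gonad_de_total	7199
gonad_de_up_female	2522
gonad_de_up_male	4677
gonad_de_assigned_to_groups	4266
muscle_de_up_slow	40
muscle_de_up_fast	52
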