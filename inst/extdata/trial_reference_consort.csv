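stage,count
downloaded,167
excluded,72
randomized,95
randomized_intervention,42
randomized_control,53
completers,30
female,52
male,43
gender_intervention_male,19
gender_intervention_female,23
gender_control_male,24
gender_control_female,29
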