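surface,canonical_form,routes,modified_release
tablet,tablet,oral,FALSE
film-coated tablet,tablet,oral,FALSE
coated tablet,tablet,oral,FALSE
chewable tablet,tablet,oral,FALSE
orodispersible tablet,tablet,oral,FALSE
dispersible tablet,tablet,oral,FALSE
effervescent tablet,tablet,oral,FALSE
prolonged-release tablet,tablet,oral,TRUE
modified-release tablet,tablet,oral,TRUE
gastro-resistant tablet,tablet,oral,TRUE
capsule hard,capsule,oral,FALSE
"capsule, hard",capsule,oral,FALSE
hard capsule,capsule,oral,FALSE
"capsule, soft",capsule,oral,FALSE
soft capsule,capsule,oral,FALSE
gastro-resistant capsule,capsule,oral,TRUE
"prolonged-release capsule, hard",capsule,oral,TRUE
oral solution,oral_solution,oral,FALSE
oral suspension,oral_suspension,oral,FALSE
powder for oral suspension,oral_suspension,oral,FALSE
granules,granules,oral,FALSE
prolonged-release granules,granules,oral,TRUE
oral powder,oral_powder,oral,FALSE
solution for injection,solution_for_injection,intravenous|subcutaneous,FALSE
solution for infusion,solution_for_infusion,intravenous,FALSE
concentrate for solution for infusion,solution_for_infusion,intravenous,FALSE
powder for solution for infusion,solution_for_infusion,intravenous,FALSE
suspension for injection,suspension_for_injection,intramuscular|subcutaneous,FALSE
cream,cream,topical,FALSE
ointment,ointment,topical,FALSE
transdermal patch,transdermal_patch,transdermal,TRUE
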