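# Ward-admission personalisation rules for the CABG model.

RULE elderly_care FOR admission_checks WHEN age >= 75 THEN add_item "Age {age}: complete a fall-risk assessment" AND set_priority elderly_care_item high

RULE diabetic_care FOR admission_checks WHEN diabetes == true THEN add_item "Diabetic patient: order peri-operative glucose monitoring"
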