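# Pre-operative alert rules for the PCI model.
# A rule fires only when its condition is definitely true; missing patient
# data evaluates to unknown and never fires.

RULE lvef_alert FOR cardiac_function WHEN lvef < 50 THEN add_item "LVEF is {lvef}, below the alert threshold of 50: assess ventricular function before the procedure" AND highlight lvef_alert_item red AND set_priority lvef_alert_item high

RULE renal_flag FOR renal_function WHEN renal_insufficiency == true THEN add_item "Renal insufficiency noticed" AND invoke_rule contrast_precaution

RULE contrast_precaution FOR renal_function WHEN renal_insufficiency == true THEN pre_check hydration_item AND attach_material hydration_item patient_data creatinine
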