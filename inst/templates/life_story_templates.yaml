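# Narrative templates for agent life stories, one per event kind.
# Placeholders: {age} {year} {week} {value} {threshold} {detail}.
# Edit freely; phrasing only, no model logic lives here.
birth: "She was born in {year}; her mother's glycemic control in pregnancy averaged {value}."
birth_male: "In {year}, at age {age}, she gave birth to a boy."
conception: "At age {age} ({year}) she became pregnant."
booking: "At age {age} ({year}) she attended her antenatal booking visit in week {week}."
early_screen: "At age {age} ({year}) she had an early screening test in week {week}: glycemic index {value} against a threshold of {threshold}."
ogtt: "At age {age} ({year}) she took the routine oral glucose tolerance test in week {week}: glycemic index {value} against a threshold of {threshold}."
diagnosis: "At age {age} ({year}) she was diagnosed with gestational diabetes at the {week}-week test (glycemic index {value}, threshold in force {threshold})."
lifestyle_rx: "She began lifestyle management of her pregnancy glycemia in week {week}."
pharmaco_rx: "Her treatment was escalated to pharmacotherapy in week {week}."
delivery_care: "At age {age} ({year}) she delivered at term; her mean glycemic index over the pregnancy was {value}."
adverse_outcome: "The delivery in {year} was complicated by an adverse perinatal outcome."
postpartum_test: "At age {age} ({year}) she attended a postpartum glucose tolerance test."
intervention_enrol: "At age {age} ({year}) she enrolled in the '{detail}' program."
death: "She died at age {age} ({year})."
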