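# Thromboembolic outcome registry: plain outcomes name their member event
# concepts; composites list other outcomes; negative controls are flagged.
deep_vein_thrombosis:
  concepts: [deep_vein_thrombosis]
pulmonary_embolism:
  concepts: [pulmonary_embolism]
venous_thromboembolism:
  composite_of: [deep_vein_thrombosis, pulmonary_embolism]
cerebral_venous_sinus_thrombosis:
  concepts: [cerebral_venous_sinus_thrombosis]
splanchnic_visceral_thrombosis:
  concepts: [splanchnic_visceral_thrombosis]
ischaemic_stroke:
  concepts: [ischaemic_stroke]
myocardial_infarction:
  concepts: [myocardial_infarction]
intestinal_infarction:
  concepts: [intestinal_infarction]
arterial_thromboembolism:
  composite_of: [ischaemic_stroke, myocardial_infarction, intestinal_infarction]
thrombocytopenia:
  concepts: [thrombocytopenia]
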