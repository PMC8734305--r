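# Heart-failure preferred terms used to widen the AOE screen.
# The proprietary Cardiac Failure SMQ is not redistributable; this editable
# stand-in list holds the HF preferred terms appearing in the source safety
# database plus obvious companions. Replace with a licensed SMQ export if one
# is available.
Cardiac failure
Cardiac failure congestive
Cardiac failure acute
Cardiac failure chronic
Left ventricular failure
Right ventricular failure
Cardiogenic shock
Ventricular failure
Pulmonary oedema
Acute pulmonary oedema
Cardiomyopathy
Ejection fraction decreased
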