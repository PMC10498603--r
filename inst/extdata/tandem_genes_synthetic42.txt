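Cadm2
Cdh4
Cdh13
Ctnna3
Dclk1
Gria3
Grm7
Grm8
Itpr2
Lama3
Macrod2
Plcb1
Prmd16
Ptprn2
Rbfox1
Wwox
Zbtb20
Dpp6
Lama2
SynthTandem01
SynthTandem02
SynthTandem03
SynthTandem04
SynthTandem05
SynthTandem06
SynthTandem07
SynthTandem08
SynthTandem09
SynthTandem10
SynthTandem11
SynthTandem12
SynthTandem13
SynthTandem14
SynthTandem15
SynthTandem16
SynthTandem17
SynthTandem18
SynthTandem19
SynthTandem20
SynthTandem21
SynthTandem22
SynthTandem23
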