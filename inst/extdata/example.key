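# Example keyword configuration (whitespace-separated keyword/value lines)
project     example
refAtoms    39 8 15 3
ff          mm3
grad        0.01
Reff        1.4
C           6.0
viscosity   2.19e-3
temperature 298.15
seed        123456789
nucleus     13C1H
bondLength  1.13
deltaCSA    0
frequency   600.132 699.973
calculate   T1 T2 NOE
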