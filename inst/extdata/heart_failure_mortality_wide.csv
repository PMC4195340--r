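study,Medical therapy events,Medical therapy n,Cardiac resynchronization events,Cardiac resynchronization n,Implantable defibrillator events,Implantable defibrillator n,Combined resynchronization and defibrillator events,Combined resynchronization and defibrillator n,Amiodarone events,Amiodarone n
CARE_HF-ext,154,404,101,409,,,,,,
COMPANION,77,308,131,617,,,105,595,,
MIRACLE,16,225,12,228,,,,,,
MUSTIC-SR,0,29,1,29,,,,,,
SCD-HeFT,244,847,,,182,829,,,240,845
MADIT-II,97,490,,,105,742,,,,
DEFINITE,40,229,,,28,229,,,,
CAT,17,54,,,13,50,,,,
MICRACLE-ICD-I,,,,,5,182,4,187,,
MICRACLE-ICD-II,,,,,2,101,2,85,,
CONTAK-CD,,,,,16,245,11,245,,
AMIOVIRT,,,,,6,51,,,7,52
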