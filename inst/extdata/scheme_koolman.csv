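group,residues
aliphatic,AGILV
aromatic,FHWY
sulfur,CM
hydroxyl,ST
basic,HKR
acidic_amide,DENQ
imino,P
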