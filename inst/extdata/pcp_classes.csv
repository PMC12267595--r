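class,residues
charged,DEKRH
positively_charged,KRH
negatively_charged,DE
polar,CDEHKNQRSTY
nonpolar,AGFILMPVW
aliphatic,AGILV
aromatic,FHWY
cyclic,P
acidic,DE
basic,KRH
neutral,ACFGHILMNPQSTVWY
hydrophobic,ACFILMVW
hydrophilic,DEKNQR
tiny,ACGS
small,ACDGNPSTV
large,FHIKLMRWY
sulfur_containing,CM
hydroxylic,ST
amide,NQ
helix_preferring,AEHKLMQR
strand_preferring,CFITVWY
coil_preferring,DGNPS
buried,ACFGILVW
exposed,DEKNQR
intermediate_accessibility,HMPSTY
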