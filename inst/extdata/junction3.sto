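# STOCKHOLM 1.0
#=GF R2R multistem_junction j dirs 180,90,0 formulation 2
#=GF R2R modular opt m n predicate present("m", "n")
seq01           GGCCGGUGGCCCGGAAUCCCUGGGCACCCCC-----------
seq02           GGCCGGUGGCCCGAAAUUCCUAGGCACUCCC-----------
seq03           GGCCGGUGGCCCGGAAUCCCUGGGCACCCCCAGGGAAACCCA
seq04           AGCCAGUGGCUCGGAAUCCCUGAGCAUCCCUAGGGAAACCCA
seq05           GGCCGGUGGCCCGAAAUUCCUGGGCACCCCC-----------
seq06           AGCCGGUGGCCCAGAAUCUCUGGGCACCCCU-----------
seq07           GACCGAUGGUCCAGAAUCUCUAGGCACUCUC-----------
seq08           GACCAAUGGUUCGGAAUCCCUGAGCAUCCUC-----------
seq09           AGCCGAUGGUCCGAAAUUCCUGGGCACCCCUAGGGAAACCCA
seq10           GACCAGUGGCUCAGAAUCUCUAAGCAUUCUC-----------
#=GC SS_cons    <<..<<...>>.<<...>>..<<...>>.>>...........
#=GC R2R_LABEL  ..j............................m.........n
//
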