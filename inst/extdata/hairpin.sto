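# STOCKHOLM 1.0
seq01           --UAGGAGGUAAUCCCUCC-ACC
seq02           CCUAGGAAAU-AUCUUUCCUACC
seq03           CCUAGAAAAUAAUCUUUUCUACC
seq04           CCU-GGGAGUAAUCCUCCCUACC
seq05           CCUAAAGGAUAAUCUCCUUUACC
seq06           CCUAAGAGGUA-UCCCUCUUACC
seq07           CCUAAAGGAUAAUCUCCUUU-CC
seq08           CCUAAAGAGUAAUCCUCUUU-CC
#=GC SS_cons    ....<<<<<.....>>>>>....
//
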