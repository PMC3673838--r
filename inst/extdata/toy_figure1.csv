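id,label,phase,year,seq,outcome,status,children,same_report_children
a1,α1,in_vitro,2000,0,positive,completed,,
a2,α2,in_vitro,2000,0,positive,completed,,
b1,β1,in_vivo,2001,0,negative,completed,,
b2,β2,in_vivo,2002,0,positive,completed,,
b3,β3,in_vivo,2002,0,positive,completed,,
g1,γ1,phase1,2003,0,positive,completed,,
g2,γ2,phase1,2003,0,inconclusive,completed,,
g3,γ3,phase1,2004,0,positive,completed,,
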