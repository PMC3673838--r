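id,label,phase,year,seq,outcome,status,children,same_report_children
a1,α1,in_vitro,2000,0,positive,completed,a2;b1,
a2,α2,in_vitro,2000,0,positive,completed,b2;b3,
b1,β1,in_vivo,2001,0,negative,completed,,
b2,β2,in_vivo,2002,0,positive,completed,g1,
b3,β3,in_vivo,2002,0,positive,completed,g2;g3;d2,
g1,γ1,phase1,2003,0,positive,completed,d1,
g2,γ2,phase1,2003,0,inconclusive,completed,,
g3,γ3,phase1,2004,0,positive,completed,d2,
d1,δ1,phase2,2004,0,negative,completed,g3,
d2,δ2,phase2,2005,0,positive,completed,,
d3,δ3,phase2,2005,0,inconclusive,completed,,
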