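population,measure,prev_w_pct,prev_m_pct,rr_printed
Blumenau,coadministration,79.08,74.06,1.07
Blumenau,interaction,14.64,9.49,1.54
Blumenau,minor,0.36,0.44,0.81
Blumenau,moderate,11.3,7.1,1.59
Blumenau,major,6.25,4.07,1.53
Catalonia,coadministration,77.39,73.88,1.05
Catalonia,interaction,11.08,8.84,1.25
Catalonia,minor,0.26,0.2,1.27
Catalonia,moderate,8.31,5.93,1.4
Catalonia,major,3.17,2.95,1.08
Indianapolis,coadministration,77.88,71.82,1.06
Indianapolis,interaction,12.69,11.36,1.12
Indianapolis,minor,1.13,1.1,1.02
Indianapolis,moderate,10.67,9.49,1.12
Indianapolis,major,4.87,4.76,1.02
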