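# Kinetic and spectroscopic constants of the four 2-naphthol photoacids,
# free in pH 7 buffer and bound to insulin amyloid fibrils.
# Units: k_PT [1/ns], k_a [A/ns], R_D [A], D [cm2/s], a [A],
# collection/band centres [nm], ratios dimensionless.
# rate_fast_reconv is the multi-exponential fast-component rate [1/ns]
# for the acids whose direct value is IRF-limited (NA otherwise).
name,condition,Z1,pKa,pKa_star,k_PT_per_ns,k_a_angstrom_per_ns,dimensionality_d,R_D_angstrom,D_cm2_per_s,a_angstrom,rate_fast_reconv,ratio,collection_nm,roh_center_nm,ro_center_nm
2N,buffer,1,9.2,2.8,0.2,0.2,3,7,9e-5,4,NA,0.74,350,350,420
2N,fibril,1,9.2,2.8,0.4,1.5,1.2,10,5e-5,4,NA,0.70,350,350,420
2N6S,buffer,2,9.2,1.7,1.0,0.8,3,14,9e-5,4,NA,16.6,355,355,420
2N6S,fibril,2,9.2,1.7,0.9,0.7,1.9,19,2.5e-5,4,NA,6.5,355,355,420
2N8S,buffer,2,9.2,1.0,1.6,1.5,3,14,9e-5,4,3.9,18.2,355,355,420
2N8S,fibril,2,9.2,1.0,0.9,1.4,2.1,16,2.6e-5,4,NA,4.9,355,355,420
"2N6,8S",buffer,3,9.2,0.4,1.8,1.3,3,21,9e-5,4,10.6,48.5,370,370,420
"2N6,8S",fibril,3,9.2,0.4,0.6,1.2,2.9,22,2e-5,4,NA,6.4,370,370,420
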