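# Published purification tables for heterologous FsCDH production:
# series A = full-length CDH, series B = isolated DH domain.
# Inputs: volumes (mL), Bradford protein concentrations (mg/mL), measured
# total protein (mg), total activities (U) per assay (DCIP / cytochrome c;
# "b.d.l." = below detection limit), A420/A280 ratio (RZ) as measured.
# printed_* columns are the table's printed derived values at printed
# precision. conc_a280 is the alternative A280-based concentration
# reported for the final step (epsilon280 100185 / 77600 M-1cm-1).
series,step,volume,conc,total_protein,total_activity_dcip,total_activity_cytc,rz,conc_a280,printed_specific_dcip,printed_specific_cytc,printed_yield,printed_factor
CDH,Supernatant,4500,0.3,1310,946,47,,,0.72,0.04,100,1
CDH,HIC,750,0.8,598,542,14,0.33,,0.91,0.02,57,1.3
CDH,AEX,15,4.5,68,111,8,0.53,9.9,1.64,0.11,12,2.3
DH,Supernatant,4500,0.3,1310,946,47,,,0.72,0.04,100,1
DH,HIC,1800,0.6,1120,860,b.d.l.,0.12,,0.77,b.d.l.,91,1.1
DH,AEX,30,6.1,183,399,b.d.l.,0.02,11.8,2.18,b.d.l.,42,3.0
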