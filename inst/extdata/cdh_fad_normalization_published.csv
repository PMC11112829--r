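# Published specific activities (lactose, DCIP assay), FAD occupancies and
# the recalculated activities at 100% FAD loading, with printed
# uncertainties, for four characterized CDHs.
enzyme,ph,specific_activity,activity_sd,occupancy_pct,printed_full_fad,printed_full_fad_sd
FsCDH,6.0,0.7,0.2,9,7.4,2.2
MtCDH,6.0,1.6,0.3,19,8.4,1.6
CtCDH,5.5,9.4,0.2,44,21.4,0.5
PcCDH,4.5,23.4,1.0,70,33.4,1.4
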