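# GT-C luminal motif library. type: pattern = scanned as a degenerate string;
# conserved_class = single conserved position called via class frequency;
# families: "all" or comma-separated registry names the entry applies to.
name	pattern	expected_side	type	families
el1_acidic	[DE]x?[DE]	luminal	pattern	all
el2_stt3_dpy19	Rx{6}[DL][NR]E	luminal	pattern	STT3,DPY19,ALG10
el2_rxd	Rx{4}D	luminal	pattern	POMT,TMTC,ALG12,PIGB,PIGZ,PIGV,ALG3,PIGM,ALG6,ALG8
el3_basic	[KRNQ]	luminal	conserved_class	all
el56_rp	Rx{4,14}P	luminal	pattern	all
dilysine_kkxx	KKxx$	cytoplasmic	pattern	ALG3,PIGM,ALG6,ALG8
dilysine_kxkxx	KxKxx$	cytoplasmic	pattern	ALG3,PIGM,ALG6,ALG8
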