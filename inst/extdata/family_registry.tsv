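# GT-C family registry: expected helix counts and organization classes.
family	n_tmds	organization	dilysine	motifs_absent
STT3	13	1-8-4	FALSE
DPY19	13	1-8-4	FALSE
ALG10	13	1-8-4	FALSE
POMT	11	1-6-4	FALSE
TMTC	11	1-6-4	FALSE
ALG9	11	1-6-4	FALSE	el2,el3
ALG12	11	1-6-4	FALSE
PIGB	11	1-6-4	FALSE
PIGZ	11	1-6-4	FALSE
PIGV	11	1-6-4	FALSE
ALG3	12	1-6-5	TRUE
PIGM	12	1-6-5	TRUE
ALG6	14	1-6-7	TRUE
ALG8	14	1-6-7	TRUE
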