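donor_id	diagnosis	sex
S1	SCZ	unknown
S2	SCZ	unknown
S3	SCZ	unknown
S4	SCZ	unknown
S5	SCZ	unknown
S6	SCZ	unknown
S7	SCZ	unknown
S8	SCZ	unknown
S9	SCZ	unknown
C1	Control	unknown
C2	Control	unknown
C3	Control	unknown
C4	Control	unknown
C5	Control	unknown
C6	Control	unknown
C7	Control	unknown
C8	Control	unknown
C9	Control	unknown
C10	Control	unknown
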