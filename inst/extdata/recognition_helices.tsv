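GCT	TSGELVR
CTA	QNSTLTE
CCC	SKKHLAE
CTT	TTGALTE
ACG	RTDTLRD
AGG	RSDHLTN
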