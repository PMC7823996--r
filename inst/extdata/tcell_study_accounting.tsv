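method	polarity	n_features	pct_above_blank	pct_above_blank_with_trend
FIA	-	1887	44.4	31.0
FIA	+	2416	52.7	28.4
LC-QTOF HILIC	-	1671	31.2	26.3
LC-QTOF Polar RP	+	1549	32.8	25.8
LC-QTOF Lipids	-	1745	57.9	53.4
LC-QTOF Lipids	+	1819	57.6	56.6
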