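# Codes on which a four-reviewer panel reached unanimity when verdicts are
# compared at lengths 3 (category), 4, and 7 characters (dot excluded).
# The three lists are separate unanimity sets: a phrase can be unanimous at
# a short length without being unanimous at full length, so the longer-length
# truncations form a subset of (not the whole of) each shorter-length list.
# Columns: length<TAB>code
length	code
3	C71
3	C77
3	C79
3	C85
3	D17
3	D18
3	D32
3	D49
3	E04
3	G06
3	G08
3	G31
3	G37
3	G91
3	G93
3	G95
3	H70
3	I60
3	I61
3	I62
3	I63
3	I65
3	I66
3	I67
3	I72
3	I77
3	J03
3	J32
3	J34
3	J36
3	J39
3	K11
3	K38
3	M25
3	M46
3	M47
3	M48
3	M50
3	M51
3	M53
3	M70
3	M99
3	N20
3	Q04
3	Q28
3	Q76
3	R22
3	R59
3	R60
3	R93
3	S00
3	S01
3	S02
3	S06
3	S12
3	S22
3	S32
3	S72
3	Z96
3	Z98
4	C77.0
4	C79.3
4	C85.8
4	D17.0
4	D17.7
4	D18.0
4	D32.9
4	D49.6
4	E04.1
4	G06.1
4	G08
4	G31.9
4	G37.9
4	G93.1
4	G93.4
4	G93.5
4	G93.6
4	G93.8
4	G95.1
4	H70.9
4	I60.9
4	I61.5
4	I61.9
4	I62.0
4	I62.9
4	I63.5
4	I63.8
4	I63.9
4	I65.0
4	I65.2
4	I66.1
4	I67.1
4	I67.8
4	I72.6
4	I77.1
4	I77.7
4	J03.9
4	J32.0
4	J34.2
4	J36
4	J39.0
4	K11.5
4	K38.9
4	M25.4
4	M46.2
4	M47.8
4	M48.0
4	M50.2
4	M51.2
4	M53.2
4	M70.6
4	M70.7
4	M99.8
4	N20.0
4	Q04.6
4	Q28.3
4	Q76.4
4	R22.0
4	R60.0
4	R93.0
4	R93.7
4	R93.8
4	S00.0
4	S01.8
4	S02.1
4	S02.8
4	S02.9
4	S06.2
4	S12.9
4	S22.0
4	S32.0
4	Z96.8
4	Z98.2
4	Z98.8
7	C77.0
7	C79.31
7	C85.89
7	D17.0
7	D17.79
7	D18.09
7	D32.9
7	D49.6
7	E04.1
7	G06.1
7	G08
7	G31.9
7	G37.9
7	G93.1
7	G93.41
7	G93.5
7	G93.6
7	G93.89
7	G95.19
7	I60.9
7	I61.5
7	I61.9
7	I62.00
7	I62.9
7	I63.512
7	I63.8
7	I63.9
7	I65.02
7	I65.21
7	I65.22
7	I65.29
7	I67.1
7	I67.83
7	I72.6
7	I77.1
7	J03.90
7	J32.0
7	J34.2
7	J36
7	J39.0
7	K11.5
7	K38.9
7	M25.459
7	M46.20
7	M47.812
7	M48.02
7	M48.04
7	M48.06
7	M50.20
7	M51.26
7	M53.2X1
7	M99.81
7	M99.82
7	M99.83
7	N20.0
7	Q04.6
7	Q28.3
7	Q76.49
7	R22.0
7	R60.0
7	R93.0
7	R93.7
7	R93.8
7	S00.03XA
7	S01.81XA
7	S02.119A
7	S02.92XA
7	S06.2X9A
7	S12.9XXA
7	S22.009A
7	S22.080A
7	Z96.89
7	Z98.2
7	Z98.890
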