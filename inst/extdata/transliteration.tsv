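α	a
β	b
γ	g
δ	d
ε	e
ζ	z
η	h
θ	t
ι	i
κ	k
λ	l
μ	m
ν	n
ξ	x
ο	o
π	p
ρ	r
σ	s
ς	s
τ	t
υ	u
φ	f
χ	c
ψ	p
ω	w
Α	A
Β	B
Γ	G
Δ	D
Ε	E
Ζ	Z
Η	H
Θ	T
Ι	I
Κ	K
Λ	L
Μ	M
Ν	N
Ξ	X
Ο	O
Π	P
Ρ	R
Σ	S
Τ	T
Υ	U
Φ	F
Χ	C
Ψ	P
Ω	W
µ	u
‐	-
‑	-
‒	-
–	-
—	-
―	-
−	-
­	-
‘	'
’	'
‚	'
‛	'
′	'
´	'
`	'
“	"
”	"
„	"
″	"
«	"
»	"
×	x
∗	*
⋅	.
·	.
•	.
…	?
±	+
∓	-
≤	<
≥	>
≠	=
≈	~
∼	~
°	o
℃	C
№	N
™	?
®	?
©	?
⁄	/
∕	/
⁎	*
½	?
¼	?
¾	?
¹	1
²	2
³	3
⁰	0
⁴	4
⁵	5
⁶	6
⁷	7
⁸	8
⁹	9
₀	0
₁	1
₂	2
₃	3
₄	4
₅	5
₆	6
₇	7
₈	8
₉	9
é	e
è	e
ê	e
ë	e
á	a
à	a
â	a
ä	a
å	a
ã	a
í	i
ì	i
î	i
ï	i
ó	o
ò	o
ô	o
ö	o
õ	o
ø	o
ú	u
ù	u
û	u
ü	u
ñ	n
ç	c
ý	y
É	E
Ö	O
Ü	U
Å	A
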