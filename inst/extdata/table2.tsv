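sample	market_name	species	col1a1	col1a2	col3a1
HP1	rabbit glue SOB1	Oryctolagus cuniculus	yes	yes	yes
HP2	rabbit glue SOB2	Bos taurus	yes	yes	yes
HP3	rabbit glue SOB3	Bos taurus	yes	yes	yes
HP4	rabbit glue SOB4	Bos taurus	yes	yes	yes
HM1	rabbit glue SOB5	Bos taurus	yes	yes	yes
HM1	rabbit glue SOB5	Sus scrofa	yes	yes	yes
HP8	rabbit glue 10	Bos taurus	yes	yes	yes
HM2	rabbit glue 2	Oryctolagus cuniculus	yes	yes	no
HM2	rabbit glue 2	Ovis aries	no	yes	yes
HM2	rabbit glue 2	Capra hircus	yes	no	no
HM3	rabbit glue 3	Bos taurus	yes	yes	yes
HM3	rabbit glue 3	Oryctolagus cuniculus	yes	yes	yes
HM3	rabbit glue 3	Ovis aries	no	yes	no
HM5	rabbit glue 7	Oryctolagus cuniculus	yes	no	no
HM5	rabbit glue 7	Sus scrofa	yes	yes	yes
HM4	rabbit glue 6	Bos taurus	yes	yes	yes
HM4	rabbit glue 6	Oryctolagus cuniculus	yes	yes	no
HP5	fish glue SOB6	Sus scrofa	yes	yes	yes
HP6	fish glue 4	Bos taurus	yes	yes	yes
HP7	fish glue 5	Bos taurus	yes	yes	yes
FM	sturgeon fish glue SOB7	Scyliorhinus canicula	yes	yes	no
BM1	strong glue SOB8	Sus scrofa	yes	yes	no
BM1	strong glue SOB8	Bos taurus	yes	yes	no
BM1	strong glue SOB8	Sus scrofa	yes	yes	no
BM2	strong glue SOB9	Bos taurus	yes	yes	no
BM2	strong glue SOB9	Sus scrofa	yes	yes	no
BM2	strong glue SOB9	Equus asinus	yes	yes	no
BM4	strong glue 8	Bos taurus	yes	yes	no
BM4	strong glue 8	Sus scrofa	yes	yes	no
BM4	strong glue 8	Equus asinus	no	yes	no
BM5	strong glue 9	Bos taurus	yes	yes	no
BM5	strong glue 9	Sus scrofa	yes	no	no
BM5	strong glue 9	Ovis aries	yes	yes	no
BM5	strong glue 9	Equus asinus	yes	yes	no
BM3	strong glue 1	Bos taurus	yes	yes	no
BM3	strong glue 1	Sus scrofa	no	yes	no
BM3	strong glue 1	Equus asinus	yes	yes	no
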