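name	pattern
DOFCOREZM	AAAG
CACTFTPPCA1	YACT
CAATBOX1	CAAT
GT1CONSENSUS	GRWAAW
GTGANTG10	GTGA
ARR1AT	NGATT
GATABOX	GATA
POLLEN1LELAT52	AGAAA
WRKY71OS	TGAC
ROOTMOTIFTAPOX1	ATATT
NODCON2GM	CTCTT
EBOXBNNAPA	CANNTG
MYCCONSENSUSAT	CANNTG
TAAAGSTKST1	TAAAG
GT1GMSCAM4	GAAAAA
POLASIG1	AATAAA
CCAATBOX1	CCAAT
SEF4MOTIFGM7S	RTTTTTR
RAV1AAT	CAACA
IBOXCORE	GATAA
POLASIG3	AATAAT
WBOXATNPR1	TTGAC
WBOXHVISO1	TGACT
BIHD1OS	TGTCA
MYBCORE	CNGTTR
CURECORECR	GTAC
EECCRCAH1	GANTTNC
ACGTATERD1	ACGT
MYB1AT	WAACCA
AGCBOXNPGLB	AGCCGCC
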