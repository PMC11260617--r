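canonical_drug	raw_name
exenatide	EXENATIDE
exenatide	BYETTA
exenatide	BYDUREON
liraglutide	LIRAGLUTIDE
liraglutide	VICTOZA
liraglutide	SAXENDA
albiglutide	ALBIGLUTIDE
albiglutide	TANZEUM
albiglutide	EPERZAN
dulaglutide	DULAGLUTIDE
dulaglutide	TRULICITY
semaglutide	SEMAGLUTIDE
semaglutide	OZEMPIC
semaglutide	WEGOVY
semaglutide	RYBELSUS
tirzepatide	TIRZEPATIDE
tirzepatide	MOUNJARO
tirzepatide	ZEPBOUND
lixisenatide	LIXISENATIDE
lixisenatide	ADLYXIN
lixisenatide	LYXUMIA
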