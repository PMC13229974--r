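genotype,year,role,n_planted,n_evaluated,n_fertile,seed_available
N525,2022,entry,100,100,90,TRUE
N516,2022,entry,100,100,82,TRUE
N542,2022,entry,100,100,75,TRUE
A427,2022,entry,100,100,69,TRUE
FR19,2022,entry,100,100,60,TRUE
NK778,2022,entry,100,100,59,TRUE
Mo307ae,2022,entry,100,100,52,TRUE
A632HTN,2022,entry,100,100,41,TRUE
AusTRCF 306308,2022,entry,100,100,34,FALSE
N545,2022,entry,100,100,29,TRUE
A632.75 A1 A2 C1 R,2022,entry,100,100,25,FALSE
A427,2023,positive_control,100,100,95,FALSE
58614 B73 (Meth),2023,entry,100,100,84,TRUE
B106,2023,entry,100,100,84,TRUE
FAPW,2023,entry,100,100,79,FALSE
LH128,2023,entry,100,100,68,TRUE
N801w,2023,entry,100,100,61,TRUE
B103,2023,entry,100,100,51,FALSE
LH127,2023,entry,100,100,46,FALSE
A681,2023,entry,100,100,45,FALSE
LH193,2023,entry,100,100,43,FALSE
LH143 (Maintainer),2023,entry,100,100,41,FALSE
LH145,2023,entry,100,100,40,FALSE
W570,2023,entry,100,100,40,FALSE
GEMS-0001,2023,entry,100,100,38,FALSE
H109,2023,entry,100,100,36,FALSE
A682,2023,entry,100,100,35,FALSE
DJ7,2023,entry,100,100,33,FALSE
Os426,2023,entry,100,100,30,FALSE
B42,2023,entry,100,100,27,FALSE
A427,2024,positive_control,100,100,85,FALSE
PHR58,2024,entry,100,100,84,TRUE
K41,2024,entry,100,100,76,TRUE
N522,2024,entry,100,100,66,TRUE
RS 710,2024,entry,100,100,64,TRUE
N524,2024,entry,100,100,59,TRUE
HUA 94,2024,entry,100,100,56,TRUE
Lai 1029,2024,entry,100,100,56,TRUE
PHG86,2024,entry,100,100,54,TRUE
(Twan x Tzuh)-S6,2024,entry,100,100,50,TRUE
2369,2024,entry,100,100,49,TRUE
PHP60,2024,entry,100,100,48,TRUE
Va91,2024,entry,100,100,44,TRUE
PHT10,2024,entry,100,100,42,TRUE
1538,2024,entry,100,100,40,TRUE
PHJ40,2024,entry,100,100,35,TRUE
PHK05,2024,entry,100,100,35,TRUE
PHR47,2024,entry,100,100,32,TRUE
W23,2024,entry,100,100,29,TRUE
S8324,2024,entry,100,100,26,TRUE
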