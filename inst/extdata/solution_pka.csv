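aa,solution_pka,peptide
ASP,3.67,AAXAA
GLU,4.25,AAXAA
HIS,6.54,AAXAA
CYS,8.55,AAXAA
TYR,9.84,AAXAA
LYS,10.40,AAXAA
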