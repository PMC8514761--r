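population	CD45	EpCAM	pdpn	CD49f	CD200	CD31	HLA-DR	CD11c	CD11b	CD3	CD1a	CD4	CD8
cTEC	50	300	25000	20000	50	50	2000	50	50	50	50	50	50
mTEC	50	20000	12000	300	20000	50	2000	50	50	50	50	50	50
FB	50	50	1500	300	50	50	50	50	50	50	50	50	50
EC	50	50	50	20000	50	20000	50	50	50	50	50	50	50
LEC	50	50	12000	20000	20000	20000	50	50	50	50	50	50	50
DC	20000	50	50	50	50	50	20000	20000	20000	50	50	50	50
MP	20000	50	50	50	50	50	20000	50	20000	50	50	50	50
thymocyte_immature	20000	50	50	50	50	50	50	50	50	1500	20000	20000	20000
thymocyte_CD4SP	20000	50	50	50	50	50	50	50	50	20000	300	20000	50
thymocyte_CD8SP	20000	50	50	50	50	50	50	50	50	20000	300	50	20000
B	20000	50	50	50	50	50	20000	50	50	50	50	50	50
other	50	50	50	50	50	50	50	50	50	50	50	50	50
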