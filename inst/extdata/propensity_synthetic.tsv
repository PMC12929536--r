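# window: 7
aa	dG_native	dH_ap_native	dH_pol_native	TdS_conf_native	dG_denatured	dH_ap_denatured	dH_pol_denatured	TdS_conf_denatured
A	1.792173948467405	-3.8299667402491058	5.324012566237478	1.472710900918052	0.5177163162596037	-0.7218545999774809	1.4989834549454097	2.0767801244987387
C	0.15940725471390693	-2.6671387226286027	4.160339407513706	1.6750041173247363	-0.5236704174801372	-1.1961824487860164	0.8872370062687008	2.7667194834651485
D	-0.697851674881206	-3.0605730772890247	5.3429700507261515	2.0706286420459956	-0.0204970225582857	-0.9560791497473266	-0.1514692145846248	2.11351566080647
E	1.0068255579880416	-2.756166609597436	1.6620328906859037	0.7765633870832951	-0.2175384355622616	-1.033180941542986	2.5715325348339917	1.577755753205269
F	0.32670824556738065	-1.3341119031452955	6.045354369887043	2.6726439105027353	-1.723474212345713	0.03684369347061367	-2.365669685825228	2.5971384722637096
G	2.0676934608149184	-5.39957215594349	2.6754200703276423	1.4777869769520637	0.8858410647253991	0.049695300464582925	0.7800147857224458	2.6984694220810552
H	-0.04829224318667702	-2.2383656362745983	3.2551746649955224	1.324996035519426	1.0129916808922728	-1.4316511361242634	-1.6261501369928566	2.531007075332182
I	1.4560721075298266	1.2246912360630064	3.0492901532185708	0.5352119446551816	1.046534012686163	-1.9795962102410591	3.4497139779231425	1.7565109047769143
K	0.2403068789206746	-6.16904952552296	3.8706531345404613	1.2730991447091038	0.7993549497035075	-1.6786479584874625	1.1375577009350095	2.6960572385409005
L	2.7667385850705637	-2.1581426887874535	3.8278660387832795	1.0984796127052845	0.30387619527342713	0.027608963882151283	-0.27410865363902537	2.4606339756870006
M	2.5403823610738905	-4.576732562323209	1.3949023374236322	1.217435323848804	0.4106493064412575	-0.032989067881832534	1.680264761823679	2.539659637140356
N	0.663069497625163	-4.445949248653619	3.663203365908924	0.9868770019181905	-0.6472908147106631	-0.777504671970892	1.757279419918583	1.081587737269071
P	1.005517488632711	-0.9633122353729973	4.322869551449751	2.1143984177163104	0.08174659888004178	-2.2143536853715737	1.53947781092659	1.6921650086869424
Q	0.39758815077071064	-4.014367340331868	2.657481028307562	1.9643477872684127	0.09957027530547326	-1.879122059038099	0.11456192047011837	3.06813414421466
R	2.4831214354033166	-2.926353034228778	4.10147613758102	0.9797099535533755	1.354710054609665	-0.6947972829394603	3.5668612185831763	1.5846633538184305
S	1.5532136566098178	-4.083560265770866	5.4036229152735045	-0.18465333770733472	0.2851205326775671	-1.1578248107029454	-0.39637743673415327	1.6112040377727024
T	0.8498089318070842	-3.545285260612624	4.094065158230871	-0.30617426699529227	-0.5345429810362003	-0.9389603358790894	-0.13106844077540636	1.2357981249638146
V	1.8047150885263514	-7.47095013294757	6.8018925321578925	2.6674710813969353	0.41802985189388164	-1.2434527071784913	0.3885718279609329	1.670524239374544
W	-0.2803168260174027	-2.16677954888873	0.7425922262579729	1.9848810908722598	1.0126232711006762	-2.402125221885826	1.768311093804328	1.6782245005936707
Y	0.41694706135148607	-0.5543714867411378	3.7377047158924976	0.8017879945909352	-0.26817539650242783	-1.818536170859719	0.2633893637955246	1.8937892893996182
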