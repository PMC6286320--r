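species	origination	extinction	status	parent	mode
sp1	37.0746250512326	25.6285151443839	extinct	NA	root
sp2	31.4044141896013	30.1707512406576	extinct	sp1	budding
sp3	30.7642128553806	22.9100474322067	extinct	sp1	budding
sp4	29.0862686166173	25.2350307806376	extinct	sp3	budding
sp5	26.6186074955181	0	extant	sp4	budding
sp6	25.2820554191331	0	extant	sp5	budding
sp7	23.5399713115356	16.9583331173755	extinct	sp6	budding
sp8	15.7935183867991	0	extant	sp6	budding
sp9	14.274880322153	3.18966833435218	extinct	sp8	budding
sp10	11.1773205484342	7.94923131090337	extinct	sp9	budding
sp11	10.4505002934141	5.06982732344901	extinct	sp9	budding
sp12	4.59648957403744	2.28615016694273	extinct	sp9	budding
sp13	26.3591200516817	22.2732972415332	extinct	sp1	budding
sp14	24.6087101242766	19.9123504375696	extinct	sp3	budding
sp15	25.6704995861776	9.65577163589883	extinct	sp4	budding
sp16	16.5401656282259	10.8565665744058	extinct	sp15	budding
sp17	13.4421231884766	13.0831009367789	extinct	sp15	budding
sp18	10.0493304508223	0	extant	sp15	budding
sp19	9.34513761565835	0	extant	sp18	budding
sp20	1.81374014900442	0	extant	sp19	budding
sp21	0.0608511178712305	0	extant	sp20	budding
sp22	13.5212179493607	0	extant	sp5	budding
sp23	9.82915573716344	2.15669539297305	extinct	sp5	budding
sp24	6.22753553425255	0	extant	sp5	budding
sp25	23.3559473125918	9.05879774577357	extinct	sp7	budding
sp26	22.2989780567479	16.7452492592394	extinct	sp7	budding
sp27	20.9280160807569	12.8231952385871	extinct	sp7	budding
sp28	17.4578620855028	17.2614914970024	extinct	sp7	budding
sp29	23.3550429675218	20.2835651381096	extinct	sp25	budding
sp30	22.2201992486834	18.9942688396131	extinct	sp29	budding
sp31	20.0809209863706	9.21752135753498	extinct	sp30	budding
sp32	21.5677435363215	21.2558640308851	extinct	sp25	budding
sp33	17.5919936772699	0	extant	sp25	budding
sp34	12.9587289861608	0.0310140592516035	extinct	sp25	budding
sp35	10.8438830780518	7.6493106354635	extinct	sp25	budding
sp36	15.221378803834	14.986934312953	extinct	sp27	budding
sp37	14.2274552928194	12.1857378711343	extinct	sp27	budding
sp38	18.6496409089255	0	extant	sp31	budding
sp39	17.8729917560517	16.2449906573274	extinct	sp31	budding
sp40	13.3334684774359	7.35286715784527	extinct	sp38	budding
sp41	15.514677598173	13.7130726803076	extinct	sp31	budding
sp42	13.2683121347865	9.68959874725206	extinct	sp33	budding
sp43	6.25806377602103	0	extant	sp33	budding
sp44	4.64297423142321	0	extant	sp33	budding
sp45	3.41348407846669	0	extant	sp33	budding
sp46	2.66538622141957	0	extant	sp33	budding
sp47	12.7312962335118	0	extant	sp16	budding
sp48	11.4458209720906	4.85445655359088	extinct	sp16	budding
sp49	10.6591323634332	6.00061343066238	extinct	sp48	budding
sp50	9.33020633443916	4.9689702700265	extinct	sp6	budding
sp51	8.4252142918865	0	extant	sp8	budding
sp52	8.0852238027158	7.31995554062608	extinct	sp8	budding
sp53	12.2451469924708	7.43053626042574	extinct	sp22	budding
sp54	6.47003340112004	0	extant	sp38	budding
sp55	2.84985799942213	0	extant	sp54	budding
sp56	1.3537655508453	0	extant	sp55	budding
sp57	0.392972634281556	0	extant	sp56	budding
sp58	10.0024740673516	8.48089079421735	extinct	sp42	budding
sp59	11.9636386685122	0	extant	sp34	budding
sp60	10.8185767376414	0	extant	sp34	budding
sp61	8.16806360887681	0.185032065102718	extinct	sp34	budding
sp62	12.2091077196727	2.04600884194338	extinct	sp47	budding
sp63	11.348047436309	5.88660364483275	extinct	sp47	budding
sp64	9.11226674889823	7.94300405913183	extinct	sp63	budding
sp65	7.29981910331888	0	extant	sp63	budding
sp66	6.95840094866332	3.23135865294122	extinct	sp22	budding
sp67	4.07764688652659	1.80961786189002	extinct	sp59	budding
sp68	6.48475018158027	0	extant	sp47	budding
sp69	3.26720681015124	0	extant	sp68	budding
sp70	10.2653138234407	0	extant	sp10	budding
sp71	7.73433488020003	4.02386156745388	extinct	sp70	budding
sp72	8.17587044302922	6.14199550179767	extinct	sp35	budding
sp73	7.49232856908332	6.84657760021412	extinct	sp60	budding
sp74	8.83659956900944	0	extant	sp11	budding
sp75	2.09870749366507	0	extant	sp74	budding
sp76	9.66373941574374	7.75318904533117	extinct	sp10	budding
sp77	8.62441142171463	0	extant	sp23	budding
sp78	7.97241207414055	2.85318417716246	extinct	sp76	budding
sp79	7.60905918477234	0	extant	sp78	budding
sp80	6.56575418850634	0	extant	sp78	budding
sp81	8.08141274467937	3.25741794382922	extinct	sp18	budding
sp82	5.79012134784418	4.91425280718253	extinct	sp18	budding
sp83	7.86589936475326	0	extant	sp6	budding
sp84	8.85147539988851	0	extant	sp64	budding
sp85	8.77352329562649	2.11552429881896	extinct	sp84	budding
sp86	7.47819942990998	0	extant	sp11	budding
sp87	5.22766010618637	2.94420535338406	extinct	sp86	budding
sp88	8.59039379050293	0	extant	sp85	budding
sp89	7.20612978018361	5.23884669505238	extinct	sp85	budding
sp90	4.88278542707902	0	extant	sp85	budding
sp91	3.9891419573605	0	extant	sp23	budding
sp92	0.349424930254003	0	extant	sp91	budding
sp93	2.88618292910547	2.36236521344139	extinct	sp88	budding
sp94	7.74943492762396	5.88865310913998	extinct	sp51	budding
sp95	5.15503214303458	0	extant	sp34	budding
sp96	5.03986374903202	4.12184263229252	extinct	sp95	budding
sp97	3.6095199490536	0	extant	sp95	budding
sp98	3.24883527358278	0	extant	sp97	budding
sp99	3.97594241548304	0.869219194236159	extinct	sp8	budding
sp100	5.09852764306832	0	extant	sp83	budding
sp101	7.45752107288282	7.12262749357053	extinct	sp51	budding
sp102	7.269673860237	6.00899964931756	extinct	sp101	budding
sp103	1.82922310675477	1.64415056181832	extinct	sp70	budding
sp104	6.12520031851797	0	extant	sp79	budding
sp105	3.76570520390727	0	extant	sp79	budding
sp106	7.37750373817913	0	extant	sp60	budding
sp107	4.49733823487546	2.28096427847431	extinct	sp106	budding
sp108	4.98734708585931	0	extant	sp51	budding
sp109	3.57307279389359	1.59071121048813	extinct	sp51	budding
sp110	4.80379187400769	0	extant	sp60	budding
sp111	4.46533269313324	0	extant	sp65	budding
sp112	1.665855858748	0	extant	sp111	budding
sp113	6.80416867992718	4.40952206721484	extinct	sp89	budding
sp114	6.26320763447378	0	extant	sp113	budding
sp115	2.22428765127014	1.67896877331734	extinct	sp114	budding
sp116	6.56902446459209	0.819220692837973	extinct	sp22	budding
sp117	3.63022256746989	0	extant	sp22	budding
sp118	3.22150963583844	0	extant	sp116	budding
sp119	2.39599899330681	0	extant	sp116	budding
sp120	5.05136269792052	0	extant	sp47	budding
sp121	4.49648211098259	0	extant	sp38	budding
sp122	2.90758175171528	0	extant	sp104	budding
sp123	5.6546910870864	2.5704111105133	extinct	sp18	budding
sp124	3.19592909969415	0	extant	sp123	budding
sp125	4.58977170755166	3.77620208443962	extinct	sp83	budding
sp126	2.77933083331927	0	extant	sp83	budding
sp127	2.4214408689513	0	extant	sp47	budding
sp128	4.82940873222432	0	extant	sp108	budding
sp129	2.1889744818368	0	extant	sp108	budding
sp130	1.88560103825075	0.836975286425634	extinct	sp60	budding
sp131	2.4126787552561	0	extant	sp44	budding
sp132	1.55878897407058	0	extant	sp131	budding
sp133	0.768017283336874	0	extant	sp131	budding
sp134	4.2743771391734	0	extant	sp125	budding
sp135	3.48894188841101	0	extant	sp134	budding
sp136	0.279970874948447	0	extant	sp95	budding
sp137	3.39426259648129	0	extant	sp45	budding
sp138	0.156241758407226	0	extant	sp45	budding
sp139	0.921307580165582	0.0602706132330582	extinct	sp68	budding
sp140	2.07925941542759	0	extant	sp104	budding
sp141	0.520429393015846	0	extant	sp104	budding
sp142	1.46898184617673	0	extant	sp83	budding
sp143	1.28494017426762	0	extant	sp83	budding
sp144	0.909440456829522	0	extant	sp44	budding
sp145	2.07669649207683	0	extant	sp119	budding
sp146	0.156817732471218	0	extant	sp129	budding
sp147	0.191382740707553	0	extant	sp145	budding
sp148	1.79333353125568	0.983593166844933	extinct	sp60	budding
sp149	1.49058164070777	1.37539193161766	extinct	sp19	budding
sp150	0.113837507792375	0	extant	sp111	budding
sp151	0.146879653256747	0	extant	sp56	budding
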