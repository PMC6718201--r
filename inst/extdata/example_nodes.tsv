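qx	qy	qz
-0.1492512215	0.05462995224	-0.01157676135
0.1301420983	0.05837721974	-0.01085354597
-0.1329797113	-0.0826914323	-0.0113406909
-0.06786497655	0.1787176348	-0.01867089273
-0.08275646205	-0.01955741775	-0.00479228014
0.03130788605	-0.107989703	-0.007463669721
0.1297321121	-0.05814388981	-0.01005028339
0.159360713	-0.1779914769	-0.02850290689
-0.09913922725	0.002286027827	-0.003807040392
0.04852446161	-0.06584561799	-0.003306964056
0.01652773048	-0.02162523139	-0.001107210246
-0.01840701317	0.1776005894	-0.01733695281
-0.1162719928	-0.04029163378	-0.007644707096
-0.01601394955	0.02172778553	0.001048655888
-0.1694014827	-0.1799501119	-0.03088303512
0.03087402654	0.1764918281	-0.01548669973
0.2099186263	0.001158039887	-0.02274099746
-0.09985414085	-0.06214192738	-0.008803263138
-0.04954323519	0.001389614311	-0.001705454506
0.1432324113	0.1922665959	-0.03031027317
0.2413505153	0.009527832814	-0.03091397542
-0.1663058282	0.0129841636	-0.01545127978
0.04650047309	0.2067172002	-0.02257356036
0.03212065997	-0.04378221248	-0.002119852344
-0.233842455	0.0233251903	-0.02729063941
0.07613657032	-0.003742385824	0.1712246306
-0.07233565741	-0.04121844348	0.05868498719
-0.1766110589	0.04209448915	-0.09783520636
-0.06025697976	-0.07675626674	-0.03414749914
0.05984150539	0.09598700546	-0.09687278274
0.004103710921	-0.03599152018	-0.2015537718
-0.01861168104	0.1605415095	0.1109093003
-0.01329884553	-0.08687592595	0.1032238353
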