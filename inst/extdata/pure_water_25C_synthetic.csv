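"frequency_hz","eps_real","eps_imag"
1e+08,79.472826128262,0.0938227626241904
111603161.520137,77.9548045921938,0.571239138314001
124552656.612899,78.6815984295511,0.93158897649161
139004702.537316,78.8923048261378,1.62797531128974
155133642.693308,78.7121452112056,0.0219918830144303
173134049.827085,78.3108347483115,1.68202211823578
193223073.274878,79.5775414340872,1.00082882005432
215643058.561135,78.3165355657386,1.6372318445361
240664470.952949,79.9707913612109,1.64036536122849
268589158.239204,78.3364781274346,1.59022765812652
299753992.095277,79.4050099539721,0.326299164228931
334534931.961152,80.1701854732866,1.20597369184583
373351560.457888,77.283599156408,1.9134426653677
416672145.05577,78.1469339171077,0.842471918745857
465019287.056012,78.2524823806838,1.34867360384062
518976226.032914,78.8448232574887,2.43503121963024
579193875.790627,78.1105233456711,2.81098508418126
646398676.713359,76.2354287612731,2.82815752292809
721401359.236441,76.3845619560472,2.0560341469774
805106724.157115,79.305246061464,2.20654301252755
898524557.770552,77.9994835298412,4.60719174412427
1002781813.50677,76.8057086714634,4.01952665084678
1119136207.02253,78.0169506589839,4.32692095603726
1248991388.75369,79.0410518588042,4.65318843260527
1393913876.96339,79.4971608163247,4.35927243487554
1555651955.55906,77.5849792928555,6.37797528739968
1736156764.65377,77.6039240286816,6.40418886851424
1937605838.29933,76.2847988041613,7.17932136045553
2162429373.34083,77.8392277210441,8.87837611495449
2413339546.28846,76.7607520680453,9.70830803702964
2693363231.87367,77.3373927661657,11.1636108657876
3005878517.99196,77.1903496701719,10.8306356012206
3354655457.53369,77.0255818430398,12.928072884138
3743901548.71543,75.2434184969882,14.8377035575489
4178312492.56782,75.4687998530216,14.3763538403238
4663128839.89654,73.0045867879471,16.151299414982
5204199211.08185,72.7844532045684,17.6471761644157
5808050851.37341,71.6101021669845,19.2134191317943
6481968372.82999,69.099758962423,22.2662080452658
7234081632.8137,69.306314381196,24.6540809427773
8073463809.16766,67.5266455915672,27.0471004084929
9010240855.21526,64.9046203678633,28.916609681396
10055713654.9993,63.1382340365047,29.4101916960651
11222494352.3914,59.2319618753292,33.1623238980123
12524658498.6877,55.6108937635379,33.0758050895459
13977914854.1361,53.2747241094196,34.9110874637536
15599794891.8088,48.753355336129,35.5770858975399
17409864289.9155,46.1638301317659,36.3587974073448
19429958963.9112,41.0790130113601,36.7006870174552
21684448485.7903,37.6632193975755,36.3870555586199
24200530068.3475,33.5891403334226,35.618261565288
27008556660.9073,29.3743904953056,34.602353414102
30142403114.5303,26.9557414388021,32.9453431147223
33639874833.9602,23.4026349589304,31.2955794923255
37543163846.1168,20.3770761202446,29.054548657974
41899357786.9515,17.9675244933672,27.5726811005191
46761007946.8719,15.9419040931404,25.5416640272244
52186763227.3918,13.931813445442,24.4393846446994
58242077656.7977,11.6100081630966,21.4024421144694
6.5e+10,11.1251816889951,19.8966925213099
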