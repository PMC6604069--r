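"label","tau_s","beta","tau_err","beta_err","composition","tau_normalized"
"c01",1.2e-11,0.0665371306904955,0,0,NA,1.44578313253012
"c02",2.00172064464007e-11,0.16110414692933,0,0,NA,2.41171162004827
"c03",3.33907128264855e-11,0.251074274545315,0,0,NA,4.02297744897416
"c04",5.56990660033533e-11,0.313921568850334,0,0,NA,6.71073084377751
"c05",9.29116419217354e-11,0.358202062402506,0,0,NA,11.1941737255103
"c06",1.54985959801786e-10,0.390215514926953,0,0,NA,18.6730072050345
"c07",2.58532162803827e-10,0.436671427694904,0,0,NA,31.1484533498586
"c08",4.31257639656555e-10,0.445781331903251,0,0,NA,51.95875176585
"c09",7.19381100382731e-10,0.488168021996862,0,0,NA,86.6724217328592
"c10",1.2e-09,0.485544466827568,0,0,NA,144.578313253012
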