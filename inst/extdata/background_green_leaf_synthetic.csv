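wl,reflectance
300,0.02
310,0.02
320,0.02
330,0.02
340,0.02
350,0.02
360,0.0201
370,0.0202
380,0.0203
390,0.0206
400,0.0211
410,0.022
420,0.0234
430,0.0256
440,0.0289
450,0.0335
460,0.0398
470,0.0478
480,0.0575
490,0.0687
500,0.0807
510,0.0926
520,0.1035
530,0.1123
540,0.118
550,0.12
560,0.118
570,0.1123
580,0.1035
590,0.0926
600,0.0807
610,0.0687
620,0.0575
630,0.0478
640,0.0398
650,0.0335
660,0.0289
670,0.0256
680,0.0234
690,0.022
700,0.0211
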