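latent_trait,parameter,loading,psd,r2
Body Size,Body length,0.699,0.041,0.488
Body Size,Body weight,0.901,0.020,0.812
Body Size,Flank girth,0.828,0.029,0.686
Body Size,Heart girth,0.799,0.032,0.639
Body Size,Hip height,0.704,0.044,0.495
Body Size,Hip width,0.727,0.039,0.529
Body Size,Mid girth,0.911,0.018,0.830
Body Composition,Antral follicle count,0.524,0.087,0.275
Body Composition,Left ovary diameter,0.561,0.083,0.314
Body Composition,Ribeye area,0.560,0.083,0.313
Body Composition,Right ovary diameter,0.513,0.088,0.263
Body Composition,Rump fat,0.189,0.102,0.036
Body Composition,Uterine horn diameter,0.586,0.081,0.343
Body Composition,Yield grade,0.212,0.102,0.045
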