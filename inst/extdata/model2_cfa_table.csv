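latent_trait,parameter,loading,psd,r2
Ovary Size,Antral follicle count,0.990,0.016,0.981
Ovary Size,Left ovary diameter,0.803,0.051,0.125
Ovary Size,Right ovary diameter,0.879,0.052,0.122
Body Size,Body length,0.720,0.030,0.519
Body Size,Body weight,0.803,0.023,0.644
Body Size,Heart girth,0.879,0.016,0.772
Body Size,Hip height,0.621,0.038,0.385
Body Size,Hip width,0.744,0.028,0.553
Body Size,Mid girth,0.928,0.012,0.860
Yield Grade,Rib fat,0.999,0.001,0.998
Yield Grade,Rump fat,0.444,0.064,0.197
Yield Grade,Yield grade,0.999,0.001,0.998
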