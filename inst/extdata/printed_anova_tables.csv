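condition,source,quantity,printed_value,half_ulp,printed_text
data,Dataset,SS,77.688,0.0005,
data,Dataset,MS,77.688,0.0005,
data,Dataset,F,6.659,0.0005,
data,Dataset,p,0.0164,0.00005,
data,Dataset,F_critical,4.259,0.0005,
data,Dataset,significance,,,**
data,Models,SS,191.983,0.0005,
data,Models,MS,63.994,0.0005,
data,Models,F,5.485,0.0005,
data,Models,p,0.0051,0.00005,
data,Models,F_critical,3.009,0.0005,
data,Models,significance,,,***
data,Interaction,SS,24.687,0.0005,
data,Interaction,MS,8.229,0.0005,
data,Interaction,F,0.705,0.0005,
data,Interaction,p,0.5582,0.00005,
data,Interaction,F_critical,3.009,0.0005,
data,Interaction,significance,,,NS
data,Within,SS,279.985,0.0005,
data,Within,MS,11.666,0.0005,
data,Total,SS,574.343,0.0005,
ad1,Dataset,SS,12.276,0.0005,
ad1,Dataset,MS,12.276,0.0005,
ad1,Dataset,F,0.604,0.0005,
ad1,Dataset,p,0.4446,0.00005,
ad1,Dataset,F_critical,4.259,0.0005,
ad1,Dataset,significance,,,NS
ad1,Models,SS,366.819,0.0005,
ad1,Models,MS,122.273,0.0005,
ad1,Models,F,6.015,0.0005,
ad1,Models,p,0.0033,0.00005,
ad1,Models,F_critical,3.009,0.0005,
ad1,Models,significance,,,***
ad1,Interaction,SS,7.659,0.0005,
ad1,Interaction,MS,2.553,0.0005,
ad1,Interaction,F,0.125,0.0005,
ad1,Interaction,p,0.944,0.0005,
ad1,Interaction,F_critical,3.009,0.0005,
ad1,Interaction,significance,,,NS
ad1,Within,SS,487.848,0.0005,
ad1,Within,MS,20.327,0.0005,
ad1,Total,SS,874.602,0.0005,
ad2,Dataset,SS,4.43e-6,0.005e-6,
ad2,Dataset,MS,4.43e-6,0.005e-6,
ad2,Dataset,F,0.816,0.0005,
ad2,Dataset,p,0.3752,0.00005,
ad2,Dataset,F_critical,4.259,0.0005,
ad2,Dataset,significance,,,NS
ad2,Models,SS,6.23e-5,0.005e-5,
ad2,Models,MS,2.08e-5,0.005e-5,
ad2,Models,F,3.829,0.0005,
ad2,Models,p,0.0225,0.00005,
ad2,Models,F_critical,3.009,0.0005,
ad2,Models,significance,,,*
ad2,Interaction,SS,1.13e-5,0.005e-5,
ad2,Interaction,MS,3.77e-6,0.005e-6,
ad2,Interaction,F,0.696,0.0005,
ad2,Interaction,p,0.5634,0.00005,
ad2,Interaction,F_critical,3.009,0.0005,
ad2,Interaction,significance,,,NS
ad2,Within,SS,0.0001,0.00005,
ad2,Within,MS,5.42e-6,0.005e-6,
ad2,Total,SS,0.0002,0.00005,
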