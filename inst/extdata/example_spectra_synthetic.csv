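sample_id,label,6000,6428.57142857143,6857.14285714286,7285.71428571429,7714.28571428571,8142.85714285714,8571.42857142857,9000
g01,gansu,0.3109,0.4488,0.7546,0.6842,0.4921,0.6077,0.6853,0.5569
h01,henan,0.2955,0.4403,0.7612,0.6825,0.4719,0.5581,0.6327,0.5197
s01,shanxi,0.2853,0.4118,0.6920,0.6321,0.4706,0.6124,0.6983,0.5520
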