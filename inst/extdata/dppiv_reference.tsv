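sequence	ic50_um	source
IPI	3.5	diprotin A, microbial/milk
VPL	10.0	diprotin B, microbial
VPV	6.6	camel whey
YPI	35.0	camel whey
VPF	55.1	camel whey
IPAVF	44.7	bovine beta-lactoglobulin
FLEP	65.3	milk tetrapeptide series
LLAP	NA	fish/milk proteins
LPVPQ	43.8	bovine milk digest
IPM	69.5	bovine milk digest
LPVP	87.0	camel milk hydrolysate
MPVQA	93.3	camel milk hydrolysate
IPYWTY	11.04	rice/soy screening
IPYWT	18.29	rice/soy screening
WVL	NA	milk proteins
LL	106.0	dipeptide series
WV	NA	dipeptide series
IPQNIPPL	46.0	cheese-derived
LPQNIPPL	NA	milk casein
VPITPT	130.0	milk casein
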