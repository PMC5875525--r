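modality,metric,max_sd
CBCT,hu_air,3.1
CBCT,hu_polyethylene,4.5
CBCT,hu_water,7.9
CBCT,hu_acrylic,6.1
CBCT,hu_bone,29.1
CBCT,uniformity,11.0
CBCT,distance,0.5
CT,hu_air,1.1
CT,hu_polyethylene,1.1
CT,hu_water,1.1
CT,hu_acrylic,1.1
CT,hu_bone,1.1
CT,uniformity,0.7
CT,lowcontrast_cnr,0.21
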