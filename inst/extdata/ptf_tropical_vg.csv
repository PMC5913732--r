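# van Genuchten pedotransfer coefficients for tropical soils
# (Hodnett & Tomasella, 2002, Geoderma 108:155-180; as used operationally in
# the GSIF R package, AWCPTF). Linear model on: intercept, sand (g/100 g),
# silt (g/100 g), clay (g/100 g), organic carbon (g/100 g), bulk density of
# the fine earth (kg/dm3), CEC (cmolc/kg), pH-H2O, silt^2, clay^2, sand*silt,
# sand*clay. All coefficients are on a x100 scale: the linear predictor is
# divided by 100, then ln_alpha and ln_n are exponentiated. alpha is in 1/kPa;
# theta_s and theta_r are volumetric fractions (cm3/cm3).
term,ln_alpha,ln_n,theta_s,theta_r
intercept,-2.294,62.986,81.799,22.733
sand,0,0,0,-0.164
silt,-3.526,0,0,0
clay,0,-0.833,0.099,0
oc,2.440,-0.529,0,0
bd,0,0,-31.42,0
cec,-0.076,0,0.018,0.235
ph,-11.331,0.593,0.451,-0.831
silt2,0.019,0,0,0
clay2,0,0.007,0,0.0018
sand_silt,0,-0.014,0,0
sand_clay,0,0,-0.0005,0.0026
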