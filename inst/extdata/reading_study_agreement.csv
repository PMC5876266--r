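region,modality,percent,numerator,denominator,consistent
iliac,mpcpr,94,85,90,TRUE
iliac,axial,88,76,86,TRUE
femoro-popliteal,mpcpr,89,359,405,TRUE
femoro-popliteal,axial,86,335,389,TRUE
infra-popliteal,mpcpr,94,324,344,TRUE
infra-popliteal,axial,94,312,330,FALSE
overall,mpcpr,92,768,839,TRUE
overall,axial,90,725,805,TRUE
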