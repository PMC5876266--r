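region,reader,modality,statistic,percent,numerator,denominator,consistent
iliac,1,mpcpr,sensitivity,82,9,11,TRUE
iliac,1,mpcpr,specificity,95,75,79,TRUE
iliac,1,mpcpr,accuracy,93,84,90,TRUE
iliac,1,mpcpr,ppv,69,9,13,TRUE
iliac,1,mpcpr,npv,97,75,77,TRUE
iliac,1,axial,sensitivity,90,9,10,TRUE
iliac,1,axial,specificity,88,67,76,TRUE
iliac,1,axial,accuracy,88,76,86,TRUE
iliac,1,axial,ppv,50,9,18,TRUE
iliac,1,axial,npv,99,67,68,TRUE
iliac,2,mpcpr,sensitivity,83,10,12,TRUE
iliac,2,mpcpr,specificity,99,79,80,TRUE
iliac,2,mpcpr,accuracy,97,89,92,TRUE
iliac,2,mpcpr,ppv,91,10,11,TRUE
iliac,2,mpcpr,npv,98,79,81,TRUE
iliac,2,axial,sensitivity,100,12,12,TRUE
iliac,2,axial,specificity,95,77,81,TRUE
iliac,2,axial,accuracy,96,89,93,TRUE
iliac,2,axial,ppv,75,12,16,TRUE
iliac,2,axial,npv,100,77,77,TRUE
femoro-popliteal,1,mpcpr,sensitivity,85,74,87,TRUE
femoro-popliteal,1,mpcpr,specificity,95,305,320,TRUE
femoro-popliteal,1,mpcpr,accuracy,93,379,407,TRUE
femoro-popliteal,1,mpcpr,ppv,83,74,89,TRUE
femoro-popliteal,1,mpcpr,npv,96,305,318,TRUE
femoro-popliteal,1,axial,sensitivity,86,74,86,TRUE
femoro-popliteal,1,axial,specificity,88,271,308,TRUE
femoro-popliteal,1,axial,accuracy,88,345,394,TRUE
femoro-popliteal,1,axial,ppv,67,74,111,TRUE
femoro-popliteal,1,axial,npv,96,271,283,TRUE
femoro-popliteal,2,mpcpr,sensitivity,82,75,91,TRUE
femoro-popliteal,2,mpcpr,specificity,88,300,321,FALSE
femoro-popliteal,2,mpcpr,accuracy,91,375,412,TRUE
femoro-popliteal,2,mpcpr,ppv,78,75,96,TRUE
femoro-popliteal,2,mpcpr,npv,98,300,306,TRUE
femoro-popliteal,2,axial,sensitivity,88,82,93,TRUE
femoro-popliteal,2,axial,specificity,92,295,321,TRUE
femoro-popliteal,2,axial,accuracy,91,377,414,TRUE
femoro-popliteal,2,axial,ppv,76,82,108,TRUE
femoro-popliteal,2,axial,npv,96,295,306,TRUE
infra-popliteal,1,mpcpr,sensitivity,95,137,144,TRUE
infra-popliteal,1,mpcpr,specificity,92,186,203,TRUE
infra-popliteal,1,mpcpr,accuracy,93,323,347,TRUE
infra-popliteal,1,mpcpr,ppv,89,137,154,TRUE
infra-popliteal,1,mpcpr,npv,96,177,184,TRUE
infra-popliteal,1,axial,sensitivity,99,138,140,TRUE
infra-popliteal,1,axial,specificity,92,176,192,TRUE
infra-popliteal,1,axial,accuracy,95,314,332,TRUE
infra-popliteal,1,axial,ppv,90,138,154,TRUE
infra-popliteal,1,axial,npv,99,175,177,TRUE
infra-popliteal,2,mpcpr,sensitivity,94,142,151,TRUE
infra-popliteal,2,mpcpr,specificity,99,206,208,TRUE
infra-popliteal,2,mpcpr,accuracy,97,348,359,TRUE
infra-popliteal,2,mpcpr,ppv,99,142,144,TRUE
infra-popliteal,2,mpcpr,npv,96,206,215,TRUE
infra-popliteal,2,axial,sensitivity,95,143,150,TRUE
infra-popliteal,2,axial,specificity,99,199,202,TRUE
infra-popliteal,2,axial,accuracy,97,342,352,TRUE
infra-popliteal,2,axial,ppv,98,143,146,TRUE
infra-popliteal,2,axial,npv,97,199,206,TRUE
overall,1,mpcpr,sensitivity,91,220,242,TRUE
overall,1,mpcpr,specificity,94,566,602,TRUE
overall,1,mpcpr,accuracy,93,786,844,TRUE
overall,1,mpcpr,ppv,86,220,256,TRUE
overall,1,mpcpr,npv,96,539,560,TRUE
overall,1,axial,sensitivity,94,221,236,TRUE
overall,1,axial,specificity,89,514,576,TRUE
overall,1,axial,accuracy,91,735,812,TRUE
overall,1,axial,ppv,78,221,283,TRUE
overall,1,axial,npv,98,511,524,TRUE
overall,2,mpcpr,sensitivity,89,227,254,TRUE
overall,2,mpcpr,specificity,96,585,609,TRUE
overall,2,mpcpr,accuracy,94,812,863,TRUE
overall,2,mpcpr,ppv,90,227,251,TRUE
overall,2,mpcpr,npv,96,585,612,TRUE
overall,2,axial,sensitivity,93,237,255,TRUE
overall,2,axial,specificity,95,571,604,TRUE
overall,2,axial,accuracy,94,808,859,TRUE
overall,2,axial,ppv,88,237,270,TRUE
overall,2,axial,npv,97,571,589,TRUE
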