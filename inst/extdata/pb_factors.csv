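name,units,low,high,coefficient,t_value,p_value
ZmPAL,mg/mL,1.5,2.25,8.35,2.92,0.027
At4CL4,mg/mL,1.5,2.25,-2.5,-0.87,0.416
GmCHS,mg/mL,1.25,1.88,-8.77,-3.06,0.022
MsCHR,mg/mL,1.25,1.88,7.62,2.66,0.037
ZmCHI,mg/mL,1,1.5,-4.68,-1.64,0.153
CoA,mM,1.5,2.25,3.99,1.39,0.213
ATP,mM,1.5,2.25,0.75,0.26,0.801
NADPH,mM,1.5,2.25,-5.83,-2.04,0.088
tyrosine,mM,2,3,5.73,2,0.092
pH,pH,6,8,7.07,2.47,0.048
temperature,degC,30,37,5.7,1.99,0.094
time,h,24,36,-1.76,-0.62,0.561
volume,uL,50,75,8.66,3.03,0.023
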