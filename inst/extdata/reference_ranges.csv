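measurement,sex,low,high,term_low,term_normal,term_high,units
platelet_count,any,150,450,thrombocytopenia,no thrombocytopenia,thrombocytosis,10^9/L
haemoglobin,male,130,170,anaemia,normal haemoglobin level,polycythaemia,g/L
haemoglobin,female,120,150,anaemia,normal haemoglobin level,polycythaemia,g/L
liver_size,any,0,1.25,,no hepatomegaly,hepatomegaly,multiples of normal
spleen_size,any,0,1.25,,no splenomegaly,splenomegaly,multiples of normal
lvmi,male,0,48,,normal left ventricular mass,left ventricular hypertrophy,g/m^2.7
lvmi,female,0,44,,normal left ventricular mass,left ventricular hypertrophy,g/m^2.7
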