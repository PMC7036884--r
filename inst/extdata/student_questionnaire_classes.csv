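class_label,first,last
Personal characteristics,1,18
Nutritional data,19,62
Physical activities,63,72
Smoking,73,81
Alcohol consumption,82,89
Drug use,90,95
Personal relationships,96,107
Hygiene and oral health,108,113
Security,114,130
Access to health services,131,138
Body image,139,145
Your opinion,146,146
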