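icpc,label,n_prescriptions
R74,Acute upper respiratory tract infection,3564
U71,Acute cystitis,3068
R76,Acute tonsillitis,2294
R78,Acute bronchitis,2223
H71,Acute otitis media,2129
,Diagnosis missing,1612
S76,Erysipelas,1344
D82,Teeth/gum disease,982
R75,Acute sinusitis,965
R81,Pneumonia,684
R77,Acute laryngitis/tracheitis,1092
R05,Cough (symptom),704
U70,Pyelonephritis,380
S84,Impetigo,900
S97,Infected skin ulcer,881
H70,Otitis externa,560
H01,Ear pain (symptom),150
D83,Mouth/tongue/lip disease,725
A78,Infectious disease other,700
A03,Fever (symptom),151
F70,Infectious conjunctivitis,428
X84,Vaginitis/vulvitis,350
L70,Infection of musculoskeletal system,200
Y75,Balanitis,150
B70,Acute lymphadenitis,100
W71,Infection complicating pregnancy,50
N71,Meningitis/encephalitis,30
T70,Endocrine infection,20
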