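# Published 2017-2021 study-period class totals (kg of active ingredient)
# of veterinary antimicrobial imports into Fiji, as printed in the
# veterinary/human importance summary (second-generation cephalosporins
# carry the 0.01 kg shown there); nitroimidazoles are outside the WOAH
# importance list and appear only in the class breakdown.
class,subclass,kg
Aminoglycosides,,1.98
Cephalosporins,First-generation cephalosporin,1.94
Cephalosporins,Second-generation cephalosporin,0.01
Quinolones,Fluoroquinolone,0.13
Lincosamides,,14.36
Macrolides,,28.78
Penicillins,,323.73
Sulfonamides,,19.06
Tetracyclines,,74.06
Nitroimidazoles,,0.26
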