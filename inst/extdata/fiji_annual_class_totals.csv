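# Annual quantities (kg of active ingredient) of veterinary antimicrobials
# imported into Fiji, 2017-2021, by class and subclass, as published in the
# national import study. One transcription note: the 2018 first-generation
# cephalosporin cell is entered as 0.01 kg, the only reading consistent with
# its printed row total (1.94), column total (134.08) and percent share (0.01).
class,subclass,year,kg
Aminoglycosides,,2017,0.29
Aminoglycosides,,2018,0
Aminoglycosides,,2019,0.16
Aminoglycosides,,2020,0.14
Aminoglycosides,,2021,1.39
Cephalosporins,First-generation cephalosporin,2017,0.83
Cephalosporins,First-generation cephalosporin,2018,0.01
Cephalosporins,First-generation cephalosporin,2019,0.43
Cephalosporins,First-generation cephalosporin,2020,0.08
Cephalosporins,First-generation cephalosporin,2021,0.60
Cephalosporins,Second-generation cephalosporin,2017,0
Cephalosporins,Second-generation cephalosporin,2018,0
Cephalosporins,Second-generation cephalosporin,2019,0.01
Cephalosporins,Second-generation cephalosporin,2020,0
Cephalosporins,Second-generation cephalosporin,2021,0
Quinolones,Fluoroquinolone,2017,0.01
Quinolones,Fluoroquinolone,2018,0.01
Quinolones,Fluoroquinolone,2019,0.10
Quinolones,Fluoroquinolone,2020,0
Quinolones,Fluoroquinolone,2021,0.01
Lincosamides,,2017,14.25
Lincosamides,,2018,0
Lincosamides,,2019,0.04
Lincosamides,,2020,0.03
Lincosamides,,2021,0.05
Macrolides,,2017,0.02
Macrolides,,2018,28.75
Macrolides,,2019,0.01
Macrolides,,2020,0
Macrolides,,2021,0
Penicillins,,2017,103.16
Penicillins,,2018,101.84
Penicillins,,2019,94.33
Penicillins,,2020,13.63
Penicillins,,2021,10.78
Sulfonamides,,2017,1.85
Sulfonamides,,2018,0
Sulfonamides,,2019,1.35
Sulfonamides,,2020,3.29
Sulfonamides,,2021,12.57
Tetracyclines,,2017,9.49
Tetracyclines,,2018,3.48
Tetracyclines,,2019,57.06
Tetracyclines,,2020,2.06
Tetracyclines,,2021,1.97
Nitroimidazoles,,2017,0.03
Nitroimidazoles,,2018,0
Nitroimidazoles,,2019,0.08
Nitroimidazoles,,2020,0
Nitroimidazoles,,2021,0.15
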